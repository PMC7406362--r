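#' Read and write streams, truth tables and event tables
#'
#' Plain-text interchange: a 2D stream is a delimited matrix with a header
#' row of location indices (one row per time step); a 3D stream is a
#' long-format table `t, x, y, value`. Ground truth is a long-format pixel
#' table plus an event registry. All files are tab-separated with headers.
#'
#' @param stream A `labeled_stream` (writers) or file prefix/paths (readers).
#' @param path,prefix File path or path prefix.
#' @name stream_io
NULL

# full-precision text so numeric round-trips are bit-exact
fmt_full <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

#' @rdname stream_io
#' @export
write_stream_matrix <- function(stream, path) {
  values <- if (inherits(stream, "labeled_stream")) stream$values else stream
  df <- fmt_full(as.data.frame(values))
  names(df) <- paste0("loc_", seq_len(ncol(values)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_stream_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  unname(as.matrix(df))
}

#' @rdname stream_io
#' @export
write_stream_3d <- function(stream, path) {
  values <- if (inherits(stream, "labeled_stream")) stream$values else stream
  idx <- arrayInd(seq_along(values), dim(values))
  df <- fmt_full(data.frame(t = idx[, 1L], x = idx[, 2L], y = idx[, 3L],
                            value = as.vector(values)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_stream_3d <- function(path) {
  df <- utils::read.delim(path)
  dims <- c(max(df$t), max(df$x), max(df$y))
  arr <- array(NA_real_, dim = dims)
  arr[cbind(df$t, df$x, df$y)] <- df$value
  arr
}

#' Write / read a labelled stream (values, truth mask, registry)
#'
#' Writes three files under a common prefix: `<prefix>_values.tsv` (the
#' stream), `<prefix>_truth.tsv` (long-format nonzero truth-mask pixels) and
#' `<prefix>_registry.tsv`. Reading the trio back reproduces the stream
#' bit-exactly up to numeric text round-trip.
#'
#' @param stream A `labeled_stream`.
#' @param prefix Path prefix for the three files.
#' @return `write_labeled_stream` returns the prefix invisibly;
#'   `read_labeled_stream` returns a `labeled_stream`.
#' @export
write_labeled_stream <- function(stream, prefix) {
  is3d <- stream$dims == "3d"
  if (is3d) write_stream_3d(stream, paste0(prefix, "_values.tsv"))
  else write_stream_matrix(stream, paste0(prefix, "_values.tsv"))
  idx <- which(stream$truth_mask != 0L, arr.ind = TRUE)
  truth <- if (is3d)
    data.frame(t = idx[, 1L], x = idx[, 2L], y = idx[, 3L],
               event_id = stream$truth_mask[idx])
  else
    data.frame(t = idx[, 1L], loc = idx[, 2L],
               event_id = stream$truth_mask[idx])
  utils::write.table(truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(stream$registry),
                     paste0(prefix, "_registry.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_labeled_stream
#' @export
read_labeled_stream <- function(prefix) {
  vpath <- paste0(prefix, "_values.tsv")
  header <- readLines(vpath, n = 1L)
  is3d <- identical(strsplit(header, "\t")[[1L]][1:2], c("t", "x"))
  values <- if (is3d) read_stream_3d(vpath) else read_stream_matrix(vpath)
  truth <- utils::read.delim(paste0(prefix, "_truth.tsv"))
  mask <- array(0L, dim = dim(values))
  if (nrow(truth) > 0L) {
    idx <- if (is3d) cbind(truth$t, truth$x, truth$y) else
      cbind(truth$t, truth$loc)
    mask[idx] <- truth$event_id
  }
  registry <- tibble::as_tibble(
    utils::read.delim(paste0(prefix, "_registry.tsv")))
  new_labeled_stream(values, mask, registry, NULL,
                     dims = if (is3d) "3d" else "2d")
}

#' Write / read an event set
#'
#' Events go to `<prefix>_pixels.tsv` (long format `event_id, t, loc(,y),
#' value`) with a sidecar `<prefix>_info.tsv` carrying per-event pixel
#' counts and first detection times.
#'
#' @param events An `event_set`.
#' @param prefix Path prefix.
#' @export
write_events <- function(events, prefix) {
  utils::write.table(fmt_full(as.data.frame(events$pixels)),
                     paste0(prefix, "_pixels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(events$info),
                     paste0(prefix, "_info.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_events
#' @export
read_events <- function(prefix) {
  px <- tibble::as_tibble(utils::read.delim(paste0(prefix, "_pixels.tsv")))
  info <- tibble::as_tibble(utils::read.delim(paste0(prefix, "_info.tsv")))
  structure(list(pixels = px, info = info, q = NA_real_,
                 changepoints = NULL), class = "event_set")
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Writes the complete model document — ages, penalty, feature names,
#' standardization constants, coefficient rows and fit diagnostics — so a
#' model can be trained in one session and applied in another.
#'
#' @param model A `cc_model` or `cc_pooled`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  doc <- unclass(model)
  doc$.class <- class(model)[1L]
  if (inherits(model, "cc_model")) {
    doc$coeff <- as.data.frame(model$coeff)
    doc$standardization$centers <- as.data.frame(model$standardization$centers)
    doc$standardization$scales <- as.data.frame(model$standardization$scales)
  } else {
    doc$coeff <- as.list(model$coeff)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- doc$.class
  doc$.class <- NULL
  if (cls == "cc_model") {
    doc$coeff <- as.matrix(doc$coeff)
    rownames(doc$coeff) <- doc$ages
    doc$standardization$centers <- as.matrix(doc$standardization$centers)
    doc$standardization$scales <- as.matrix(doc$standardization$scales)
    rownames(doc$standardization$centers) <- doc$ages
    rownames(doc$standardization$scales) <- doc$ages
  } else {
    doc$coeff <- unlist(doc$coeff)
    doc$standardization$centers <- unlist(doc$standardization$centers)
    doc$standardization$scales <- unlist(doc$standardization$scales)
  }
  structure(doc, class = cls)
}

#' Write / read an observation table
#'
#' @param table Observation tibble.
#' @param path File path (tab-separated with header).
#' @export
write_observations <- function(table, path) {
  utils::write.table(fmt_full(as.data.frame(table)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}
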