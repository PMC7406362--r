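#' Extraction parameters
#'
#' Parameter set of the change-point density-based event extractor: the upper
#' quantile level `alpha` defining high-signal pixels, the DBSCAN
#' neighbourhood radius `eps` and density threshold `min_pts`, the PELT
#' penalty specification, and a flag for extracting low-valued events by
#' negating the stream first. Defaults are `alpha = 0.95`, `eps = 5`,
#' `min_pts = 10`.
#'
#' @param alpha Quantile level in (0, 1).
#' @param eps Neighbourhood radius in pixel units.
#' @param min_pts Minimum number of points (including the point itself) in an
#'   `eps`-neighbourhood for a core point.
#' @param pelt_penalty Penalty per change point (`NULL` = `3 * log(n)`).
#' @param pelt_cost `"meanvar"` or `"mean"` segment cost.
#' @param low_value_mode Negate the stream before extraction.
#' @param boundary_slack Dilation (in index units) applied to the change-point
#'   sets when confirming candidate events; 0 keeps the exact intersection.
#' @return A list of class `extraction_params`.
#' @export
extraction_params <- function(alpha = 0.95, eps = 5, min_pts = 10,
                              pelt_penalty = NULL, pelt_cost = "meanvar",
                              low_value_mode = FALSE, boundary_slack = 0L) {
  stopifnot(alpha > 0, alpha < 1, eps > 0, min_pts >= 1)
  structure(list(alpha = alpha, eps = eps, min_pts = as.integer(min_pts),
                 pelt_penalty = pelt_penalty, pelt_cost = pelt_cost,
                 low_value_mode = isTRUE(low_value_mode),
                 boundary_slack = as.integer(boundary_slack)),
            class = "extraction_params")
}

#' High-signal pixels above the alpha-quantile
#'
#' Computes the `alpha`-quantile `q` of all entries of `X` (linear
#' interpolation between order statistics) and returns every coordinate whose
#' value is strictly greater than `q`.
#'
#' @param X Numeric matrix or 3D array.
#' @param alpha Quantile level in (0, 1).
#' @return List with `S` (integer coordinate matrix, one row per pixel,
#'   columns `t, loc` or `t, x, y`) and `q` (the threshold).
#' @export
threshold_pixels <- function(X, alpha = 0.95) {
  stopifnot(all(is.finite(X)))
  q <- stats::quantile(X, probs = alpha, names = FALSE, type = 7)
  S <- which(X > q, arr.ind = TRUE)
  colnames(S) <- if (length(dim(X)) == 3L || (is.array(X) && length(dim(X)) == 3L))
    c("t", "x", "y") else c("t", "loc")
  list(S = unname_rows(S), q = q)
}

unname_rows <- function(m) { rownames(m) <- NULL; m }

#' Density-based clustering of pixel coordinates (DBSCAN)
#'
#' Standard DBSCAN with Euclidean distance on integer grid coordinates: a
#' core point has at least `min_pts` points (itself included) within radius
#' `eps`; clusters are the connected components of density-reachability;
#' points reachable from no core point are noise and get label 0. Cluster ids
#' `1..K` are assigned in first-encounter order of the input rows.
#' Neighbourhood queries use spatial grid binning with cell size `eps`, so
#' only points in adjacent cells are examined.
#'
#' @param S Integer coordinate matrix (unique rows), any dimension.
#' @param eps Radius.
#' @param min_pts Core-point threshold.
#' @return Integer vector of cluster labels aligned with the rows of `S`.
#' @export
density_cluster <- function(S, eps = 5, min_pts = 10) {
  n <- nrow(S)
  if (is.null(n) || n == 0L) return(integer(0))
  d <- ncol(S)
  eps2 <- eps^2
  # bucket points into cells of side eps; neighbours live in adjacent cells
  cell <- floor(S / eps)
  cell <- sweep(cell, 2L, apply(cell, 2L, min))
  mult <- cumprod(c(1, apply(cell, 2L, max) + 3))[seq_len(d)]
  key <- as.vector(cell %*% mult)
  bucket_keys <- sort(unique(key))
  bucket_of <- split(seq_len(n), factor(key, levels = bucket_keys))
  off_keys <- as.vector(as.matrix(
    do.call(expand.grid, rep(list(-1:1), d))) %*% mult)
  ei <- vector("list", length(off_keys))
  for (o in seq_along(off_keys)) {
    tgt <- match(key + off_keys[o], bucket_keys)
    has <- which(!is.na(tgt))
    if (length(has) == 0L) next
    cand_lists <- bucket_of[tgt[has]]
    cnt <- lengths(cand_lists)
    ii <- rep.int(has, cnt)
    jj <- unlist(cand_lists, use.names = FALSE)
    dif2 <- rowSums((S[ii, , drop = FALSE] - S[jj, , drop = FALSE])^2)
    okp <- dif2 <= eps2
    ei[[o]] <- cbind(ii[okp], jj[okp])
  }
  edges <- do.call(rbind, ei)   # includes self-pairs (i, i)
  deg <- tabulate(edges[, 1L], nbins = n)
  core <- deg >= min_pts
  comp <- integer(n)
  cc_edges <- edges[core[edges[, 1L]] & core[edges[, 2L]], , drop = FALSE]
  if (any(core)) {
    g <- igraph::graph_from_edgelist(cc_edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::gorder(g)))
    comp_all <- as.integer(igraph::components(g)$membership)
    comp[core] <- comp_all[which(core)]
  }
  finalize_dbscan_labels(S, edges, core, comp)
}

# Shared deterministic finish: border points join the cluster of their
# lowest-index core neighbour; cluster ids 1..K in first-encounter order.
finalize_dbscan_labels <- function(S, edges, core, comp) {
  n <- nrow(S)
  labels <- integer(n)
  labels[core] <- comp[core]
  border <- which(!core)
  if (length(border) > 0L && any(core)) {
    e <- edges[edges[, 1L] %in% border & core[edges[, 2L]], , drop = FALSE]
    if (nrow(e) > 0L) {
      first_core <- tapply(e[, 2L], e[, 1L], min)
      labels[as.integer(names(first_core))] <- comp[as.integer(first_core)]
    }
  }
  # renumber in order of first appearance along the input rows
  seen <- unique(labels[labels > 0L])
  labels[labels > 0L] <- match(labels[labels > 0L], seen)
  labels
}

#' Brute-force DBSCAN oracle
#'
#' O(n^2) density-reachability closure used as an independent check of
#' [density_cluster()]: core points are found from the full distance matrix,
#' clusters are connected components of the core-core adjacency at radius
#' `eps`, and border points join the cluster of the first core point (in row
#' order) within `eps`. Intended for small fixtures only.
#'
#' @inheritParams density_cluster
#' @return Integer label vector (0 = noise), ids in first-encounter order.
#' @export
density_cluster_bruteforce <- function(S, eps = 5, min_pts = 10) {
  n <- nrow(S)
  if (is.null(n) || n == 0L) return(integer(0))
  D2 <- as.matrix(stats::dist(S))^2
  within <- D2 <= eps^2
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    k <- k + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == 0L &
                      apply(within[, comp, drop = FALSE], 1L, any))
      grow <- setdiff(grow, comp)
      labels[comp] <- k
      if (length(grow) == 0L) break
      comp <- c(comp, grow)
    }
  }
  for (i in which(labels == 0L & !core)) {
    reach <- which(core & within[i, ])
    if (length(reach) > 0L) labels[i] <- labels[min(reach)]
  }
  seen <- unique(labels[labels > 0L])
  labels[labels > 0L] <- match(labels[labels > 0L], seen)
  labels
}

#' Confirm candidate clusters by change points
#'
#' A candidate cluster is retained exactly when it contains at least one
#' pixel whose first coordinate lies in `C1` or whose second coordinate lies
#' in `C2` (for 3D, any coordinate in its dimension's change-point set).
#' Noise pixels (label 0) are always dropped. Retained clusters are
#' renumbered `1..K` preserving their original order.
#'
#' @param S Coordinate matrix as from [threshold_pixels()].
#' @param labels Cluster labels aligned with `S`.
#' @param cps List of change-point index vectors, one per coordinate of `S`
#'   (e.g. `list(C1, C2)`), each optionally dilated by the caller.
#' @return Integer vector of retained event ids aligned with `S` (0 = drop).
#' @export
filter_candidates <- function(S, labels, cps) {
  stopifnot(length(labels) == nrow(S), length(cps) == ncol(S))
  hit <- rep(FALSE, nrow(S))
  for (d in seq_along(cps)) hit <- hit | (S[, d] %in% cps[[d]])
  keep_ids <- sort(unique(labels[labels > 0L & hit]))
  out <- integer(length(labels))
  for (j in seq_along(keep_ids)) out[labels == keep_ids[j]] <- j
  out
}

dilate_cps <- function(cp, slack) {
  if (slack <= 0L || length(cp) == 0L) return(cp)
  sort(unique(as.integer(outer(cp, -slack:slack, `+`))))
}

#' Extract events from a 2D or 3D stream (CPDBEE)
#'
#' End-to-end event extraction: change points in each dimension from PELT on
#' first principal-component score series, thresholding at the
#' `alpha`-quantile, DBSCAN clustering of the above-threshold pixels, and
#' retention of clusters confirmed by a change point. With `low_value_mode`
#' the stream is negated first so that low-valued events are extracted.
#'
#' @param X Numeric matrix (`t` by `loc`) or 3D array (`t`, `x`, `y`).
#' @param params An [extraction_params()].
#' @return An `event_set`: a list with `pixels` (tibble `event_id, t,
#'   loc(, loc2), value`), `info` (tibble `event_id, n_pixels,
#'   first_detection_time` and bounding box columns), the threshold `q` and
#'   the change-point sets used.
#' @export
extract_events <- function(X, params = extraction_params()) {
  # detection runs on the (possibly negated) working copy; reported pixel
  # values always come from the caller's input
  W <- if (params$low_value_mode) -X else X
  is3d <- length(dim(W)) == 3L
  cps <- if (is3d) {
    cc <- changepoints_3d(W, penalty = params$pelt_penalty,
                          cost = params$pelt_cost)
    list(cc$C_t, cc$C_x, cc$C_y)
  } else {
    cc <- changepoints_2d(W, penalty = params$pelt_penalty,
                          cost = params$pelt_cost)
    list(cc$C1, cc$C2)
  }
  th <- threshold_pixels(W, params$alpha)
  labels <- density_cluster(th$S, eps = params$eps, min_pts = params$min_pts)
  cps_used <- lapply(cps, dilate_cps, slack = params$boundary_slack)
  ids <- filter_candidates(th$S, labels, cps_used)
  build_event_set(th$S, X, ids, q = th$q, cps = cps)
}

build_event_set <- function(S, X, ids, q = NA_real_, cps = NULL) {
  keep <- ids > 0L
  Sk <- S[keep, , drop = FALSE]
  px <- tibble::as_tibble(as.data.frame(Sk))
  px$value <- as.numeric(X[Sk])
  px <- dplyr::bind_cols(tibble::tibble(event_id = ids[keep]), px)
  px <- dplyr::arrange(px, .data$event_id, .data$t)
  info <- event_info(px)
  structure(list(pixels = px, info = info, q = q, changepoints = cps),
            class = "event_set")
}

event_info <- function(px) {
  if (nrow(px) == 0L) {
    return(tibble::tibble(event_id = integer(), n_pixels = integer(),
                          t_min = integer(), t_max = integer(),
                          first_detection_time = integer()))
  }
  px |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(n_pixels = dplyr::n(),
                     t_min = min(.data$t), t_max = max(.data$t),
                     .groups = "drop") |>
    dplyr::mutate(first_detection_time = .data$t_max)
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set> ", nrow(x$info), " events, ", nrow(x$pixels),
      " pixels (threshold q = ", format(x$q, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Jaccard index between actual and detected masks
#'
#' Pixelwise comparison of two same-shape binary masks:
#' `J = TP / (TP + FN + FP)`, i.e. intersection over union of the two pixel
#' sets. When both masks are empty the union is empty and `J = 1` by
#' convention.
#'
#' @param actual_mask,detected_mask Same-shape masks; nonzero = event pixel.
#' @return A one-row tibble with `tp`, `fp`, `fn` and `j`.
#' @export
jaccard_index <- function(actual_mask, detected_mask) {
  da <- dim(actual_mask) %||% length(actual_mask)
  db <- dim(detected_mask) %||% length(detected_mask)
  if (!identical(da, db)) stop("mask shapes differ", call. = FALSE)
  a <- actual_mask != 0
  b <- detected_mask != 0
  tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
  j <- if (tp + fp + fn == 0L) 1 else tp / (tp + fn + fp)
  tibble::tibble(tp = tp, fp = fp, fn = fn, j = j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mask of detected event pixels
#'
#' Converts an `event_set` into a binary/integer mask on the stream's grid,
#' for Jaccard evaluation against a truth mask.
#'
#' @param events An `event_set`.
#' @param dim Dimensions of the stream the events came from.
#' @return Integer mask (event id per pixel, 0 elsewhere).
#' @export
event_mask <- function(events, dim) {
  m <- array(0L, dim = dim)
  px <- events$pixels
  if (nrow(px) > 0L) {
    idx <- if ("loc2" %in% names(px) || "y" %in% names(px))
      cbind(px$t, px$x, px$y) else cbind(px$t, px$loc)
    m[idx] <- px$event_id
  }
  m
}

#' Tune extraction parameters by Jaccard index
#'
#' Evaluates the full grid of `(alpha, eps, min_pts)` combinations on a
#' labelled stream, scoring each by the Jaccard index between the truth mask
#' and the mask of extracted events, and returns the maximizer. Ties are
#' broken toward larger `alpha`, then smaller `eps`, then larger `min_pts`.
#'
#' @param stream A `labeled_stream` with a truth mask.
#' @param alpha_grid,eps_grid,min_pts_grid Numeric grids; all combinations
#'   are evaluated.
#' @param params Base [extraction_params()] supplying the remaining settings.
#' @return List with `best` (an `extraction_params`) and `table` (tibble of
#'   `alpha, eps, min_pts, j` for every combination).
#' @export
tune_parameters <- function(stream, alpha_grid, eps_grid, min_pts_grid,
                            params = extraction_params()) {
  if (length(alpha_grid) == 0L || length(eps_grid) == 0L ||
      length(min_pts_grid) == 0L)
    stop("parameter grids must be nonempty", call. = FALSE)
  grid <- tidyr::expand_grid(alpha = alpha_grid, eps = eps_grid,
                             min_pts = min_pts_grid)
  dims <- dim(stream$values)
  grid$j <- purrr::pmap_dbl(grid, function(alpha, eps, min_pts) {
    p <- params
    p$alpha <- alpha; p$eps <- eps; p$min_pts <- as.integer(min_pts)
    ev <- extract_events(stream$values, p)
    jaccard_index(stream$truth_mask, event_mask(ev, dims))$j
  })
  ord <- order(-grid$j, -grid$alpha, grid$eps, -grid$min_pts)
  top <- grid[ord[1L], ]
  best <- params
  best$alpha <- top$alpha; best$eps <- top$eps
  best$min_pts <- as.integer(top$min_pts)
  list(best = best, table = grid)
}

#' Scan a stream with a moving window
#'
#' Emulates streaming arrival of data: the window first grows from
#' `warmup_width` to `window_width` one step at a time (so young events can
#' be caught as soon as they develop), then slides forward by `step`. Events
#' are extracted in every window; detections in different windows are
#' identified as the same event when they share any pixel, keeping the
#' earliest window end time as the event's `first_detection_time` and
#' accumulating the union of detected pixels.
#'
#' @param X Stream matrix (rows = time).
#' @param window_width Width `w` of the moving window (time steps).
#' @param step Slide increment after the window reaches full width.
#' @param params [extraction_params()].
#' @param warmup_width Initial window width; defaults to `window_width` (no
#'   growth phase). Must not exceed `window_width`.
#' @return An `event_set` whose `info` carries per-event
#'   `first_detection_time` (window end time of first extraction).
#' @export
stream_scan <- function(X, window_width, step = 1L,
                        params = extraction_params(),
                        warmup_width = window_width) {
  nt <- nrow(X)
  stopifnot(window_width <= nt, step >= 1L)
  if (warmup_width > window_width)
    stop("warmup_width must not exceed window_width", call. = FALSE)
  ends <- unique(c(seq.int(warmup_width, window_width),
                   seq.int(window_width, nt, by = step),
                   nt))
  ends <- sort(unique(ends[ends <= nt]))
  assign_mask <- array(0L, dim = dim(X))
  first_det <- integer(0)
  det_start <- integer(0)   # event start as known in the first detecting window
  next_id <- 0L
  for (e in ends) {
    s <- max(1L, e - window_width + 1L)
    win <- if (length(dim(X)) == 3L) X[s:e, , , drop = FALSE] else
      X[s:e, , drop = FALSE]
    ev <- suppressWarnings(extract_events(win, params))
    if (nrow(ev$pixels) == 0L) next
    px <- ev$pixels
    px$t <- px$t + s - 1L
    for (cid in unique(px$event_id)) {
      sub <- px[px$event_id == cid, , drop = FALSE]
      idx <- if ("y" %in% names(sub)) cbind(sub$t, sub$x, sub$y) else
        cbind(sub$t, sub$loc)
      hits <- unique(assign_mask[idx])
      hits <- hits[hits > 0L]
      if (length(hits) == 0L) {
        next_id <- next_id + 1L
        gid <- next_id
        first_det[gid] <- e
        det_start[gid] <- min(sub$t)
      } else {
        gid <- min(hits)
        # merge any other overlapped ids into the earliest one
        for (h in setdiff(hits, gid)) {
          assign_mask[assign_mask == h] <- gid
          if (first_det[h] < first_det[gid])
            det_start[gid] <- det_start[h]
          first_det[gid] <- min(first_det[gid], first_det[h])
          first_det[h] <- NA_integer_
        }
      }
      assign_mask[idx] <- gid
    }
  }
  scan_result_from_mask(X, assign_mask, first_det, det_start)
}

scan_result_from_mask <- function(X, assign_mask, first_det,
                                  det_start = NULL) {
  live <- which(!is.na(first_det) & tabulate(assign_mask[assign_mask > 0L],
                                             nbins = length(first_det)) > 0L)
  idx <- which(assign_mask > 0L, arr.ind = TRUE)
  is3d <- length(dim(X)) == 3L
  if (nrow(idx) == 0L) {
    px <- if (is3d)
      tibble::tibble(event_id = integer(), t = integer(), x = integer(),
                     y = integer(), value = numeric())
    else
      tibble::tibble(event_id = integer(), t = integer(), loc = integer(),
                     value = numeric())
    return(structure(list(pixels = px, info = event_info(px), q = NA_real_,
                          changepoints = NULL), class = "event_set"))
  }
  old_ids <- assign_mask[idx]
  new_ids <- match(old_ids, live)
  px <- if (is3d)
    tibble::tibble(event_id = new_ids, t = idx[, 1L], x = idx[, 2L],
                   y = idx[, 3L], value = X[idx])
  else
    tibble::tibble(event_id = new_ids, t = idx[, 1L], loc = idx[, 2L],
                   value = X[idx])
  px <- dplyr::arrange(px, .data$event_id, .data$t)
  info <- event_info(px)
  info$first_detection_time <- first_det[live][match(info$event_id,
                                                     seq_along(live))]
  if (!is.null(det_start))
    info$detected_start <- det_start[live][match(info$event_id,
                                                 seq_along(live))]
  structure(list(pixels = px, info = info, q = NA_real_,
                 changepoints = NULL), class = "event_set")
}

#' Detection delays against a ground-truth registry
#'
#' Matches each detected event to the truth event with which it shares the
#' most pixels (via the truth mask) and reports, per truth event, the delay
#' `first_detection_time - start_time`. Truth events matched by no detection
#' get a missing delay.
#'
#' @param detections An `event_set` from [stream_scan()] or
#'   [extract_events()].
#' @param stream The `labeled_stream` the detections came from.
#' @return Tibble with one row per truth event: `event_id`, `class`,
#'   `start_time`, `detected_id`, `first_detection_time`, `delay`.
#' @export
detection_delays <- function(detections, stream) {
  reg <- stream$registry
  mask <- stream$truth_mask
  px <- detections$pixels
  match_tbl <- NULL
  if (nrow(px) > 0L) {
    idx <- if ("y" %in% names(px)) cbind(px$t, px$x, px$y) else
      cbind(px$t, px$loc)
    truth_id <- mask[idx]
    ov <- tibble::tibble(detected_id = px$event_id, truth_id = truth_id) |>
      dplyr::filter(.data$truth_id > 0L) |>
      dplyr::count(.data$truth_id, .data$detected_id)
    # each truth event takes the detection overlapping it most; a detection
    # may cover several truth events (they merge into one detected blob)
    match_tbl <- ov |>
      dplyr::group_by(.data$truth_id) |>
      dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  out <- reg |>
    dplyr::select(dplyr::any_of(c("event_id", "class", "start_time")))
  if (is.null(match_tbl) || nrow(match_tbl) == 0L) {
    out$detected_id <- NA_integer_
    out$first_detection_time <- NA_integer_
  } else {
    out <- out |>
      dplyr::left_join(match_tbl, by = c(event_id = "truth_id")) |>
      dplyr::rename(overlap = "n") |>
      dplyr::left_join(detections$info |>
                         dplyr::select("event_id", "first_detection_time") |>
                         dplyr::rename(detected_id = "event_id"),
                       by = "detected_id")
  }
  out$delay <- out$first_detection_time - out$start_time
  out
}
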