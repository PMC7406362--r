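#' Background model from the head of a window
#'
#' Summarizes the recent-past background of a 2D window: the mean, median,
#' interquartile range and standard deviation of each location (column) over
#' the first `head_len` time steps, each smoothed across location by a cubic
#' smoothing spline with smoothness chosen by generalized cross-validation.
#' The smoothed IQR and sd curves are floored at 0. Local event features
#' (proportions beyond multiples of the local IQR, signal-to-background
#' ratios) are read off these smoothers at the event centroid.
#'
#' @param window Numeric matrix (rows = time, columns = locations).
#' @param head_len Number of initial time steps to use; values larger than
#'   the window are clipped with a warning. Default `max(5, 10%)` of the
#'   window height.
#' @return Object of class `background_model` with a `predict` method
#'   returning the four smoothed statistics at requested locations.
#' @export
fit_background <- function(window, head_len = NULL) {
  nt <- nrow(window)
  if (is.null(head_len)) head_len <- max(5L, ceiling(0.1 * nt))
  if (head_len > nt) {
    warning("head_len exceeds window length; clipped", call. = FALSE)
    head_len <- nt
  }
  stopifnot(head_len >= 2L)
  head <- window[seq_len(head_len), , drop = FALSE]
  stats_tbl <- tibble::tibble(
    loc = seq_len(ncol(window)),
    mean = colMeans(head),
    median = apply(head, 2L, stats::median),
    iqr = apply(head, 2L, stats::IQR),
    sd = apply(head, 2L, stats::sd))
  smoothers <- lapply(c("mean", "median", "iqr", "sd"), function(nm) {
    y <- stats_tbl[[nm]]
    if (length(y) >= 10L && stats::sd(y) > 0) {
      fit <- stats::smooth.spline(stats_tbl$loc, y, cv = FALSE)
      function(loc) stats::predict(fit, loc)$y
    } else {
      # too few locations (or flat): piecewise-linear through the raw stats
      function(loc) stats::approx(stats_tbl$loc, y, xout = loc,
                                  rule = 2L)$y
    }
  })
  names(smoothers) <- c("mean", "median", "iqr", "sd")
  structure(list(smoothers = smoothers, head_len = head_len,
                 n_loc = ncol(window), stats = stats_tbl),
            class = "background_model")
}

#' @export
predict.background_model <- function(object, loc, ...) {
  tibble::tibble(
    loc = loc,
    mean = object$smoothers$mean(loc),
    median = object$smoothers$median(loc),
    iqr = pmax(object$smoothers$iqr(loc), 0),
    sd = pmax(object$smoothers$sd(loc), 0))
}

#' Snapshot of an event at a given age
#'
#' Restricts an event's pixels to its first `age` time slices: pixels with
#' `t < start + age`, where `start` is the event's earliest pixel time. Ages
#' at or beyond the event's duration return the full event; `age = 1` keeps
#' exactly the first time slice.
#'
#' @param pixels Tibble of event pixels with a `t` column.
#' @param age Positive integer age in time steps.
#' @return The filtered pixel tibble.
#' @export
event_snapshot <- function(pixels, age) {
  stopifnot(age >= 1L, nrow(pixels) > 0L)
  start <- min(pixels$t)
  pixels[pixels$t < start + age, , drop = FALSE]
}

#' Feature configuration
#'
#' Selects which feature families are computed. The core features (pixel
#' count, temporal length, spatial width, their ratio, value sum/mean/sd,
#' the slope of a line and the linear and quadratic coefficients of a
#' parabola fitted to the per-time mean signal) are always computed, and the
#' centroid is always carried but never used as a classifier input. The
#' optional families are the global-sd exceedance proportions, the local-IQR
#' exceedance proportions, and the two local signal-to-background ratios
#' (75th percentile in local-IQR units above the local median; 80th
#' percentile in local-sd units above the local mean).
#'
#' Presets: `"full"` enables everything; `"synthetic"` drops the two
#' exceedance-proportion families (kept out of the synthetic experiments for
#' computational economy); `"no_background"` drops every feature that needs
#' the background spline model (local proportions and both local ratios).
#'
#' @param preset `"full"`, `"synthetic"` or `"no_background"`.
#' @param squares Also include the square of every enabled classifier
#'   feature.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(preset = c("full", "synthetic", "no_background"),
                           squares = FALSE) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    full = list(global_props = TRUE, local_props = TRUE, local_snr = TRUE),
    synthetic = list(global_props = FALSE, local_props = FALSE,
                     local_snr = TRUE),
    no_background = list(global_props = TRUE, local_props = FALSE,
                         local_snr = FALSE))
  cfg$squares <- isTRUE(squares)
  cfg$preset <- preset
  structure(cfg, class = "feature_config")
}

needs_background <- function(cfg) cfg$local_props || cfg$local_snr

#' Compute the feature vector of an event (or snapshot)
#'
#' Computes the event features from a pixel tibble: pixel count, temporal
#' length, spatial width, length-to-width ratio, centroid (carried only),
#' value sum, mean and sd, the slope of a least-squares line through the
#' per-time mean signal values, the linear and quadratic coefficients of a
#' least-squares parabola through the same values, and the configured
#' relative-to-background families. Global statistics are taken over the
#' supplied `window`; local statistics are the background smoothers evaluated
#' at the event centroid's location. Events spanning a single time step get
#' zero slope, and events with fewer than three distinct time steps get zero
#' parabola coefficients, so very young snapshots remain classifiable. For 3D
#' events (pixels with `x` and `y`) only the core features plus the global
#' analogue of the sd-ratio are computed.
#'
#' @param pixels Tibble with `t`, `loc` (or `x`, `y`) and `value`.
#' @param window Numeric matrix/array over which global mean and sd are
#'   computed; defaults to the event's own values if omitted.
#' @param background A [fit_background()] model (2D only; required when a
#'   local family is enabled).
#' @param cfg A [feature_config()].
#' @return One-row tibble of named features.
#' @export
compute_features <- function(pixels, window = NULL, background = NULL,
                             cfg = feature_config()) {
  stopifnot(nrow(pixels) > 0L)
  is3d <- "y" %in% names(pixels)
  v <- pixels$value
  ts <- pixels$t
  sp <- if (is3d) pixels$x else pixels$loc
  out <- list(
    n_pixels = as.numeric(nrow(pixels)),
    length = as.numeric(diff(range(ts)) + 1L),
    width = as.numeric(diff(range(sp)) + 1L))
  out$lw_ratio <- out$length / out$width
  out$centroid_t <- mean(ts)
  out$centroid_loc <- mean(sp)
  if (is3d) out$centroid_loc2 <- mean(pixels$y)
  out$value_sum <- sum(v)
  out$value_mean <- mean(v)
  out$value_sd <- if (length(v) > 1L) stats::sd(v) else 0
  tm <- tapply(v, ts, mean)
  x <- as.numeric(names(tm)) - min(ts)
  y <- as.numeric(tm)
  out$slope <- if (length(x) >= 2L)
    unname(stats::coef(stats::lm.fit(cbind(1, x), y))[2L]) else 0
  if (length(x) >= 3L) {
    pc <- stats::coef(stats::lm.fit(cbind(1, x, x^2), y))
    out$parab_lin <- unname(pc[2L]); out$parab_quad <- unname(pc[3L])
  } else {
    out$parab_lin <- 0; out$parab_quad <- 0
  }
  g_mean <- mean(window %||% v)
  g_sd <- stats::sd(window %||% v)
  if (!is3d && cfg$global_props) {
    for (n in 2:4)
      out[[paste0("prop_gsd_", n)]] <- mean(v > g_mean + n * g_sd)
  }
  if (is3d) {
    # global analogue of the sd-ratio feature for 3D streams
    q80 <- stats::quantile(v, 0.80, names = FALSE)
    out$sd_above_mean <- (q80 - g_mean) / max(g_sd, 1e-8)
  } else if (needs_background(cfg)) {
    if (is.null(background))
      stop("background model required for local features", call. = FALSE)
    loc0 <- min(max(round(out$centroid_loc), 1L), background$n_loc)
    bg <- predict(background, loc0)
    if (cfg$local_props) {
      for (n in 5:8)
        out[[paste0("prop_liqr_", n)]] <-
          mean(v > bg$median + n * bg$iqr)
    }
    if (cfg$local_snr) {
      q75 <- stats::quantile(v, 0.75, names = FALSE)
      q80 <- stats::quantile(v, 0.80, names = FALSE)
      out$iqr_above_median <- (q75 - bg$median) / max(bg$iqr, 1e-8)
      out$sd_above_mean <- (q80 - bg$mean) / max(bg$sd, 1e-8)
    }
  }
  res <- tibble::as_tibble(out)
  if (cfg$squares) {
    sq <- res[classifier_feature_names(res)]^2
    names(sq) <- paste0(names(sq), "_sq")
    res <- dplyr::bind_cols(res, sq)
  }
  res
}

#' Names of classifier-input feature columns
#'
#' Every feature column except identifiers, the age, the label and the
#' centroid (which is carried for bookkeeping but never used in
#' classification).
#'
#' @param tbl A feature or observation tibble.
#' @return Character vector of column names.
#' @export
classifier_feature_names <- function(tbl) {
  drop <- c("event_id", "age", "label",
            grep("^centroid", names(tbl), value = TRUE))
  setdiff(names(tbl), drop)
}

#' Build a partial-observation table
#'
#' Produces one row per (event, age) pair: the event's feature vector
#' computed on its snapshot at each requested age, together with its class
#' label. An age contributes a row only when it does not exceed the event's
#' observed duration, and — when scan output with first-detection times is
#' supplied — only when the event had actually been detected by the stream
#' time the snapshot represents. The table is therefore naturally unbalanced
#' across ages: young ages miss late-detected events, old ages miss
#' short-lived ones.
#'
#' @param events An `event_set`; if its `info` has a `label` column (see
#'   [label_events()]) labels are attached to the rows.
#' @param X The stream values the events came from (matrix or 3D array).
#' @param ages Increasing integer vector of snapshot ages.
#' @param cfg [feature_config()].
#' @param window_width When supplied, global/background statistics for a
#'   snapshot are computed over the window of this width ending at the
#'   snapshot's last time step, mirroring what a moving-window scanner would
#'   have seen; otherwise the full stream is used.
#' @param head_len Passed to [fit_background()].
#' @return Tibble `event_id, age, label, <features...>`.
#' @export
build_observation_table <- function(events, X, ages,
                                    cfg = feature_config(),
                                    window_width = NULL, head_len = NULL) {
  info <- events$info
  if (nrow(info) == 0L)
    return(tibble::tibble(event_id = integer(), age = integer(),
                          label = integer()))
  is3d <- length(dim(X)) == 3L
  bg_cache <- new.env(parent = emptyenv())
  get_window <- function(end_t) {
    if (is.null(window_width)) return(X)
    s <- max(1L, end_t - window_width + 1L)
    if (is3d) X[s:end_t, , , drop = FALSE] else X[s:end_t, , drop = FALSE]
  }
  get_background <- function(end_t, win) {
    key <- as.character(end_t)
    if (!is.null(bg_cache[[key]])) return(bg_cache[[key]])
    bg <- fit_background(win, head_len = head_len)
    bg_cache[[key]] <- bg
    bg
  }
  rows <- list()
  for (i in seq_len(nrow(info))) {
    eid <- info$event_id[i]
    px <- events$pixels[events$pixels$event_id == eid, , drop = FALSE]
    # age origin: the start as known when the event was first detected (the
    # accumulated pixel set may backfill earlier, fainter pixels later)
    start <- if ("detected_start" %in% names(info))
      info$detected_start[i] else min(px$t)
    duration <- max(px$t) - start + 1L
    # detection-time gating applies only to scanner output (marked by the
    # detected_start column); a one-shot extraction has no detection history
    fd <- if ("detected_start" %in% names(info))
      info$first_detection_time[i] else NA_integer_
    lab <- if ("label" %in% names(info)) info$label[i] else NA_integer_
    for (age in ages) {
      if (age > duration) next
      end_t <- start + age - 1L
      if (!is.na(fd) && end_t < fd) next  # not yet detected at this age
      snap <- px[px$t < start + age, , drop = FALSE]
      if (nrow(snap) == 0L) next
      win <- get_window(end_t)
      bg <- if (!is3d && needs_background(cfg))
        get_background(if (is.null(window_width)) 0L else end_t, win)
      else NULL
      feats <- compute_features(snap, window = win, background = bg,
                                cfg = cfg)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(event_id = eid, age = age,
                                        label = lab), feats)
    }
  }
  if (length(rows) == 0L)
    return(tibble::tibble(event_id = integer(), age = integer(),
                          label = integer()))
  dplyr::bind_rows(rows)
}

#' Label extracted events from a truth mask
#'
#' Assigns each detected event the class of the truth event it overlaps most
#' (by pixel count), as a binary label with class A = 1 and class B = 0.
#' Detections overlapping no truth event (false positives) get `NA` labels.
#'
#' @param events An `event_set`.
#' @param stream The `labeled_stream` the events were extracted from.
#' @param positive_class Truth class mapped to label 1.
#' @return The `event_set` with `truth_id`, `class` and `label` columns added
#'   to its `info`.
#' @export
label_events <- function(events, stream, positive_class = "A") {
  px <- events$pixels
  info <- events$info
  if (nrow(px) == 0L) {
    info$truth_id <- integer(0); info$class <- character(0)
    info$label <- integer(0)
    events$info <- info
    return(events)
  }
  idx <- if ("y" %in% names(px)) cbind(px$t, px$x, px$y) else
    cbind(px$t, px$loc)
  truth <- stream$truth_mask[idx]
  best <- tibble::tibble(event_id = px$event_id, truth_id = truth) |>
    dplyr::filter(.data$truth_id > 0L) |>
    dplyr::count(.data$event_id, .data$truth_id) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("event_id", "truth_id")
  info <- info |>
    dplyr::left_join(best, by = "event_id") |>
    dplyr::left_join(stream$registry |>
                       dplyr::select("event_id", "class") |>
                       dplyr::rename(truth_id = "event_id"),
                     by = "truth_id")
  info$label <- ifelse(is.na(info$class), NA_integer_,
                       as.integer(info$class == positive_class))
  events$info <- info
  events
}
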