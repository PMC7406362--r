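#' Configuration for the synthetic stream generator
#'
#' Builds the parameter set that defines a simulated spatio-temporal data
#' stream: a grid of `n_time` time steps by `n_loc` locations filled with
#' Gaussian background noise, in which events of two classes (A and B) are
#' buried. An event is a contiguous patch of pixels whose intensities start
#' from a class-specific starting distribution and ramp linearly, in both mean
#' and standard deviation, to a class-specific ending distribution over the
#' event's lifetime.
#'
#' The defaults reproduce the two-class design used throughout the package's
#' synthetic experiments: class A pixels start at N(4, 2) and end at N(8, 2);
#' class B pixels start at N(3, 3) and end at N(5, 3); class A events always
#' have shape 1 while class B events draw one of three shapes; shape-1 events
#' last U\{20..30\} steps with maximum width U\{20..26\}, shapes 2 and 3 last
#' U\{100..150\} steps with maximum widths U\{30..38\} and U\{50..58\};
#' background pixels are N(0, 1).
#'
#' @param n_time Number of time steps (rows).
#' @param n_loc Number of spatial locations (columns).
#' @param event_rate Expected number of events per 1000 time steps.
#' @param class_probs Named probabilities for classes A and B.
#' @param class_A_start,class_A_end,class_B_start,class_B_end Length-2 numeric
#'   vectors `c(mean, sd)` for the starting and ending pixel-value
#'   distributions of each class.
#' @param shape_probs_B Probabilities over shapes 1..3 for class B events
#'   (class A is always shape 1).
#' @param duration_ranges List with elements `shape1`, `shape2`, `shape3`,
#'   each an integer range `c(lo, hi)` for the event duration (maximum age).
#' @param width_ranges List as `duration_ranges` for the maximum location
#'   width of each shape.
#' @param background Length-2 `c(mean, sd)` of the background noise.
#' @param allow_overlap If `FALSE` (default) event placements that would
#'   overlap an existing event are redrawn, since overlapping events are
#'   extracted as a single event downstream.
#' @param placement_margin Minimum empty border (pixels, space and time)
#'   kept around each event's bounding box when `allow_overlap` is `FALSE`,
#'   so that distinct events are not chained into one density cluster by an
#'   extractor whose neighbourhood radius is smaller than the margin.
#' @param seed Optional integer seed; when supplied the generator is
#'   deterministic.
#'
#' @return An object of class `stream_config` (a validated list).
#' @export
stream_config <- function(n_time = 500L,
                          n_loc = 250L,
                          event_rate = 16,
                          class_probs = c(A = 0.5, B = 0.5),
                          class_A_start = c(4, 2),
                          class_A_end = c(8, 2),
                          class_B_start = c(3, 3),
                          class_B_end = c(5, 3),
                          shape_probs_B = c(1 / 3, 1 / 3, 1 / 3),
                          duration_ranges = list(shape1 = c(20L, 30L),
                                                 shape2 = c(100L, 150L),
                                                 shape3 = c(100L, 150L)),
                          width_ranges = list(shape1 = c(20L, 26L),
                                              shape2 = c(30L, 38L),
                                              shape3 = c(50L, 58L)),
                          background = c(0, 1),
                          allow_overlap = FALSE,
                          placement_margin = 10L,
                          seed = NULL) {
  cfg <- list(n_time = as.integer(n_time), n_loc = as.integer(n_loc),
              event_rate = event_rate, class_probs = class_probs,
              class_A_start = class_A_start, class_A_end = class_A_end,
              class_B_start = class_B_start, class_B_end = class_B_end,
              shape_probs_B = shape_probs_B,
              duration_ranges = duration_ranges, width_ranges = width_ranges,
              background = background, allow_overlap = isTRUE(allow_overlap),
              placement_margin = as.integer(placement_margin),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_stream_config(cfg)
  structure(cfg, class = "stream_config")
}

validate_stream_config <- function(cfg) {
  stopifnot(cfg$n_time >= 1L, cfg$n_loc >= 1L, cfg$event_rate >= 0)
  sds <- c(cfg$class_A_start[2], cfg$class_A_end[2],
           cfg$class_B_start[2], cfg$class_B_end[2], cfg$background[2])
  if (any(sds <= 0)) stop("all distribution sds must be > 0", call. = FALSE)
  if (abs(sum(cfg$shape_probs_B) - 1) > 1e-8)
    stop("shape_probs_B must sum to 1", call. = FALSE)
  for (nm in c("shape1", "shape2", "shape3")) {
    dr <- cfg$duration_ranges[[nm]]; wr <- cfg$width_ranges[[nm]]
    if (is.null(dr) || is.null(wr) || dr[2] < dr[1] || wr[2] < wr[1])
      stop("duration/width ranges must be nonempty for ", nm, call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.stream_config <- function(x, ...) {
  cat("<stream_config> ", x$n_time, " x ", x$n_loc,
      ", event rate ", x$event_rate, " / 1000 steps\n", sep = "")
  cat("  class A: start N(", x$class_A_start[1], ",", x$class_A_start[2],
      "), end N(", x$class_A_end[1], ",", x$class_A_end[2], "), shape 1\n",
      sep = "")
  cat("  class B: start N(", x$class_B_start[1], ",", x$class_B_start[2],
      "), end N(", x$class_B_end[1], ",", x$class_B_end[2],
      "), shapes 1-3\n", sep = "")
  invisible(x)
}

#' Draw an event template
#'
#' Samples the geometry of a single event: its class-specific shape, duration
#' and maximum width, and the per-age footprint of location offsets it
#' occupies. Class A events always take shape 1; class B events draw a shape
#' from `shape_probs_B`. Shapes are parametric: shape 1 is a wedge that widens
#' linearly from one location to the maximum width over the event's lifetime;
#' shape 2 widens over the first half and then holds its width; shape 3 is a
#' lens that widens to the maximum width at mid-life and narrows again. All
#' three start from a single location, so young events are genuinely small and
#' partial observations carry limited information.
#'
#' @param class_label `"A"` or `"B"`.
#' @param config A [stream_config()].
#' @return A list of class `event_template` with fields `class_label`,
#'   `shape_id`, `duration`, `max_width` and `footprint` (a list of integer
#'   offset vectors, one per age `0..duration-1`, centred on 0).
#' @export
sample_event_template <- function(class_label, config = stream_config()) {
  stopifnot(class_label %in% c("A", "B"))
  shape_id <- if (class_label == "A") 1L else
    sample.int(3L, 1L, prob = config$shape_probs_B)
  key <- paste0("shape", shape_id)
  dr <- config$duration_ranges[[key]]
  wr <- config$width_ranges[[key]]
  duration <- sample(seq.int(dr[1], dr[2]), 1L)
  max_width <- sample(seq.int(wr[1], wr[2]), 1L)
  footprint <- lapply(seq_len(duration) - 1L, function(a) {
    w <- shape_width(shape_id, a, duration, max_width)
    half <- (w - 1L) %/% 2L
    seq.int(-half, -half + w - 1L)
  })
  structure(list(class_label = class_label, shape_id = shape_id,
                 duration = duration, max_width = max_width,
                 footprint = footprint),
            class = "event_template")
}

# width of an event at age a (0-based) for each parametric shape family
shape_width <- function(shape_id, a, duration, max_width) {
  frac <- if (duration > 1L) a / (duration - 1) else 1
  w <- switch(shape_id,
    # wedge: widen linearly over the whole lifetime
    1 + (max_width - 1) * frac,
    # band: widen over the first half, then constant
    1 + (max_width - 1) * min(1, 2 * frac),
    # lens: widen to mid-life, then narrow symmetrically
    1 + (max_width - 1) * (1 - abs(2 * frac - 1)))
  max(1L, as.integer(round(w)))
}

#' Generate a labelled two-dimensional stream
#'
#' Fills an `n_time` by `n_loc` matrix with iid Gaussian background noise and
#' plants randomly placed events drawn by [sample_event_template()]. A pixel
#' of an event at age `a` (out of duration `d`) is drawn from
#' N(mu(a), sigma(a)) where mean and sd are linearly interpolated between the
#' class's starting and ending distributions at fraction `a / (d - 1)`, so
#' event intensity ramps linearly with age. The number of events is
#' `Poisson(event_rate * n_time / 1000)`; start times and centre locations are
#' uniform over positions where the event fits inside the grid, and
#' placements overlapping an existing event are redrawn unless
#' `allow_overlap` is set.
#'
#' @param config A [stream_config()].
#' @return An object of class `labeled_stream`: a list with `values` (numeric
#'   matrix, rows = time), `truth_mask` (integer matrix, 0 = background,
#'   k = event id) and `registry` (tibble with one row per event: id, class,
#'   shape, start time, duration, max width and centre location).
#' @export
generate_stream <- function(config = stream_config()) {
  validate_stream_config(config)
  run <- function() generate_stream_impl(config)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

generate_stream_impl <- function(config) {
  nt <- config$n_time; nl <- config$n_loc
  values <- matrix(stats::rnorm(nt * nl, config$background[1],
                                config$background[2]), nrow = nt)
  mask <- matrix(0L, nrow = nt, ncol = nl)
  min_dur <- min(vapply(config$duration_ranges, `[`, integer(1), 1L))
  min_wid <- min(vapply(config$width_ranges, `[`, integer(1), 1L))
  n_events <- stats::rpois(1L, config$event_rate * nt / 1000)
  if (n_events > 0L && (nt < min_dur || nl < min_wid))
    stop("grid too small for the smallest configured event", call. = FALSE)
  reg <- vector("list", n_events)
  id <- 0L
  for (k in seq_len(n_events)) {
    cls <- sample(names(config$class_probs), 1L, prob = config$class_probs)
    placed <- FALSE
    for (try in seq_len(50L)) {
      tmpl <- sample_event_template(cls, config)
      if (tmpl$duration > nt || tmpl$max_width > nl) next
      start <- sample.int(nt - tmpl$duration + 1L, 1L)
      half <- (tmpl$max_width - 1L) %/% 2L
      centre <- sample(seq.int(1L + half, nl - (tmpl$max_width - 1L - half)), 1L)
      px <- template_pixels(tmpl, start, centre)
      idx <- cbind(px$t, px$loc)
      if (!config$allow_overlap &&
          bbox_occupied(mask, range(px$t), range(px$loc),
                        config$placement_margin %||% 0L)) next
      id <- id + 1L
      mask[idx] <- id
      mu <- interp_age(config[[paste0("class_", cls, "_start")]][1],
                       config[[paste0("class_", cls, "_end")]][1],
                       px$age, tmpl$duration)
      sg <- interp_age(config[[paste0("class_", cls, "_start")]][2],
                       config[[paste0("class_", cls, "_end")]][2],
                       px$age, tmpl$duration)
      values[idx] <- stats::rnorm(nrow(idx), mu, sg)
      reg[[id]] <- tibble::tibble(event_id = id, class = cls,
                                  shape_id = tmpl$shape_id,
                                  start_time = start,
                                  duration = tmpl$duration,
                                  max_width = tmpl$max_width,
                                  centre_loc = centre)
      placed <- TRUE
      break
    }
    if (!placed && !config$allow_overlap) next  # crowded grid: drop the event
  }
  registry <- if (id > 0L) dplyr::bind_rows(reg[seq_len(id)]) else
    tibble::tibble(event_id = integer(), class = character(),
                   shape_id = integer(), start_time = integer(),
                   duration = integer(), max_width = integer(),
                   centre_loc = integer())
  new_labeled_stream(values, mask, registry, config)
}

interp_age <- function(from, to, age, duration) {
  frac <- if (duration > 1L) age / (duration - 1) else 1
  from + (to - from) * frac
}

# all pixels of a template placed at (start, centre): tibble t, loc, age
template_pixels <- function(tmpl, start, centre) {
  ages <- seq_len(tmpl$duration) - 1L
  n_per <- lengths(tmpl$footprint)
  tibble::tibble(t = rep(start + ages, n_per),
                 loc = centre + unlist(tmpl$footprint, use.names = FALSE),
                 age = rep(ages, n_per))
}

new_labeled_stream <- function(values, mask, registry, config,
                               dims = "2d", coords = NULL) {
  structure(list(values = values, truth_mask = mask, registry = registry,
                 config = config, dims = dims, coords = coords),
            class = "labeled_stream")
}

#' @export
print.labeled_stream <- function(x, ...) {
  if (x$dims == "2d") {
    cat("<labeled_stream> ", nrow(x$values), " time steps x ",
        ncol(x$values), " locations, ", nrow(x$registry), " events\n",
        sep = "")
  } else {
    d <- dim(x$values)
    cat("<labeled_stream 3d> ", d[1], " x ", d[2], " x ", d[3], ", ",
        nrow(x$registry), " events\n", sep = "")
  }
  invisible(x)
}

#' Generate a labelled three-dimensional stream
#'
#' Minimal 3D analogue of [generate_stream()] for streams with one time and
#' two spatial dimensions. Events are contiguous blobs whose square spatial
#' cross-section widens linearly with age (the 3D counterpart of the 2D
#' wedge); pixel intensities ramp between the class start and end
#' distributions exactly as in 2D.
#'
#' @param config A [stream_config()]; `n_loc` is used for both spatial axes.
#' @param n_loc2 Size of the second spatial axis (defaults to `config$n_loc`).
#' @return A `labeled_stream` whose `values` and `truth_mask` are 3D arrays
#'   `(t, x, y)`.
#' @export
generate_stream_3d <- function(config = stream_config(), n_loc2 = NULL) {
  validate_stream_config(config)
  run <- function() generate_stream_3d_impl(config, n_loc2)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

generate_stream_3d_impl <- function(config, n_loc2) {
  nt <- config$n_time; nx <- config$n_loc
  ny <- if (is.null(n_loc2)) nx else as.integer(n_loc2)
  values <- array(stats::rnorm(nt * nx * ny, config$background[1],
                               config$background[2]), dim = c(nt, nx, ny))
  mask <- array(0L, dim = c(nt, nx, ny))
  n_events <- stats::rpois(1L, config$event_rate * nt / 1000)
  reg <- vector("list", n_events)
  id <- 0L
  for (k in seq_len(n_events)) {
    cls <- sample(names(config$class_probs), 1L, prob = config$class_probs)
    for (try in seq_len(50L)) {
      key <- "shape1"
      dr <- config$duration_ranges[[key]]; wr <- config$width_ranges[[key]]
      duration <- sample(seq.int(dr[1], dr[2]), 1L)
      max_w <- sample(seq.int(wr[1], wr[2]), 1L)
      if (duration > nt || max_w > min(nx, ny)) break
      start <- sample.int(nt - duration + 1L, 1L)
      half <- (max_w - 1L) %/% 2L
      cx <- sample(seq.int(1L + half, nx - (max_w - 1L - half)), 1L)
      cy <- sample(seq.int(1L + half, ny - (max_w - 1L - half)), 1L)
      px <- blob_pixels_3d(duration, max_w, start, cx, cy)
      idx <- cbind(px$t, px$x, px$y)
      if (!config$allow_overlap &&
          bbox_occupied_3d(mask, range(px$t), range(px$x), range(px$y),
                           config$placement_margin %||% 0L)) next
      id <- id + 1L
      mask[idx] <- id
      mu <- interp_age(config[[paste0("class_", cls, "_start")]][1],
                       config[[paste0("class_", cls, "_end")]][1],
                       px$age, duration)
      sg <- interp_age(config[[paste0("class_", cls, "_start")]][2],
                       config[[paste0("class_", cls, "_end")]][2],
                       px$age, duration)
      values[idx] <- stats::rnorm(nrow(idx), mu, sg)
      reg[[id]] <- tibble::tibble(event_id = id, class = cls, shape_id = 1L,
                                  start_time = start, duration = duration,
                                  max_width = max_w, centre_loc = cx,
                                  centre_loc2 = cy)
      break
    }
  }
  registry <- if (id > 0L) dplyr::bind_rows(reg[seq_len(id)]) else
    tibble::tibble(event_id = integer(), class = character(),
                   shape_id = integer(), start_time = integer(),
                   duration = integer(), max_width = integer(),
                   centre_loc = integer(), centre_loc2 = integer())
  new_labeled_stream(values, mask, registry, config, dims = "3d")
}

blob_pixels_3d <- function(duration, max_w, start, cx, cy) {
  out <- vector("list", duration)
  for (a in seq_len(duration) - 1L) {
    w <- shape_width(1L, a, duration, max_w)
    half <- (w - 1L) %/% 2L
    off <- seq.int(-half, -half + w - 1L)
    g <- expand.grid(dx = off, dy = off)
    out[[a + 1L]] <- tibble::tibble(t = start + a, x = cx + g$dx,
                                    y = cy + g$dy, age = a)
  }
  dplyr::bind_rows(out)
}

#' Plant a constant-value cuboid event in a noise stream
#'
#' Utility for constructing fully controlled 3D fixtures: a single cuboid of
#' constant value embedded in N(0, 1) noise, with a matching truth mask and
#' registry.
#'
#' @param dim Length-3 integer dimensions `(t, x, y)`.
#' @param t_range,x_range,y_range Inclusive index ranges of the cuboid.
#' @param value Constant value of the cuboid pixels.
#' @param seed Optional seed for the background noise.
#' @return A 3D `labeled_stream`.
#' @export
plant_cuboid_stream <- function(dim, t_range, x_range, y_range, value = 10,
                                seed = NULL) {
  run <- function() {
    values <- array(stats::rnorm(prod(dim)), dim = dim)
    mask <- array(0L, dim = dim)
    ti <- seq.int(t_range[1], t_range[2])
    xi <- seq.int(x_range[1], x_range[2])
    yi <- seq.int(y_range[1], y_range[2])
    values[ti, xi, yi] <- value
    mask[ti, xi, yi] <- 1L
    registry <- tibble::tibble(event_id = 1L, class = "A", shape_id = 1L,
                               start_time = t_range[1],
                               duration = length(ti),
                               max_width = length(xi),
                               centre_loc = as.integer(round(mean(xi))),
                               centre_loc2 = as.integer(round(mean(yi))))
    new_labeled_stream(values, mask, registry, NULL, dims = "3d")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# any nonzero mask entry inside the margin-expanded bounding box?
bbox_occupied <- function(mask, tr, lr, margin) {
  ti <- max(1L, tr[1] - margin):min(nrow(mask), tr[2] + margin)
  li <- max(1L, lr[1] - margin):min(ncol(mask), lr[2] + margin)
  any(mask[ti, li] != 0L)
}

bbox_occupied_3d <- function(mask, tr, xr, yr, margin) {
  d <- dim(mask)
  ti <- max(1L, tr[1] - margin):min(d[1], tr[2] + margin)
  xi <- max(1L, xr[1] - margin):min(d[2], xr[2] + margin)
  yi <- max(1L, yr[1] - margin):min(d[3], yr[2] + margin)
  any(mask[ti, xi, yi] != 0L)
}
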