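#' Experiment configuration
#'
#' Assembles every knob of the end-to-end synthetic classification study:
#' stream size and generator settings, the train/test time split, the moving
#' window, the snapshot ages (by default the first four multiples of the
#' window step), extraction parameters, the feature preset and the
#' classifier penalty. The defaults reproduce the package's reference
#' synthetic study: a 3500 x 250 stream, 80/20 time split, window 200
#' stepping by 8, ages 8/16/24/32, default extraction parameters and
#' `lambda = 0.05`.
#'
#' @param n_time,n_loc Stream dimensions.
#' @param train_frac Fraction of stream time used for training.
#' @param window_width,step Moving-window geometry.
#' @param warmup_width Initial scan window width; the window grows from this
#'   width to `window_width` before sliding, so events near the start of the
#'   stream get meaningful first-detection times.
#' @param ages Snapshot ages; default `step * 1:4`.
#' @param params [extraction_params()].
#' @param preset,squares Passed to [feature_config()].
#' @param lambda Connected-classifier penalty.
#' @param n_rep Number of repetitions (distinct generator seeds).
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @param stream_config Optional [stream_config()] template overriding the
#'   generator defaults (its size and seed are still set per repetition).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_time = 3500L, n_loc = 250L,
                              train_frac = 0.8,
                              window_width = 200L, step = 8L,
                              warmup_width = 15L,
                              ages = NULL,
                              params = extraction_params(),
                              preset = "synthetic", squares = TRUE,
                              lambda = 0.05, n_rep = 5L, seed = 1L,
                              stream_config = NULL) {
  if (is.null(ages)) ages <- step * seq_len(4L)
  stopifnot(train_frac > 0, train_frac < 1, window_width <= n_time)
  structure(list(n_time = as.integer(n_time), n_loc = as.integer(n_loc),
                 train_frac = train_frac,
                 window_width = as.integer(window_width),
                 warmup_width = as.integer(warmup_width),
                 step = as.integer(step), ages = as.integer(ages),
                 params = params, preset = preset, squares = squares,
                 lambda = lambda, n_rep = as.integer(n_rep),
                 seed = as.integer(seed), stream_config = stream_config),
            class = "experiment_config")
}

#' Run the end-to-end classification experiment
#'
#' For each repetition: generate a labelled stream; scan it with the moving
#' window, tracking each event's first detection time; label the detected
#' events from the truth mask; build partial-observation tables at the
#' configured ages, assigning events to the training or test side by their
#' detected start time against the train-fraction boundary; fit the
#' connected classifier, the independent per-age baseline and the pooled
#' baseline on the training table; and score all three on the test table
#' per age. Repetitions use distinct seeds derived from the base seed.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress to standard error.
#' @return A list of class `experiment_report`: `metrics` (tibble with one
#'   row per repetition, classifier and age), `summary` (mean and sd of
#'   accuracy per classifier and age over repetitions), per-repetition event
#'   counts, and the config with seeds for provenance.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  all_metrics <- list()
  counts <- list()
  for (rep in seq_len(config$n_rep)) {
    rep_seed <- config$seed + rep
    say("repetition ", rep, " (seed ", rep_seed, ")")
    scfg <- config$stream_config %||% stream_config()
    scfg$n_time <- config$n_time
    scfg$n_loc <- config$n_loc
    scfg$seed <- rep_seed
    stream <- generate_stream(scfg)
    t0 <- Sys.time()
    scan <- stream_scan(stream$values, window_width = config$window_width,
                        step = config$step, params = config$params,
                        warmup_width = config$warmup_width)
    say("  scan: ", nrow(scan$info), " events in ",
        round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s")
    scan <- label_events(scan, stream)
    labelled <- scan$info[!is.na(scan$info$label), , drop = FALSE]
    boundary <- floor(config$train_frac * config$n_time)
    train_ids <- labelled$event_id[labelled$detected_start <= boundary]
    test_ids <- setdiff(labelled$event_id, train_ids)
    counts[[rep]] <- tibble::tibble(rep = rep, n_detected = nrow(scan$info),
                                    n_labelled = nrow(labelled),
                                    n_train = length(train_ids),
                                    n_test = length(test_ids))
    if (length(train_ids) == 0L || length(test_ids) == 0L) {
      say("  no events on one side of the split; skipping repetition")
      next
    }
    cfg_feat <- feature_config(preset = config$preset,
                               squares = config$squares)
    subset_events <- function(ids) {
      ev <- scan
      ev$pixels <- ev$pixels[ev$pixels$event_id %in% ids, , drop = FALSE]
      ev$info <- ev$info[ev$info$event_id %in% ids, , drop = FALSE]
      ev
    }
    train_tbl <- build_observation_table(
      subset_events(train_ids), stream$values, config$ages, cfg_feat,
      window_width = config$window_width)
    test_tbl <- build_observation_table(
      subset_events(test_ids), stream$values, config$ages, cfg_feat,
      window_width = config$window_width)
    if (nrow(train_tbl) == 0L || nrow(test_tbl) == 0L) {
      say("  empty observation table; skipping repetition")
      next
    }
    train_ages <- sort(unique(train_tbl$age))
    test_tbl <- test_tbl[test_tbl$age %in% train_ages, , drop = FALSE]
    if (nrow(test_tbl) == 0L) next
    models <- list(
      cc = fit_cc(train_tbl, lambda = config$lambda, ages = train_ages),
      nlog = fit_independent(train_tbl, ages = train_ages),
      onelog = fit_single(train_tbl))
    for (nm in names(models)) {
      preds <- test_tbl[c("event_id", "age", "label")]
      preds$prob <- suppressWarnings(
        as.numeric(predict(models[[nm]], test_tbl)))
      rep_metrics <- metric_report(preds)
      rep_metrics$classifier <- nm
      rep_metrics$rep <- rep
      all_metrics[[length(all_metrics) + 1L]] <- rep_metrics
    }
  }
  metrics <- if (length(all_metrics) > 0L) dplyr::bind_rows(all_metrics)
  else tibble::tibble(age = integer(), n = integer(), accuracy = numeric(),
                      classifier = character(), rep = integer())
  summary <- metrics |>
    dplyr::group_by(.data$classifier, .data$age) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_rep = dplyr::n(), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 counts = dplyr::bind_rows(counts), config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", x$config$n_rep, " repetitions, ",
      x$config$n_time, " x ", x$config$n_loc, " streams\n", sep = "")
  if (nrow(x$summary) > 0L) {
    tbl <- x$summary |>
      tidyr::pivot_wider(id_cols = "classifier", names_from = "age",
                         values_from = "mean_accuracy",
                         names_prefix = "t=")
    print(as.data.frame(tbl), row.names = FALSE, digits = 3)
  } else cat("  (no events classified)\n")
  invisible(x)
}
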