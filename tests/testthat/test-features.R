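test_that("background smoothers recover constant and smooth location profiles", {
  bg <- fit_background(matrix(3, 40, 60), head_len = 10L)
  p <- predict(bg, 1:60)
  expect_true(all(abs(p$mean - 3) < 1e-8))
  expect_true(all(abs(p$median - 3) < 1e-8))
  expect_true(all(p$iqr < 1e-8))
  expect_true(all(p$sd < 1e-8))

  withr::with_seed(31, {
    n_loc <- 120L
    truth <- sin(seq_len(n_loc) / 20)
    win <- matrix(rnorm(60L * n_loc, sd = 0.2), 60L, n_loc) +
      matrix(truth, 60L, n_loc, byrow = TRUE)
    bg2 <- fit_background(win, head_len = 60L)
    interior <- 5:(n_loc - 5L)
    p2 <- predict(bg2, interior)
    expect_lt(max(abs(p2$mean - truth[interior])), 0.1)
  })

  expect_warning(bg3 <- fit_background(matrix(rnorm(200), 10, 20),
                                       head_len = 50L), "clipped")
  expect_identical(bg3$head_len, 10L)
})

test_that("event snapshots cut exactly at the requested age", {
  px <- tibble::tibble(t = c(5L, 5L, 6L, 7L, 7L),
                       loc = c(1L, 2L, 1L, 1L, 3L),
                       value = 1:5 / 2)
  expect_identical(event_snapshot(px, 1L), px[px$t == 5L, ])
  expect_identical(event_snapshot(px, 2L), px[px$t <= 6L, ])
  expect_identical(event_snapshot(px, 3L), px)
  expect_identical(event_snapshot(px, 99L), px)
})

test_that("hand-built event features match closed-form values", {
  px <- rect_event_pixels()
  f <- compute_features(px, cfg = feature_config("no_background"))
  expect_equal(f$n_pixels, 6)
  expect_equal(f$length, 3)
  expect_equal(f$width, 2)
  expect_equal(f$lw_ratio, 1.5)
  expect_equal(f$value_sum, 21)
  expect_equal(f$value_mean, 3.5)
  # least-squares line through per-time means (2, 3.5, 5)
  ref <- lm(c(2, 3.5, 5) ~ c(0, 1, 2))
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  ref2 <- lm(c(2, 3.5, 5) ~ poly(0:2, 2, raw = TRUE))
  expect_equal(f$parab_lin, unname(coef(ref2)[2]), tolerance = 1e-10)
  expect_equal(f$parab_quad, unname(coef(ref2)[3]), tolerance = 1e-10)

  single <- tibble::tibble(t = 4L, loc = 9L, value = 2.5)
  fs <- compute_features(single, cfg = feature_config("no_background"))
  expect_equal(fs$n_pixels, 1)
  expect_equal(fs$length, 1)
  expect_equal(fs$width, 1)
  expect_equal(fs$lw_ratio, 1)
  expect_equal(fs$value_sd, 0)
  expect_equal(fs$slope, 0)
  expect_equal(fs$parab_lin, 0)
})

test_that("global exceedance proportions agree with a counting oracle", {
  withr::with_seed(32, {
    win <- matrix(rnorm(2000), 50, 40)
    px <- tibble::tibble(t = sample(1:50, 30, TRUE),
                         loc = sample(1:40, 30, TRUE),
                         value = rnorm(30, 2))
    f <- compute_features(px, window = win,
                          cfg = feature_config("no_background"))
    for (n in 2:4) {
      oracle <- sum(px$value > mean(win) + n * sd(win)) / nrow(px)
      expect_equal(f[[paste0("prop_gsd_", n)]], oracle)
    }
  })
})

test_that("squared copies equal squares and features ignore pixel order", {
  px <- rect_event_pixels()
  cfg <- feature_config("no_background", squares = TRUE)
  f <- compute_features(px, cfg = cfg)
  for (nm in grep("_sq$", names(f), value = TRUE))
    expect_equal(f[[nm]], f[[sub("_sq$", "", nm)]]^2)
  shuf <- px[sample(nrow(px)), ]
  expect_equal(compute_features(shuf, cfg = cfg), f)
})

test_that("snapshot features grow monotonically with age", {
  cfg <- stream_config(n_time = 200L, n_loc = 80L, seed = 33L)
  s <- generate_stream(cfg)
  ev <- extract_events(s$values)
  fcfg <- feature_config("no_background")
  for (eid in ev$info$event_id) {
    px <- ev$pixels[ev$pixels$event_id == eid, ]
    dur <- diff(range(px$t)) + 1L
    agegrid <- unique(pmin(c(2L, 5L, 10L, dur), dur))
    fs <- lapply(agegrid, function(a)
      compute_features(event_snapshot(px, a), cfg = fcfg))
    for (nm in c("n_pixels", "length", "value_sum")) {
      vals <- vapply(fs, function(f) f[[nm]], numeric(1))
      expect_true(all(diff(vals) >= 0))
    }
    # a snapshot at or past the duration is the complete event
    expect_equal(fs[[length(fs)]],
                 compute_features(px, cfg = fcfg))
  }
})

test_that("observation tables follow the age <= duration rule", {
  empty <- structure(list(pixels = tibble::tibble(), info = tibble::tibble()),
                     class = "event_set")
  expect_identical(nrow(build_observation_table(empty, matrix(0, 2, 2),
                                                c(8L, 16L))), 0L)

  mk_px <- function(id, start, dur) {
    tibble::tibble(event_id = id, t = seq.int(start, start + dur - 1L),
                   loc = 5L, value = 1)
  }
  px <- dplyr::bind_rows(mk_px(1L, 1L, 10L), mk_px(2L, 30L, 20L),
                         mk_px(3L, 80L, 35L))
  info <- tibble::tibble(event_id = 1:3,
                         n_pixels = c(10L, 20L, 35L),
                         label = c(1L, 0L, 1L))
  events <- structure(list(pixels = px, info = info), class = "event_set")
  X <- matrix(0.1, 130, 10)
  tbl <- build_observation_table(events, X, c(8L, 16L, 24L, 32L),
                                 feature_config("no_background"))
  expect_identical(as.integer(table(tbl$age)), c(3L, 2L, 1L, 1L))
  expect_identical(tbl$label[tbl$event_id == 2L], c(0L, 0L))
})

test_that("per-age standardization yields mean zero and unit variance", {
  tbl <- simulated_obs_table(N = 40L)
  ages <- sort(unique(tbl$age))
  const <- ccstream:::std_constants(tbl, ages, c("f1", "f2"))
  std <- ccstream:::apply_standardization(tbl, ages, const)
  for (a in ages) {
    sub <- std[std$age == a, ]
    expect_lt(max(abs(colMeans(sub[c("f1", "f2")]))), 1e-12)
    expect_equal(unname(vapply(sub[c("f1", "f2")], sd, numeric(1))),
                 c(1, 1), tolerance = 1e-12)
  }
})
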