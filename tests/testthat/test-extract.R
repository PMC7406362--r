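test_that("thresholding keeps exactly the strict exceedances of the quantile", {
  expect_identical(nrow(threshold_pixels(matrix(3, 5, 5))$S), 0L)

  withr::with_seed(21, {
    X <- matrix(sample(seq(1, 1000, length.out = 100)), 10, 10)
    th <- threshold_pixels(X, 0.95)
    expect_identical(nrow(th$S), 5L)
    expect_identical(sort(X[th$S]), sort(X)[96:100])
    expect_equal(th$q, quantile(X, 0.95, names = FALSE))
    # alpha near 0 keeps everything except the minimum
    th0 <- threshold_pixels(X, 1e-6)
    expect_identical(nrow(th0$S), 99L)
  })

  # monotonicity: raising alpha never adds pixels
  withr::with_seed(22, {
    X <- matrix(rnorm(400), 20, 20)
    sizes <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                    function(a) nrow(threshold_pixels(X, a)$S), integer(1))
    expect_true(all(diff(sizes) <= 0L))
  })
})

test_that("density clustering matches the reachability-closure oracle", {
  expect_identical(density_cluster(matrix(numeric(0), 0, 2), 5, 10),
                   integer(0))
  expect_identical(density_cluster(matrix(c(3L, 7L), 1, 2), 5, 2), 0L)

  # two well-separated blobs form exactly two clusters
  withr::with_seed(23, {
    blob <- function(cx, cy) cbind(cx + sample(0:5, 30, TRUE),
                                   cy + sample(0:5, 30, TRUE))
    S <- unique(rbind(blob(0, 0), blob(100, 100)))
    lab <- density_cluster(S, eps = 5, min_pts = 10)
    expect_identical(sort(unique(lab[lab > 0])), c(1L, 2L))
    expect_identical(lab, density_cluster_bruteforce(S, 5, 10))
  })

  withr::with_seed(24, {
    for (i in 1:25) {
      S <- unique(matrix(sample(1:35, 90, TRUE), ncol = 2))
      for (mp in c(2L, 5L, 10L))
        expect_identical(density_cluster(S, 5, mp),
                         density_cluster_bruteforce(S, 5, mp))
    }
  })
})

test_that("candidate filtering keeps exactly change-point-confirmed clusters", {
  S <- rbind(cbind(10:20, 5L),      # cluster 1: rows 10..20
             cbind(40:50, 5L),      # cluster 2: rows 40..50
             cbind(70:80, 5L))      # cluster 3: rows 70..80
  labels <- rep(1:3, each = 11L)
  expect_identical(filter_candidates(S, labels, list(integer(0), integer(0))),
                   integer(33))
  out <- filter_candidates(S, labels, list(15L, integer(0)))
  expect_identical(unique(out[1:11]), 1L)
  expect_identical(unique(out[12:33]), 0L)
  # two of three clusters touch change points; verify with a per-pixel scan
  cps <- list(c(15L, 45L), integer(0))
  out2 <- filter_candidates(S, labels, cps)
  manual_keep <- vapply(1:3, function(k) {
    any(S[labels == k, 1L] %in% cps[[1L]])
  }, logical(1))
  expect_identical(sort(unique(out2[out2 > 0L])),
                   seq_len(sum(manual_keep)))
  expect_identical(out2 > 0L, labels %in% which(manual_keep))
  # noise pixels are always dropped
  expect_identical(filter_candidates(S, integer(33), cps), integer(33))
})

test_that("end-to-end extraction recovers a planted event and respects negation", {
  w <- capture_warnings(ev0 <- extract_events(matrix(1, 30, 30)))
  expect_true(all(grepl("zero variance", w)))
  expect_identical(nrow(ev0$info), 0L)

  s <- planted_block_stream()
  ev <- extract_events(s$values)
  expect_identical(nrow(ev$info), 1L)
  j <- jaccard_index(s$truth_mask, event_mask(ev, dim(s$values)))$j
  expect_gte(j, 0.8)
  # every extracted pixel is above the threshold, clusters satisfy min_pts
  expect_true(all(ev$pixels$value > ev$q))
  expect_true(all(ev$info$n_pixels >= 10L))

  ev_neg <- extract_events(-s$values,
                           extraction_params(low_value_mode = TRUE))
  expect_equal(ev$pixels$t, ev_neg$pixels$t)
  expect_equal(ev$pixels$loc, ev_neg$pixels$loc)
  expect_equal(ev_neg$pixels$value, -ev$pixels$value)
})

test_that("the Jaccard index follows the TP/(TP+FN+FP) definition", {
  actual <- matrix(0L, 3, 3); detected <- matrix(0L, 3, 3)
  actual[c(1, 2, 3, 4)] <- 1L      # 4 actual pixels
  detected[c(2, 3, 4, 5)] <- 1L    # 3 shared, 1 detected-only
  r <- jaccard_index(actual, detected)
  expect_identical(c(r$tp, r$fn, r$fp), c(3L, 1L, 1L))
  expect_equal(r$j, 0.6)
  expect_equal(jaccard_index(actual, actual)$j, 1)
  other <- matrix(0L, 3, 3); other[c(8, 9)] <- 1L
  expect_equal(jaccard_index(actual, other)$j, 0)
  expect_equal(jaccard_index(matrix(0L, 2, 2), matrix(0L, 2, 2))$j, 1)
  expect_error(jaccard_index(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
})

test_that("parameter tuning maximizes the Jaccard index over the grid", {
  s <- planted_block_stream()
  one <- tune_parameters(s, 0.9, 4, 8)
  expect_equal(one$best$alpha, 0.9)
  expect_identical(nrow(one$table), 1L)

  tuned <- tune_parameters(s, c(0.5, 0.95), c(5), c(10))
  expect_equal(tuned$best$alpha, 0.95)
  expect_equal(max(tuned$table$j),
               tuned$table$j[tuned$table$alpha == tuned$best$alpha &
                               tuned$table$eps == tuned$best$eps &
                               tuned$table$min_pts == tuned$best$min_pts])
  expect_error(tune_parameters(s, numeric(0), 5, 10), "nonempty")
})

test_that("the stream scanner finds events shortly after they start", {
  z <- matrix(0, 120, 40)
  sc0 <- stream_scan(z, window_width = 30L, step = 5L)
  expect_identical(nrow(sc0$info), 0L)

  s <- planted_block_stream(n_time = 120L, n_loc = 40L,
                            t_range = c(50L, 65L), loc_range = c(10L, 19L),
                            seed = 25L)
  sc <- stream_scan(s$values, window_width = 50L, step = 1L,
                    warmup_width = 15L)
  expect_gte(nrow(sc$info), 1L)
  dd <- detection_delays(sc, s)
  expect_true(dd$first_detection_time[1] >= 50L &&
                dd$first_detection_time[1] <= 57L)

  # a step spanning the whole stream degenerates to one full extraction
  sc1 <- stream_scan(s$values, window_width = nrow(s$values),
                     step = nrow(s$values))
  ev <- extract_events(s$values)
  expect_equal(sc1$pixels[c("t", "loc")], ev$pixels[c("t", "loc")])
  expect_error(stream_scan(s$values, 50L, warmup_width = 60L), "warmup")
})

test_that("detection delays are measured against the truth registry", {
  s <- planted_block_stream(n_time = 100L, n_loc = 40L,
                            t_range = c(40L, 55L), loc_range = c(10L, 19L),
                            seed = 26L)
  # hand-made detection exactly at the true start
  det <- extract_events(s$values)
  det$info$first_detection_time <- 40L
  dd <- detection_delays(det, s)
  expect_identical(dd$delay, 0L)
  # overlap-matched events cannot be detected before they exist
  det2 <- stream_scan(s$values, window_width = 50L, step = 2L,
                      warmup_width = 15L)
  dd2 <- detection_delays(det2, s)
  expect_true(all(dd2$delay >= 0L, na.rm = TRUE))
})
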