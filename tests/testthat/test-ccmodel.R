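test_that("the logistic loss matches direct arithmetic and its limits", {
  expect_equal(logistic_loss(c(1, 2), 1, c(0, 0, 0)), log(2))
  expect_equal(logistic_loss(c(1, 2), 0, c(0, 0, 0)), log(2))
  expect_equal(logistic_loss(1, 1, c(0.5, 0.5)), -1 + log(1 + exp(1)),
               tolerance = 1e-12)
  # limits: a huge correct score drives the loss to 0, a wrong one to ~score
  expect_lt(logistic_loss(1, 1, c(500, 500)), 1e-10)
  expect_gt(logistic_loss(1, 0, c(500, 500)), 500)
  expect_error(logistic_loss(c(1, 2), 1, c(0, 0)), "length")
})

test_that("the objective decomposition matches a pencil-and-paper expansion", {
  tbl <- tibble::tibble(event_id = 1:2, age = c(8L, 16L),
                        label = c(1L, 0L), f1 = c(0.5, -1))
  B <- rbind(c(0.2, 0.4), c(-0.1, 0.3))
  lam <- 0.7
  eta1 <- 0.2 + 0.4 * 0.5
  eta2 <- -0.1 + 0.3 * (-1)
  hand_data <- mean(c(log(1 + exp(eta1)) - eta1, log(1 + exp(eta2))))
  hand_pen <- lam * ((-0.1 - 0.2)^2 + (0.3 - 0.4)^2)
  dec <- cc_objective(B, tbl, lam)
  expect_equal(dec$data_term, hand_data, tolerance = 1e-12)
  expect_equal(dec$penalty_term, hand_pen, tolerance = 1e-12)
  expect_equal(dec$total, hand_data + hand_pen, tolerance = 1e-12)

  expect_equal(cc_objective(B, tbl, 0)$penalty_term, 0)
  Beq <- rbind(c(0.2, 0.4), c(0.2, 0.4))
  expect_equal(cc_objective(Beq, tbl, 5)$penalty_term, 0)
})

test_that("the analytic gradient agrees with central differences", {
  tbl <- simulated_obs_table(N = 60L)
  withr::with_seed(41, {
    for (rep in 1:20) {
      B <- matrix(rnorm(12, sd = 0.5), 4, 3)
      lam <- runif(1, 0, 2)
      g <- cc_gradient(B, tbl, lam)
      num <- B * 0
      h <- 1e-6
      for (i in seq_along(B)) {
        Bp <- B; Bm <- B
        Bp[i] <- B[i] + h; Bm[i] <- B[i] - h
        num[i] <- (cc_objective(Bp, tbl, lam)$total -
                     cc_objective(Bm, tbl, lam)$total) / (2 * h)
      }
      expect_lt(max(abs(g - num) / (abs(num) + 1e-8)), 1e-5)
    }
  })
  # identical rows: the penalty contributes nothing to the gradient
  Beq <- matrix(rep(c(0.3, -0.2, 0.1), each = 4), 4, 3)
  expect_equal(cc_gradient(Beq, tbl, 3), cc_gradient(Beq, tbl, 0))
})

test_that("the penalty interpolates between independent and shared fits", {
  tbl <- simulated_obs_table(N = 150L)
  m0 <- fit_cc(tbl, lambda = 0)
  mi <- fit_independent(tbl)
  expect_lt(max(abs(m0$coeff - mi$coeff)), 1e-4)

  mb <- fit_cc(tbl, lambda = 1e6)
  expect_lt(max(abs(diff(mb$coeff))), 1e-3)

  # the fitted objective can never exceed the zero-coefficient baseline
  expect_lte(as.numeric(m0$diagnostics$objective), log(2))

  # stationarity at the optimum
  std <- ccstream:::apply_standardization(tbl, m0$ages, m0$standardization)
  g <- cc_gradient(m0$coeff, std, 0, m0$ages)
  expect_lt(max(abs(g)), 1e-6)

  # max row-to-row coefficient distance shrinks as lambda grows
  lams <- c(0, 0.05, 1, 100, 1e6)
  spread <- vapply(lams, function(l) {
    max(abs(diff(fit_cc(tbl, lambda = l)$coeff)))
  }, numeric(1))
  expect_true(all(diff(spread) <= 1e-6))
})

test_that("independent fits match the reference logistic solver", {
  tbl <- simulated_obs_table(N = 120L)
  one_age <- tbl[tbl$age == 16L, ]
  m <- fit_independent(one_age, standardize = FALSE)
  ref <- glm(label ~ f1 + f2, binomial(), data = one_age)
  expect_equal(unname(m$coeff[1, ]), unname(coef(ref)), tolerance = 1e-6)
  expect_error(fit_independent(one_age, ages = c(16L, 99L)), "stratum")
})

test_that("label swap negates the coefficients of an unpenalized fit", {
  tbl <- simulated_obs_table(N = 300L, seed = 42L)
  # balance the labels exactly by pairing each row with its mirror image
  mirror <- tbl
  mirror$label <- 1L - tbl$label
  mirror$f1 <- -tbl$f1; mirror$f2 <- -tbl$f2
  both <- dplyr::bind_rows(tbl, mirror)
  m <- fit_cc(both, lambda = 0, standardize = FALSE)
  flipped <- both
  flipped$label <- 1L - both$label
  mf <- fit_cc(flipped, lambda = 0, standardize = FALSE)
  expect_lt(max(abs(m$coeff + mf$coeff)), 1e-4)
  # symmetric data also forces the intercept to vanish
  expect_lt(max(abs(m$coeff[, 1])), 1e-4)
})

test_that("the pooled classifier matches a reference fit and handles one age", {
  tbl <- simulated_obs_table(N = 120L)
  m <- fit_single(tbl, standardize = FALSE)
  ref <- glm(label ~ f1 + f2 + age, binomial(),
             data = as.data.frame(tbl[c("label", "f1", "f2", "age")]))
  expect_equal(unname(m$coeff), unname(coef(ref)[c(1, 2, 3, 4)]),
               tolerance = 1e-6)
  p <- predict(m, tbl)
  expect_true(all(p > 0 & p < 1))

  one_age <- tbl[tbl$age == 24L, ]
  m1 <- fit_single(one_age)
  mi <- fit_independent(one_age)
  expect_equal(unname(m1$coeff[c("(Intercept)", "f1", "f2")]),
               unname(mi$coeff[1, ]), tolerance = 1e-4)
})

test_that("predictions apply the age-mapped logistic score", {
  tbl <- simulated_obs_table(N = 80L)
  m <- fit_cc(tbl, lambda = 0.05)
  m$coeff[] <- 0
  expect_equal(predict_probability(m, c(f1 = 0.3, f2 = -1), 16L), 0.5)

  # hand-set single-feature model: intercept 1, slope 2 at p = 0.5
  hand <- m
  hand$feature_names <- "f1"
  hand$coeff <- matrix(rep(c(1, 2), each = 4), 4, 2,
                       dimnames = list(m$ages, c("(Intercept)", "f1")))
  hand$standardization <- list(
    centers = matrix(0, 4, 1, dimnames = list(m$ages, "f1")),
    scales = matrix(1, 4, 1, dimnames = list(m$ages, "f1")))
  expect_equal(predict_probability(hand, c(f1 = 0.5), 8L),
               exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # negating the score reflects the probability
  hand2 <- hand
  hand2$coeff <- -hand$coeff
  expect_equal(predict_probability(hand2, c(f1 = 0.5), 8L),
               1 - exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # ages below the grid fall back to the first row with a warning
  expect_warning(p <- predict_probability(hand, c(f1 = 0.5), 2L), "grid")
  expect_equal(p, exp(2) / (1 + exp(2)), tolerance = 1e-12)
})

test_that("growing predictions equal element-wise probability calls", {
  tbl <- simulated_obs_table(N = 100L)
  m <- fit_cc(tbl, lambda = 0.05)
  snaps <- tbl[tbl$event_id == 1L, ]
  seqp <- growing_prediction(m, snaps)
  expect_identical(length(seqp), nrow(snaps))
  for (i in seq_len(nrow(snaps)))
    expect_equal(seqp[i], predict_probability(
      m, c(f1 = snaps$f1[i], f2 = snaps$f2[i]), snaps$age[i]))

  # under an identical-rows model (fitted on the raw feature scale so the
  # per-age standardization cannot reintroduce age dependence), constant
  # snapshots give a constant path
  mb <- fit_cc(tbl, lambda = 1e6, standardize = FALSE)
  const <- snaps
  const$f1 <- 0.4; const$f2 <- -0.2
  path <- growing_prediction(mb, const)
  expect_lt(diff(range(path)), 1e-3)
})

test_that("lambda selection returns the argmin of the validation curve", {
  train <- simulated_obs_table(N = 100L, seed = 43L)
  valid <- simulated_obs_table(N = 80L, seed = 44L)
  one <- select_lambda(train, valid, 0.3)
  expect_equal(one$lambda, 0.3)

  sel <- select_lambda(train, valid, c(0, 0.01, 0.1, 1))
  expect_equal(sel$curves$penalty_term[sel$curves$lambda == 0], 0)
  expect_equal(sel$lambda,
               sel$curves$lambda[which.min(sel$curves$total)])
  # independent re-evaluation of the winning curve entry
  m <- fit_cc(train, lambda = sel$lambda)
  vt <- ccstream:::apply_standardization(valid, m$ages, m$standardization)
  dec <- cc_objective(m$coeff, vt, sel$lambda, m$ages)
  expect_equal(dec$total,
               sel$curves$total[sel$curves$lambda == sel$lambda],
               tolerance = 1e-10)
  expect_error(select_lambda(train, valid, numeric(0)), "nonempty")
})

test_that("the objective is midpoint convex", {
  tbl <- simulated_obs_table(N = 50L)
  withr::with_seed(45, {
    for (i in 1:20) {
      A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
      lam <- runif(1, 0, 1)
      mid <- cc_objective((A + B) / 2, tbl, lam)$total
      ends <- (cc_objective(A, tbl, lam)$total +
                 cc_objective(B, tbl, lam)$total) / 2
      expect_lte(mid, ends + 1e-10)
    }
  })
})

test_that("fitting recovers a known age-varying logistic model", {
  gen <- function(N, seed) {
    withr::with_seed(seed, {
      ages <- c(8L, 16L, 24L, 32L)
      true_b <- cbind(intercept = seq(-0.5, 0.4, length.out = 4),
                      f1 = seq(1, 2.2, length.out = 4),
                      f2 = seq(-1.5, -0.6, length.out = 4))
      rows <- lapply(1:4, function(j) {
        x1 <- rnorm(N); x2 <- rnorm(N)
        eta <- true_b[j, 1] + true_b[j, 2] * x1 + true_b[j, 3] * x2
        tibble::tibble(event_id = seq_len(N), age = ages[j],
                       label = rbinom(N, 1, plogis(eta)), f1 = x1, f2 = x2)
      })
      list(tbl = dplyr::bind_rows(rows), truth = true_b)
    })
  }
  rmse <- vapply(c(200L, 2000L), function(N) {
    d <- gen(N, 46L)
    m <- fit_cc(d$tbl, lambda = 0.001, standardize = FALSE)
    sqrt(mean((m$coeff - d$truth)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.12)
})

test_that("degenerate age strata are handled per the identification rules", {
  tbl <- simulated_obs_table(N = 60L)
  expect_error(fit_cc(tbl, lambda = 0, ages = c(8L, 16L, 24L, 32L, 40L)),
               "unidentified")
  expect_warning(m <- fit_cc(tbl, lambda = 0.5,
                             ages = c(8L, 16L, 24L, 32L, 40L)),
                 "tied")
  # the empty age row is pulled to its neighbour by the penalty
  expect_lt(max(abs(m$coeff[5, ] - m$coeff[4, ])), 0.5)
})

test_that("models survive a JSON round-trip with identical predictions", {
  tbl <- simulated_obs_table(N = 80L)
  m <- fit_cc(tbl, lambda = 0.05)
  path <- file.path(withr::local_tempdir(), "m.json")
  write_model(m, path)
  r <- read_model(path)
  expect_equal(r$coeff, m$coeff)
  expect_equal(as.numeric(predict(r, tbl)), as.numeric(predict(m, tbl)))

  s <- fit_single(tbl)
  path2 <- file.path(withr::local_tempdir(), "s.json")
  write_model(s, path2)
  r2 <- read_model(path2)
  expect_equal(as.numeric(predict(r2, tbl)), as.numeric(predict(s, tbl)))
})

test_that("tidiers expose coefficients and fit summaries", {
  tbl <- simulated_obs_table(N = 60L)
  m <- fit_cc(tbl, lambda = 0.05)
  td <- tidy(m)
  expect_identical(nrow(td), 12L)
  expect_setequal(unique(td$term), c("(Intercept)", "f1", "f2"))
  expect_equal(td$estimate[td$age == 16 & td$term == "f1"],
               unname(m$coeff["16", "f1"]))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$lambda, 0.05)
  expect_true(gl$converged)
})
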