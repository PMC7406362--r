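#' Logistic loss of one observation
#'
#' The negative log-likelihood contribution of a single observation under a
#' logistic model: `-y * eta + log(1 + exp(eta))` with linear score
#' `eta = [1 p'] beta_row` (intercept prepended). Computed through the
#' log1p-of-exponential identity so large scores do not overflow.
#'
#' @param p Numeric feature vector (without intercept).
#' @param y Label in \{0, 1\}.
#' @param beta_row Coefficient vector of length `length(p) + 1`
#'   (intercept first).
#' @return The loss value.
#' @export
logistic_loss <- function(p, y, beta_row) {
  if (length(beta_row) != length(p) + 1L)
    stop("beta_row must have length(p) + 1 entries", call. = FALSE)
  stopifnot(y %in% c(0, 1))
  eta <- sum(c(1, p) * beta_row)
  log1pexp(eta) - y * eta
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# design pieces from an observation table: intercept-augmented matrix,
# labels, age index per row
make_design <- function(table, ages, feature_names = NULL) {
  if (nrow(table) == 0L) stop("observation table is empty", call. = FALSE)
  if (is.null(feature_names)) feature_names <- classifier_feature_names(table)
  jidx <- match(table$age, ages)
  if (anyNA(jidx))
    stop("table contains ages outside the model age grid", call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(table[feature_names]))
  list(X = X, y = as.numeric(table$label), jidx = jidx,
       feature_names = feature_names, M = nrow(table))
}

path_laplacian <- function(n) {
  if (n == 1L) return(matrix(0, 1L, 1L))
  P <- diag(c(1, rep(2, n - 2L), 1))
  for (j in seq_len(n - 1L)) { P[j, j + 1L] <- -1; P[j + 1L, j] <- -1 }
  P
}

#' Connected-classifier objective decomposition
#'
#' Evaluates the connected classifier's penalized objective at a coefficient
#' matrix: the data term is the average logistic loss over the observed
#' (event, age) pairs (which reduces to `1/(nN)` times the double sum on a
#' complete grid), and the penalty term is `lambda` times the sum of squared
#' L2 differences between consecutive age rows, intercept column included
#' unless `penalize_intercept = FALSE`. Features are used exactly as they
#' appear in `table`; standardize beforehand if desired.
#'
#' @param coeff Numeric matrix, one row per age, columns = intercept then
#'   features.
#' @param table Observation tibble with `age`, `label` and feature columns.
#' @param lambda Penalty weight, `>= 0`.
#' @param ages Age grid (defaults to the sorted ages in `table`).
#' @param penalize_intercept Include the intercept column in the penalty.
#' @return Tibble with `data_term`, `penalty_term` and `total`.
#' @export
cc_objective <- function(coeff, table, lambda, ages = NULL,
                         penalize_intercept = TRUE) {
  if (is.null(ages)) ages <- sort(unique(table$age))
  dd <- make_design(table, ages)
  eta <- rowSums(dd$X * coeff[dd$jidx, , drop = FALSE])
  data_term <- mean(log1pexp(eta) - dd$y * eta)
  pen <- cc_penalty(coeff, penalize_intercept)
  tibble::tibble(data_term = data_term, penalty_term = lambda * pen,
                 total = data_term + lambda * pen)
}

cc_penalty <- function(coeff, penalize_intercept = TRUE) {
  if (nrow(coeff) < 2L) return(0)
  D <- diff(coeff)
  if (!penalize_intercept) D <- D[, -1L, drop = FALSE]
  sum(D^2)
}

#' Gradient of the connected-classifier objective
#'
#' Exact analytic gradient of [cc_objective()] with respect to the
#' coefficient matrix. The data part is the usual logistic-regression score
#' accumulated per age row; the smoothness penalty contributes
#' `2 lambda (beta_j - beta_{j-1}) - 2 lambda (beta_{j+1} - beta_j)` to row
#' `j` (existing neighbours only).
#'
#' @inheritParams cc_objective
#' @return Matrix of the same shape as `coeff`.
#' @export
cc_gradient <- function(coeff, table, lambda, ages = NULL,
                        penalize_intercept = TRUE) {
  if (is.null(ages)) ages <- sort(unique(table$age))
  dd <- make_design(table, ages)
  eta <- rowSums(dd$X * coeff[dd$jidx, , drop = FALSE])
  r <- (stats::plogis(eta) - dd$y) / dd$M
  G <- matrix(0, nrow = nrow(coeff), ncol = ncol(coeff),
              dimnames = dimnames(coeff))
  for (j in seq_len(nrow(coeff))) {
    sel <- dd$jidx == j
    if (any(sel)) G[j, ] <- colSums(dd$X[sel, , drop = FALSE] * r[sel])
  }
  if (nrow(coeff) >= 2L && lambda > 0) {
    P <- path_laplacian(nrow(coeff))
    Gpen <- 2 * lambda * (P %*% coeff)
    if (!penalize_intercept) Gpen[, 1L] <- 0
    G <- G + Gpen
  }
  G
}

# standardization constants per age for the classifier features
std_constants <- function(table, ages, feature_names) {
  centers <- matrix(0, length(ages), length(feature_names),
                    dimnames = list(ages, feature_names))
  scales <- matrix(1, length(ages), length(feature_names),
                   dimnames = list(ages, feature_names))
  for (j in seq_along(ages)) {
    sub <- table[table$age == ages[j], feature_names, drop = FALSE]
    if (nrow(sub) == 0L) next
    mu <- vapply(sub, mean, numeric(1))
    sg <- vapply(sub, stats::sd, numeric(1))
    sg[!is.finite(sg) | sg == 0] <- 1
    centers[j, ] <- mu
    scales[j, ] <- sg
  }
  list(centers = centers, scales = scales)
}

apply_standardization <- function(table, ages, constants) {
  feature_names <- colnames(constants$centers)
  jidx <- match(table$age, ages)
  for (k in seq_along(feature_names)) {
    nm <- feature_names[k]
    table[[nm]] <- (table[[nm]] - constants$centers[jidx, k]) /
      constants$scales[jidx, k]
  }
  table
}

#' Fit the connected classifier
#'
#' Minimizes the convex penalized objective — average logistic loss over all
#' observed (event, age) pairs plus `lambda` times the sum of squared
#' differences between consecutive age rows of the coefficient matrix — by
#' damped Newton iterations from a zero start. The Hessian is the per-age
#' block-diagonal logistic curvature plus a tridiagonal-in-age penalty term,
#' so each step is a small dense solve. Features are standardized per age
#' (center/scale from the training table) before fitting; the constants are
#' stored in the model and applied at prediction time.
#'
#' With `lambda = 0` the objective separates by age and the fit coincides
#' with independent per-age logistic regressions; as `lambda` grows the rows
#' are pulled together, and in the large-`lambda` limit all ages share one
#' classifier. An age on the grid with no observations is unidentified at
#' `lambda = 0` (an error); with `lambda > 0` it is fitted tied to its
#' neighbours, with a warning.
#'
#' @param table Observation tibble (`age`, `label`, feature columns).
#' @param lambda Smoothness penalty, `>= 0`; default 0.05.
#' @param ages Age grid; defaults to the ages present in `table`.
#' @param opts List of optimizer options: `max_iter` (default 200),
#'   `grad_tol` (default 1e-8).
#' @param penalize_intercept Include the intercept in the penalty.
#' @param standardize Standardize features per age before fitting.
#' @return Object of class `cc_model`: coefficient matrix (one row per age),
#'   `lambda`, `ages`, feature names, standardization constants and fit
#'   diagnostics.
#' @export
fit_cc <- function(table, lambda = 0.05, ages = NULL, opts = list(),
                   penalize_intercept = TRUE, standardize = TRUE) {
  stopifnot(lambda >= 0)
  if (is.null(ages)) ages <- sort(unique(table$age))
  n_ages <- length(ages)
  feature_names <- classifier_feature_names(table)
  empty <- setdiff(ages, unique(table$age))
  if (length(empty) > 0L) {
    if (lambda == 0)
      stop("ages with no observations are unidentified at lambda = 0: ",
           paste(empty, collapse = ", "), call. = FALSE)
    warning("ages with no observations are fitted tied to neighbours: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  constants <- if (standardize) std_constants(table, ages, feature_names)
  else list(centers = matrix(0, n_ages, length(feature_names),
                             dimnames = list(ages, feature_names)),
            scales = matrix(1, n_ages, length(feature_names),
                            dimnames = list(ages, feature_names)))
  std_table <- apply_standardization(table, ages, constants)
  dd <- make_design(std_table, ages, feature_names)
  max_iter <- opts$max_iter %||% 200L
  grad_tol <- opts$grad_tol %||% 1e-8
  l1 <- length(feature_names) + 1L
  B <- matrix(0, n_ages, l1,
              dimnames = list(ages, c("(Intercept)", feature_names)))
  P <- path_laplacian(n_ages)
  Ipen <- diag(l1)
  if (!penalize_intercept) Ipen[1L, 1L] <- 0
  Hpen <- 2 * lambda * (P %x% Ipen)   # theta stacks rows of B
  obj <- function(B) {
    eta <- rowSums(dd$X * B[dd$jidx, , drop = FALSE])
    mean(log1pexp(eta) - dd$y * eta) +
      lambda * cc_penalty(B, penalize_intercept)
  }
  f <- obj(B)
  it <- 0L
  converged <- FALSE
  repeat {
    G <- cc_gradient(B, std_table, lambda, ages, penalize_intercept)
    gnorm <- max(abs(G))
    if (gnorm <= grad_tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    eta <- rowSums(dd$X * B[dd$jidx, , drop = FALSE])
    w <- stats::plogis(eta)
    w <- pmax(w * (1 - w), 1e-10) / dd$M
    H <- matrix(0, n_ages * l1, n_ages * l1)
    for (j in seq_len(n_ages)) {
      sel <- dd$jidx == j
      rows <- (j - 1L) * l1 + seq_len(l1)
      if (any(sel)) {
        Xj <- dd$X[sel, , drop = FALSE]
        H[rows, rows] <- crossprod(Xj, Xj * w[sel])
      }
    }
    H <- H + Hpen
    g <- as.vector(t(G))
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, nrow(H)), g))
    # backtracking line search on the convex objective
    alpha <- 1
    repeat {
      Bn <- B - alpha * matrix(step, n_ages, l1, byrow = TRUE,
                               dimnames = dimnames(B))
      fn <- obj(Bn)
      if (fn <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (abs(f - fn) < 1e-15 && alpha < 1e-8) break
    B <- Bn; f <- fn
  }
  if (!converged && lambda == 0)
    warning("optimizer hit the iteration cap (possible perfect separation)",
            call. = FALSE)
  dec <- cc_objective(B, std_table, lambda, ages, penalize_intercept)
  structure(list(coeff = B, lambda = lambda, ages = ages,
                 feature_names = feature_names,
                 standardization = constants,
                 penalize_intercept = penalize_intercept,
                 diagnostics = list(objective = dec$total,
                                    data_term = dec$data_term,
                                    penalty_term = dec$penalty_term,
                                    iterations = it,
                                    grad_norm = max(abs(cc_gradient(
                                      B, std_table, lambda, ages,
                                      penalize_intercept))),
                                    converged = converged),
                 method = "cc"),
            class = "cc_model")
}

#' @export
print.cc_model <- function(x, ...) {
  cat("<cc_model> ", length(x$ages), " ages (",
      paste(x$ages, collapse = ", "), "), ",
      length(x$feature_names), " features, lambda = ", x$lambda, "\n",
      sep = "")
  cat("  objective ", format(x$diagnostics$objective, digits = 6),
      " after ", x$diagnostics$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Independent per-age logistic fits (n-Log baseline)
#'
#' Fits one unlinked logistic regression per age stratum, the `lambda = 0`
#' limit of the connected classifier implemented as separate fits through
#' `stats::glm`. Uses the same per-age standardization as [fit_cc()], so
#' coefficients are directly comparable.
#'
#' @inheritParams fit_cc
#' @return A `cc_model` with `method = "nlog"` and `lambda = 0`.
#' @export
fit_independent <- function(table, ages = NULL, standardize = TRUE) {
  if (is.null(ages)) ages <- sort(unique(table$age))
  feature_names <- classifier_feature_names(table)
  if (length(setdiff(ages, unique(table$age))) > 0L)
    stop("every age stratum needs at least one observation", call. = FALSE)
  constants <- if (standardize) std_constants(table, ages, feature_names)
  else list(centers = matrix(0, length(ages), length(feature_names),
                             dimnames = list(ages, feature_names)),
            scales = matrix(1, length(ages), length(feature_names),
                            dimnames = list(ages, feature_names)))
  std_table <- apply_standardization(table, ages, constants)
  B <- matrix(0, length(ages), length(feature_names) + 1L,
              dimnames = list(ages, c("(Intercept)", feature_names)))
  for (j in seq_along(ages)) {
    sub <- std_table[std_table$age == ages[j], , drop = FALSE]
    dat <- as.data.frame(sub[c("label", feature_names)])
    fit <- suppressWarnings(stats::glm(
      label ~ ., family = stats::binomial(), data = dat,
      control = stats::glm.control(maxit = 100)))
    B[j, ] <- stats::coef(fit)
  }
  B[!is.finite(B)] <- 0  # aliased columns in a degenerate stratum
  dec <- cc_objective(B, std_table, 0, ages)
  structure(list(coeff = B, lambda = 0, ages = ages,
                 feature_names = feature_names,
                 standardization = constants, penalize_intercept = TRUE,
                 diagnostics = list(objective = dec$total,
                                    data_term = dec$data_term,
                                    penalty_term = 0, iterations = NA,
                                    grad_norm = NA, converged = TRUE),
                 method = "nlog"),
            class = "cc_model")
}

#' Single pooled logistic fit (1-Log baseline)
#'
#' Fits one logistic regression on all partial observations pooled across
#' ages, with the (standardized) age appended as an additional covariate
#' (disable with `use_age = FALSE` to merely pool rows). Features are
#' standardized with pooled constants.
#'
#' @inheritParams fit_cc
#' @param use_age Include age as a covariate.
#' @return Object of class `cc_pooled`.
#' @export
fit_single <- function(table, use_age = TRUE, standardize = TRUE) {
  if (nrow(table) == 0L) stop("observation table is empty", call. = FALSE)
  feature_names <- classifier_feature_names(table)
  dat <- as.data.frame(table[c("label", feature_names)])
  centers <- vapply(dat[feature_names], mean, numeric(1))
  scales <- vapply(dat[feature_names], stats::sd, numeric(1))
  scales[!is.finite(scales) | scales == 0] <- 1
  if (!standardize) { centers[] <- 0; scales[] <- 1 }
  for (nm in feature_names)
    dat[[nm]] <- (dat[[nm]] - centers[nm]) / scales[nm]
  age_center <- 0; age_scale <- 1
  if (use_age) {
    age_center <- mean(table$age)
    age_scale <- stats::sd(table$age)
    if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
    if (!standardize) { age_center <- 0; age_scale <- 1 }
    dat$age <- (table$age - age_center) / age_scale
  }
  fit <- suppressWarnings(stats::glm(
    label ~ ., family = stats::binomial(), data = dat,
    control = stats::glm.control(maxit = 100)))
  beta <- stats::coef(fit)
  beta[!is.finite(beta)] <- 0
  structure(list(coeff = beta, feature_names = feature_names,
                 use_age = use_age,
                 standardization = list(centers = centers, scales = scales,
                                        age_center = age_center,
                                        age_scale = age_scale),
                 method = "onelog"),
            class = "cc_pooled")
}

#' @export
print.cc_pooled <- function(x, ...) {
  cat("<cc_pooled> pooled logistic fit, ", length(x$feature_names),
      " features", if (x$use_age) " + age", "\n", sep = "")
  invisible(x)
}

#' Predicted class probability for one partial observation
#'
#' Applies the age-appropriate coefficient row to a feature vector and maps
#' the linear score through the logistic function. The age is mapped to the
#' nearest model age at or below it; ages below the smallest grid age use the
#' first row with a warning.
#'
#' @param model A `cc_model` or `cc_pooled`.
#' @param p Named numeric feature vector (raw scale; the model's stored
#'   standardization is applied).
#' @param age Age of the observation.
#' @return Probability in (0, 1).
#' @export
predict_probability <- function(model, p, age) {
  tbl <- tibble::as_tibble(as.list(p))
  tbl$age <- age
  tbl$label <- NA_integer_
  as.numeric(predict(model, tbl))
}

model_age_row <- function(model, age) {
  j <- findInterval(age, model$ages)
  if (any(j == 0L)) {
    warning("age below the model grid; using the first age row",
            call. = FALSE)
    j[j == 0L] <- 1L
  }
  j
}

#' @export
predict.cc_model <- function(object, newdata, type = "response", ...) {
  j <- model_age_row(object, newdata$age)
  X <- as.matrix(newdata[object$feature_names])
  Xs <- (X - object$standardization$centers[j, , drop = FALSE]) /
    object$standardization$scales[j, , drop = FALSE]
  eta <- rowSums(cbind(1, Xs) * object$coeff[j, , drop = FALSE])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
predict.cc_pooled <- function(object, newdata, type = "response", ...) {
  X <- as.matrix(newdata[object$feature_names])
  Xs <- sweep(sweep(X, 2L, object$standardization$centers), 2L,
              object$standardization$scales, `/`)
  if (object$use_age) {
    age_s <- (newdata$age - object$standardization$age_center) /
      object$standardization$age_scale
    Xs <- cbind(Xs, age = age_s)
  }
  eta <- drop(cbind(1, Xs) %*% object$coeff)
  if (type == "link") eta else stats::plogis(eta)
}

#' Growing prediction over a sequence of snapshots
#'
#' Applies the model to each snapshot of a developing event in age order,
#' returning the sequence of class probabilities that grows as the event
#' matures.
#'
#' @param model A fitted `cc_model` or `cc_pooled`.
#' @param snapshots Tibble with an `age` column and the model's feature
#'   columns, one row per snapshot, in increasing age order.
#' @return Numeric vector of probabilities, one per snapshot.
#' @export
growing_prediction <- function(model, snapshots) {
  as.numeric(predict(model, snapshots))
}

#' Select the smoothness penalty on a validation set
#'
#' Fits the connected classifier on the training table for every `lambda` in
#' the grid and evaluates the objective decomposition on the validation
#' table (standardized with the training constants): the validation data
#' term, the penalty term at the fitted coefficients, and their total.
#' Returns the `lambda` minimizing the chosen criterion together with the
#' full curves.
#'
#' @param train_table,valid_table Observation tibbles.
#' @param lambda_grid Nonempty numeric grid of penalty values.
#' @param criterion `"total"` (default) or `"data"`.
#' @param ... Passed to [fit_cc()].
#' @return List with `lambda` (the selected value) and `curves` (tibble
#'   `lambda, data_term, penalty_term, total`).
#' @export
select_lambda <- function(train_table, valid_table, lambda_grid,
                          criterion = c("total", "data"), ...) {
  criterion <- match.arg(criterion)
  if (length(lambda_grid) == 0L)
    stop("lambda grid must be nonempty", call. = FALSE)
  rows <- purrr::map(lambda_grid, function(lam) {
    m <- fit_cc(train_table, lambda = lam, ...)
    vt <- apply_standardization(valid_table, m$ages, m$standardization)
    dec <- cc_objective(m$coeff, vt, lam, m$ages, m$penalize_intercept)
    dplyr::bind_cols(tibble::tibble(lambda = lam), dec)
  })
  curves <- dplyr::bind_rows(rows)
  key <- if (criterion == "total") curves$total else curves$data_term
  list(lambda = curves$lambda[which.min(key)], curves = curves)
}
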