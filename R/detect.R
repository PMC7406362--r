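#' First principal component scores of a matrix
#'
#' Projects each observation of `M` onto the leading principal axis of the
#' column-centred data. With `axis = "rows"` each row is an observation
#' (variables in columns); with `axis = "cols"` the transpose is analysed.
#' The loading sign is fixed so that the first nonzero loading is positive,
#' making scores reproducible across eigensolvers; downstream change-point
#' detection is invariant to a global sign flip anyway.
#'
#' @param M Numeric matrix with finite entries.
#' @param axis `"rows"` or `"cols"`: which dimension holds the observations.
#' @return A list of class `score_series` with `scores` (numeric vector, one
#'   per observation), `axis`, and `zero_variance` (`TRUE` when the centred
#'   matrix has no variance, in which case scores are all zero and a warning
#'   is raised).
#' @export
first_pc_scores <- function(M, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(M))
  if (!all(is.finite(M))) stop("matrix contains non-finite values", call. = FALSE)
  X <- if (axis == "rows") M else t(M)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (max(abs(Xc)) < 1e-12) {
    warning("matrix has zero variance; returning all-zero scores",
            call. = FALSE)
    return(structure(list(scores = numeric(nrow(X)), axis = axis,
                          zero_variance = TRUE), class = "score_series"))
  }
  sv <- svd(Xc, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  nz <- which(abs(v) > 1e-12)[1L]
  if (!is.na(nz) && v[nz] < 0) v <- -v
  structure(list(scores = drop(Xc %*% v), axis = axis, zero_variance = FALSE),
            class = "score_series")
}

# Per-segment Gaussian costs from cumulative sums. `starts` are 0-based
# segment starts (segment covers starts+1 .. end); vectorized over starts.
seg_cost <- function(cs0, css0, starts, end, cost) {
  len <- end - starts
  s <- cs0[end + 1L] - cs0[starts + 1L]
  if (cost == "mean") {
    ss <- css0[end + 1L] - css0[starts + 1L]
    ss - s^2 / len
  } else {
    ss <- css0[end + 1L] - css0[starts + 1L]
    sigma2 <- pmax(ss / len - (s / len)^2, 1e-8)
    len * (log(2 * pi) + log(sigma2) + 1)
  }
}

default_penalty <- function(n) 3 * log(n)

#' Exact penalized change-point segmentation (PELT)
#'
#' Finds the segmentation of a univariate series minimizing the summed
#' per-segment cost plus a constant penalty per change point, using pruned
#' exact linear-time dynamic programming. The default cost is the Gaussian
#' likelihood for a change in mean and variance; `cost = "mean"` uses the
#' squared-error cost for a mean change only. Both costs satisfy the pruning
#' condition, so the result equals an exhaustive search.
#'
#' @param series Numeric vector, length at least 2, finite.
#' @param penalty Penalty per change point; defaults to `3 * log(n)`.
#' @param cost `"meanvar"` (default) or `"mean"`.
#' @return A list of class `changepoint_result` with `indices` (strictly
#'   increasing change-point positions; a change point at `k` ends a segment
#'   at index `k`), and `penalty_spec` recording cost and penalty.
#' @export
pelt_segment <- function(series, penalty = NULL,
                         cost = c("meanvar", "mean")) {
  cost <- match.arg(cost)
  if (!all(is.finite(series))) stop("series contains non-finite values",
                                    call. = FALSE)
  n <- length(series)
  stopifnot(n >= 2L)
  if (is.null(penalty)) penalty <- default_penalty(n)
  stopifnot(penalty >= 0)
  minseg <- if (cost == "meanvar") 2L else 1L
  cs0 <- c(0, cumsum(series))
  css0 <- c(0, cumsum(series^2))
  F <- rep(Inf, n + 1L)
  F[1L] <- -penalty
  last <- integer(n + 1L)
  cands <- 0L
  dead_at <- Inf  # time from which each candidate is dominated
  for (t in seq.int(minseg, n)) {
    ok <- cands[t - cands >= minseg & t < dead_at]
    if (length(ok) == 0L) next
    vals <- F[ok + 1L] + seg_cost(cs0, css0, ok, t, cost) + penalty
    i <- which.min(vals)
    F[t + 1L] <- vals[i]
    last[t + 1L] <- ok[i]
    # a candidate failing the K = 0 check at t is dominated by a change
    # point at t, but only from t + minseg on (before that, t itself is
    # infeasible as the most recent change point)
    fail <- F[cands + 1L] +
      seg_cost(cs0, css0, cands, t, cost) > F[t + 1L]
    dead_at[fail] <- pmin(dead_at[fail], t + minseg)
    live <- dead_at > t + 1L
    cands <- c(cands[live], t)
    dead_at <- c(dead_at[live], Inf)
  }
  cps <- integer(0)
  k <- n
  while (k > 0L) {
    p <- last[k + 1L]
    if (p > 0L) cps <- c(p, cps)
    k <- p
  }
  structure(list(indices = cps,
                 penalty_spec = list(cost = cost, penalty = penalty)),
            class = "changepoint_result")
}

#' Exhaustive optimal segmentation (test oracle)
#'
#' Enumerates every possible set of change points of a short series and
#' returns the global minimizer of the penalized cost. Exponential in the
#' series length; guarded to length 16. Serves as the independent oracle for
#' [pelt_segment()].
#'
#' @inheritParams pelt_segment
#' @return A `changepoint_result`.
#' @export
exhaustive_segment <- function(series, penalty = NULL,
                               cost = c("meanvar", "mean")) {
  cost <- match.arg(cost)
  n <- length(series)
  if (n > 16L) stop("exhaustive_segment is limited to length <= 16",
                    call. = FALSE)
  if (is.null(penalty)) penalty <- default_penalty(n)
  minseg <- if (cost == "meanvar") 2L else 1L
  cs0 <- c(0, cumsum(series))
  css0 <- c(0, cumsum(series^2))
  best <- Inf; best_cps <- integer(0)
  positions <- seq_len(n - 1L)
  for (bits in 0:(2^(n - 1L) - 1L)) {
    cps <- positions[bitwAnd(bits, 2^(positions - 1L)) > 0L]
    bounds <- c(0L, cps, n)
    lens <- diff(bounds)
    if (any(lens < minseg)) next
    tot <- penalty * length(cps)
    for (j in seq_along(lens))
      tot <- tot + seg_cost(cs0, css0, bounds[j], bounds[j + 1L], cost)
    if (tot < best - 1e-12) { best <- tot; best_cps <- cps }
  }
  structure(list(indices = best_cps,
                 penalty_spec = list(cost = cost, penalty = penalty)),
            class = "changepoint_result")
}

#' Change points of a 2D stream in both dimensions
#'
#' Computes the first principal-component score series treating rows as
#' observations and, separately, columns as observations, and segments each
#' with [pelt_segment()]. A zero-variance matrix yields empty change-point
#' sets (with a warning) so that all-background windows flow through the
#' stream scanner.
#'
#' @param X Numeric matrix (rows = first coordinate, e.g. time).
#' @param penalty,cost Passed to [pelt_segment()].
#' @return List with `C1` (change points over rows) and `C2` (over columns).
#' @export
changepoints_2d <- function(X, penalty = NULL, cost = "meanvar") {
  one <- function(axis) {
    s <- first_pc_scores(X, axis)
    if (s$zero_variance || length(s$scores) < 2L) return(integer(0))
    pelt_segment(s$scores, penalty = penalty, cost = cost)$indices
  }
  list(C1 = one("rows"), C2 = one("cols"))
}

#' Change points of a 3D stream in all three dimensions
#'
#' Averages the array over the third and then the first axis to obtain the
#' two 2D matrices `(t, x)` and `(x, y)`, and applies [changepoints_2d()] to
#' each. The shared middle dimension `x` appears in both analyses; its change
#' points are the union of the two.
#'
#' @param X Numeric 3D array `(t, x, y)`.
#' @param penalty,cost Passed to [pelt_segment()].
#' @return List with `C_t`, `C_x`, `C_y`.
#' @export
changepoints_3d <- function(X, penalty = NULL, cost = "meanvar") {
  stopifnot(length(dim(X)) == 3L)
  M_tx <- apply(X, c(1, 2), mean)
  M_xy <- apply(X, c(2, 3), mean)
  a <- changepoints_2d(M_tx, penalty = penalty, cost = cost)
  b <- changepoints_2d(M_xy, penalty = penalty, cost = cost)
  list(C_t = a$C1, C_x = sort(union(a$C2, b$C1)), C_y = b$C2)
}
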