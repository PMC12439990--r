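default_lambda_grid <- function() 10^seq(-4, 4, length.out = 25)

# Cubic B-spline knot vector for `basis_dim` basis functions on [lo, hi] with
# interior knots at weighted pseudotime quantiles.
spline_knots <- function(t, w, basis_dim) {
  lo <- min(t[w > 0]); hi <- max(t[w > 0])
  n_interior <- basis_dim - 4L
  interior <- if (n_interior > 0) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    weighted_quantile(t[w > 0], w[w > 0], probs)
  } else numeric(0)
  # guard against coincident knots on degenerate weight configurations
  interior <- pmin(pmax(interior, lo + 1e-10), hi - 1e-10)
  c(rep(lo, 4), interior, rep(hi, 4))
}

# Exact curvature penalty: integral of B_i''(t) B_j''(t) over the fitting
# range.  B'' of a cubic spline is piecewise linear, so per-interval Simpson
# quadrature is exact.  Constants and linear functions are exactly
# penalty-free on any knot layout.
curvature_penalty <- function(knots, basis_dim) {
  brk <- unique(knots)
  P <- matrix(0, basis_dim, basis_dim)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    xs <- c(a, (a + b) / 2, b)
    B2 <- splines::splineDesign(knots, xs, ord = 4L,
                                derivs = rep(2L, 3L), outer.ok = TRUE)
    P <- P + (b - a) / 6 *
      (tcrossprod(B2[1, ]) + 4 * tcrossprod(B2[2, ]) + tcrossprod(B2[3, ]))
  }
  (P + t(P)) / 2
}

#' Weighted penalized B-spline fit of a score along pseudotime
#'
#' Fits `score ~ f(pseudotime)` by penalized weighted least squares on a
#' cubic B-spline basis of dimension `basis_dim` (default 7, matching the
#' basis size used for lineage trajectory smoothing in this workflow), with
#' interior knots at weighted pseudotime quantiles and an exact
#' integrated-squared-second-derivative penalty.  The smoothing parameter is
#' selected by generalized cross-validation (GCV) over a log-spaced grid.
#' Cells with zero weight do not influence the fit and do not extend its
#' range.
#'
#' @param pseudotime,score,weights per-cell vectors; weights nonnegative.
#' @param basis_dim basis dimension (>= 4).
#' @param lambda_grid candidate smoothing parameters.
#' @return object of class `spline_fit` with `knots`, `coefficients`,
#'   `lambda`, `edf`, `gcv` (per grid point), `range`, and `weights_used`.
#'   Evaluate with [predict()][predict.spline_fit].
#' @export
fit_weighted_spline <- function(pseudotime, score, weights,
                                basis_dim = 7L,
                                lambda_grid = default_lambda_grid()) {
  stopifnot(length(pseudotime) == length(score),
            length(score) == length(weights))
  if (basis_dim < 4L) stop_config("basis_dim must be >= 4", "basis_dim")
  if (any(weights < 0)) stop_config("weights must be nonnegative", "weights")
  eff <- weights > 0
  if (!any(eff)) stop("all weights are zero; nothing to fit")
  if (sum(eff) < basis_dim + 2L)
    stop(sprintf("need at least %d cells with positive weight, have %d",
                 basis_dim + 2L, sum(eff)))
  t_e <- pseudotime[eff]; y_e <- score[eff]; w_e <- weights[eff]
  if (diff(range(t_e)) <= 0) stop("pseudotime span is degenerate")

  knots <- spline_knots(pseudotime, weights, basis_dim)
  B <- splines::splineDesign(knots, t_e, ord = 4L, outer.ok = TRUE)
  P <- curvature_penalty(knots, basis_dim)
  sw <- sqrt(w_e)
  A <- crossprod(B * sw)
  bv <- crossprod(B, w_e * y_e)
  n_eff <- length(y_e)

  best <- NULL
  gcv_tab <- data.frame(lambda = lambda_grid, gcv = NA_real_, edf = NA_real_)
  for (j in seq_along(lambda_grid)) {
    lam <- lambda_grid[j]
    M <- A + lam * P
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) next
    beta <- backsolve(ch, forwardsolve(t(ch), bv))
    fitted <- drop(B %*% beta)
    rss <- sum(w_e * (y_e - fitted)^2)
    edf <- sum(diag(chol2inv(ch) %*% A))
    gcv <- n_eff * rss / (n_eff - edf)^2
    gcv_tab$gcv[j] <- gcv; gcv_tab$edf[j] <- edf
    if (is.null(best) || gcv < best$gcv)
      best <- list(beta = beta, lambda = lam, edf = edf, gcv = gcv)
  }
  if (is.null(best)) stop("spline fit failed at every smoothing parameter")
  structure(list(
    knots = knots,
    basis_dim = as.integer(basis_dim),
    coefficients = drop(best$beta),
    lambda = best$lambda,
    edf = best$edf,
    gcv = gcv_tab,
    range = range(t_e),
    weights_used = weights
  ), class = "spline_fit")
}

#' Evaluate a fitted trajectory spline
#'
#' @param object a `spline_fit`.
#' @param newdata pseudotime values within the fitting range.
#' @param ... unused.
#' @return fitted values.
#' @export
predict.spline_fit <- function(object, newdata, ...) {
  if (any(newdata < object$range[1] - 1e-9 | newdata > object$range[2] + 1e-9))
    stop("evaluation outside the fitting range")
  x <- pmin(pmax(newdata, object$range[1]), object$range[2])
  B <- splines::splineDesign(object$knots, x, ord = 4L, outer.ok = TRUE)
  drop(B %*% object$coefficients)
}

#' @export
print.spline_fit <- function(x, ...) {
  cat("penalized B-spline fit: basis_dim =", x$basis_dim,
      "| lambda =", signif(x$lambda, 3),
      "| edf =", round(x$edf, 2), "\n")
  invisible(x)
}

#' Area under a fitted trajectory curve
#'
#' Trapezoidal integral of the fitted curve on an evenly spaced grid over
#' `range`.
#'
#' @param fit a `spline_fit`.
#' @param range integration range (within the fitting range).
#' @param grid_points number of grid points (default 200).
#' @return the AUC (a real number).
#' @export
trajectory_auc <- function(fit, range = fit$range, grid_points = 200L) {
  if (length(range) != 2L || !(range[2] > range[1]))
    stop("degenerate integration range")
  grid <- seq(range[1], range[2], length.out = grid_points)
  trapz(grid, predict(fit, grid))
}

# Fit both lineages and return their AUC difference over the shared range
# (intersection of the two lineages' pseudotime supports).
delta_auc_once <- function(pseudotime, score, w_myo, w_peri, basis_dim,
                           grid_points) {
  lo <- max(min(pseudotime[w_myo > 0]), min(pseudotime[w_peri > 0]))
  hi <- min(max(pseudotime[w_myo > 0]), max(pseudotime[w_peri > 0]))
  if (!(hi > lo)) stop("shared pseudotime range is degenerate")
  fit_myo <- fit_weighted_spline(pseudotime, score, w_myo, basis_dim)
  fit_peri <- fit_weighted_spline(pseudotime, score, w_peri, basis_dim)
  auc_myo <- trajectory_auc(fit_myo, c(lo, hi), grid_points)
  auc_peri <- trajectory_auc(fit_peri, c(lo, hi), grid_points)
  list(auc_myo = auc_myo, auc_peri = auc_peri, delta = auc_myo - auc_peri)
}

#' Permutation test for a score difference between trajectory lineages
#'
#' Fits the score against pseudotime twice -- once weighted by the
#' myofibroblast-lineage curve weights, once by the pericyte-lineage weights
#' -- and summarizes each fit by its AUC over the shared pseudotime range.
#' The observed statistic is delta-AUC = AUC(myofibroblast lineage) -
#' AUC(pericyte lineage).  The null distribution is built by independently
#' swapping each cell's weight pair with probability 1/2 and refitting both
#' curves; this preserves every cell's pseudotime and total weight and
#' destroys only the lineage-score association.  The two-sided p-value is
#' the plain proportion of permuted delta-AUC values at least as large in
#' magnitude as the observed one (it can be 0); an add-one-smoothed p is
#' reported alongside for reference.
#'
#' @param cells cell table with `pseudotime`, `weight_lineage_myo`,
#'   `weight_lineage_peri`.
#' @param score per-cell score vector aligned with `cells`.
#' @param n_perm number of permutations (>= 1; default 1000).
#' @param seed integer; permutation `i` draws from a stream derived from
#'   `(seed, i)`, so results are reproducible and order-independent.
#' @param basis_dim spline basis dimension (default 7).
#' @param grid_points AUC grid resolution.
#' @param scheme `"swap_weights"` (default, described above) or
#'   `"shuffle_score"` (permute the score vector across cells; sensitivity
#'   alternative).
#' @return object of class `delta_auc_test`: `auc_myo`, `auc_peri`,
#'   `delta_auc`, `perm_deltas`, `p_two_sided`, `p_smoothed`, `n_perm`.
#' @export
delta_auc_test <- function(cells, score, n_perm = 1000L, seed = 1L,
                           basis_dim = 7L, grid_points = 200L,
                           scheme = c("swap_weights", "shuffle_score")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop_config("n_perm must be >= 1", "n_perm")
  need <- c("pseudotime", "weight_lineage_myo", "weight_lineage_peri")
  if (!all(need %in% names(cells)))
    stop_config("cells must carry pseudotime and both lineage weights", "cells")
  t <- cells$pseudotime
  w_myo <- cells$weight_lineage_myo
  w_peri <- cells$weight_lineage_peri
  stopifnot(length(score) == length(t))

  obs <- delta_auc_once(t, score, w_myo, w_peri, basis_dim, grid_points)

  n <- length(t)
  perm_deltas <- rep(NA_real_, n_perm)
  n_fail <- 0L
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("perm", i)))
    res <- tryCatch({
      if (scheme == "swap_weights") {
        swap <- runif(n) < 0.5
        pm <- ifelse(swap, w_peri, w_myo)
        pp <- ifelse(swap, w_myo, w_peri)
        delta_auc_once(t, score, pm, pp, basis_dim, grid_points)$delta
      } else {
        delta_auc_once(t, score[sample.int(n)], w_myo, w_peri, basis_dim,
                       grid_points)$delta
      }
    }, error = function(e) NA_real_)
    if (is.na(res)) n_fail <- n_fail + 1L
    perm_deltas[i] <- res
  }
  if (n_fail > 0.01 * n_perm)
    stop(sprintf("spline fits failed in %d/%d permutations (> 1%%); inspect weights and pseudotime support",
                 n_fail, n_perm))
  ok <- !is.na(perm_deltas)
  exceed <- sum(abs(perm_deltas[ok]) >= abs(obs$delta))
  structure(list(
    auc_myo = obs$auc_myo,
    auc_peri = obs$auc_peri,
    delta_auc = obs$delta,
    perm_deltas = perm_deltas,
    n_perm = as.integer(n_perm),
    n_failed = n_fail,
    p_two_sided = exceed / sum(ok),
    p_smoothed = (exceed + 1) / (sum(ok) + 1),
    scheme = scheme
  ), class = "delta_auc_test")
}

#' @export
print.delta_auc_test <- function(x, ...) {
  cat("delta-AUC permutation test (", x$scheme, "):\n",
      "  AUC myo = ", signif(x$auc_myo, 4),
      ", AUC peri = ", signif(x$auc_peri, 4),
      ", delta = ", signif(x$delta_auc, 4), "\n",
      "  p (two-sided, ", x$n_perm, " permutations) = ",
      signif(x$p_two_sided, 3), "\n", sep = "")
  invisible(x)
}

#' Subject-level permutation test for genotype bias in lineage assignment
#'
#' Summarizes each cell by its normalized myofibroblast-lineage weight
#' `w_myo / (w_myo + w_peri)`, averages within subject, and compares group
#' means between genotypes (group 1 minus group 0).  The null distribution
#' permutes genotype labels at the subject level, respecting the clustering
#' of cells within subjects.  Two-sided exceedance p-value.
#'
#' @param cells cell table with `subject_id`, both lineage weights, and the
#'   grouping column.
#' @param by name of the (binary) grouping column, default `"genotype"`.
#' @param n_perm number of label permutations (default 2000).
#' @param seed integer.
#' @return list with `statistic` (difference in group means), `p_two_sided`,
#'   `p_smoothed`, `subject_means`, `n_perm`.
#' @export
lineage_bias_test <- function(cells, by = "genotype", n_perm = 2000L,
                              seed = 1L) {
  need <- c("subject_id", "weight_lineage_myo", "weight_lineage_peri", by)
  if (!all(need %in% names(cells)))
    stop_config(sprintf("cells must carry %s", paste(need, collapse = ", ")),
                "cells")
  v <- cells$weight_lineage_myo /
    (cells$weight_lineage_myo + cells$weight_lineage_peri)
  if (any(!is.finite(v))) stop("cells with zero total lineage weight")
  subj_mean <- tapply(v, cells$subject_id, mean)
  subj_group <- tapply(cells[[by]], cells$subject_id, function(g) g[1])
  groups <- sort(unique(subj_group))
  if (length(groups) != 2L)
    stop(sprintf("'%s' must have exactly two levels, found %d", by,
                 length(groups)))
  if (min(table(subj_group)) < 2L)
    stop("need at least 2 subjects per group")

  stat_fun <- function(g) mean(subj_mean[g == groups[2]]) -
    mean(subj_mean[g == groups[1]])
  observed <- stat_fun(subj_group)
  perm_stats <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, paste0("bias", i)))
    perm_stats[i] <- stat_fun(sample(subj_group))
  }
  exceed <- sum(abs(perm_stats) >= abs(observed))
  list(statistic = observed,
       p_two_sided = exceed / n_perm,
       p_smoothed = (exceed + 1) / (n_perm + 1),
       subject_means = subj_mean,
       n_perm = as.integer(n_perm))
}
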