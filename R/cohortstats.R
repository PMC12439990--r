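#' Natural cubic spline basis
#'
#' Natural cubic spline basis with `df` columns, boundary knots at the data
#' range, interior knots at evenly spaced quantiles (for `df = 3`: the 33.33%
#' and 66.67% quantiles), and zero second derivative at and beyond the
#' boundary knots.  This is the age basis used in the subject-level
#' proportion model.
#'
#' @param x numeric vector.
#' @param df degrees of freedom (number of basis columns).
#' @param knots,boundary_knots optional explicit knots (used when evaluating
#'   the basis of a fitted model on new data).
#' @return matrix with `df` columns and attributes `knots` and
#'   `boundary_knots`.
#' @export
natural_spline_basis <- function(x, df = 3, knots = NULL,
                                 boundary_knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(x)) < df + 1)
      stop(sprintf("need at least %d distinct values for df = %d",
                   df + 1, df))
    b <- splines::ns(x, df = df)
  } else {
    b <- splines::ns(x, knots = knots, Boundary.knots = boundary_knots)
  }
  out <- unclass(b)
  attributes(out) <- list(dim = dim(b),
                          dimnames = list(NULL, paste0("ns", seq_len(ncol(b)))),
                          knots = as.numeric(attr(b, "knots")),
                          boundary_knots = as.numeric(attr(b, "Boundary.knots")))
  out
}

#' Binomial logistic regression by iteratively reweighted least squares
#'
#' Fits `cbind(successes, failures) ~ X` with a logit link by IRLS, iterating
#' to a deviance change below `tol`.  Standard errors come from the inverse
#' of the final weighted information matrix (Wald), and odds ratios are
#' `exp(coefficient)` with 95% CI `exp(coefficient +- 1.96 * SE)`.
#'
#' @param X design matrix (including the intercept column); must be full
#'   rank.
#' @param successes,failures nonnegative integer vectors per observation.
#' @param max_iter,tol IRLS controls.
#' @return object of class `pmt_glm`: `coefficients`, `vcov`, `se`,
#'   `odds_ratios` (with `ci_low`/`ci_high`), `fitted` (proportions),
#'   `deviance`, `iterations`, `converged`.
#' @export
fit_logistic_irls <- function(X, successes, failures, max_iter = 50L,
                              tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(successes), length(successes) == length(failures))
  if (any(successes < 0) || any(failures < 0))
    stop("negative counts")
  n_trials <- successes + failures
  if (any(n_trials == 0)) stop("observation with zero trials")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", ")))
  }

  y <- successes / n_trials
  beta <- rep(0, ncol(X))
  # deviance with 0*log(0) = 0 convention
  dev_fun <- function(mu) {
    term <- function(obs, fit) ifelse(obs > 0, obs * log(obs / fit), 0)
    2 * sum(term(successes, n_trials * mu) +
            term(failures, n_trials * (1 - mu)))
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  dev <- dev_fun(mu)
  converged <- FALSE
  iter <- 0L
  W <- NULL
  for (iter in seq_len(max_iter)) {
    w <- n_trials * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    dev_new <- dev_fun(mu)
    if (abs(dev_new - dev) < tol * (abs(dev) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  w <- n_trials * mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  if (any(abs(beta) > 15))
    warning("|coefficient| > 15: possible separation; estimates unreliable")

  ors <- data.frame(
    term = colnames(X),
    estimate = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    log_or = beta,
    se_log = se,
    z = beta / se,
    row.names = NULL
  )
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    vcov = vcov,
    se = setNames(se, colnames(X)),
    odds_ratios = ors,
    fitted = plogis(eta),
    deviance = dev,
    iterations = iter,
    converged = converged
  ), class = "pmt_glm")
}

#' @export
print.pmt_glm <- function(x, ...) {
  cat("binomial logit GLM (IRLS,", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(x$odds_ratios[, c("term", "estimate", "ci_low", "ci_high")],
        digits = 3)
  invisible(x)
}

# Build the design matrix for the subject-level proportion model:
# intercept + genotype + ns(age, df) + sex + dataset (treatment coding,
# lexicographic reference level).  Stores factor levels and spline knots so
# prediction on new subjects reuses them.
build_proportion_design <- function(subjects, age_df = 3,
                                    spline_attrs = NULL, levels = NULL) {
  n <- nrow(subjects)
  cols <- list("(Intercept)" = rep(1, n))
  if (!is.null(subjects$genotype)) cols$genotype <- as.numeric(subjects$genotype)
  if (!is.null(subjects$age) && age_df > 0) {
    basis <- if (is.null(spline_attrs)) {
      natural_spline_basis(subjects$age, df = age_df)
    } else {
      natural_spline_basis(subjects$age, knots = spline_attrs$knots,
                           boundary_knots = spline_attrs$boundary_knots)
    }
    for (j in seq_len(ncol(basis))) cols[[paste0("age_ns", j)]] <- basis[, j]
    spline_attrs <- list(knots = attr(basis, "knots"),
                         boundary_knots = attr(basis, "boundary_knots"))
  }
  lev_out <- list()
  for (v in c("sex", "dataset")) {
    if (is.null(subjects[[v]])) next
    obs_lev <- sort(unique(as.character(subjects[[v]])))
    lev <- if (is.null(levels)) obs_lev else levels[[v]]
    unseen <- setdiff(obs_lev, lev)
    if (length(unseen))
      stop(sprintf("unseen level(s) of '%s': %s", v,
                   paste(unseen, collapse = ", ")))
    for (l in lev[-1]) cols[[paste0(v, l)]] <- as.numeric(subjects[[v]] == l)
    lev_out[[v]] <- lev
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, spline_attrs = spline_attrs, levels = lev_out)
}

#' Subject-level proportion model
#'
#' Models a per-subject cell-state proportion (`numerator` of `denominator`
#' cells) with a binomial logit GLM on genotype, a natural cubic spline in
#' age (default 3 df), sex, and dataset -- the subject-level adjustment used
#' to test whether the risk genotype carries more transitioned cells.
#'
#' @param subjects subject table with `numerator`, `denominator`, `genotype`,
#'   `age`, and optionally `sex`, `dataset`.
#' @param age_df spline degrees of freedom for age (0 drops the age term).
#' @return a `pmt_glm` augmented with the design metadata needed by
#'   [predict_proportions()].
#' @export
fit_proportion_glm <- function(subjects, age_df = 3) {
  stopifnot(all(c("numerator", "denominator") %in% names(subjects)))
  if (any(subjects$numerator > subjects$denominator))
    stop("numerator exceeds denominator")
  d <- build_proportion_design(subjects, age_df = age_df)
  fit <- fit_logistic_irls(d$X, subjects$numerator,
                           subjects$denominator - subjects$numerator)
  fit$design <- list(age_df = age_df, spline_attrs = d$spline_attrs,
                     levels = d$levels)
  fit
}

#' Predicted cell-state proportions for subjects
#'
#' Inverse-logit of the linear predictor of a fitted proportion model,
#' evaluated on (possibly new) subjects with the training spline knots and
#' factor coding.  Unseen categorical levels raise an error naming the
#' level.
#'
#' @param fit result of [fit_proportion_glm()].
#' @param subjects subject table with all model covariates.
#' @return per-subject predicted proportions in (0, 1).
#' @export
predict_proportions <- function(fit, subjects) {
  if (is.null(fit$design))
    stop("fit carries no design metadata; use fit_proportion_glm()")
  d <- build_proportion_design(subjects, age_df = fit$design$age_df,
                               spline_attrs = fit$design$spline_attrs,
                               levels = fit$design$levels)
  keep <- intersect(names(fit$coefficients), colnames(d$X))
  if (length(keep) != length(fit$coefficients))
    stop("subjects lack covariates required by the model")
  plogis(drop(d$X[, names(fit$coefficients), drop = FALSE] %*%
                fit$coefficients))
}

# Standardized mean difference of a covariate between genotype groups,
# using the pooled SD of the two groups (binary covariates coerced to 0/1).
smd <- function(x, group) {
  x <- as.numeric(if (is.character(x) || is.factor(x))
    x == sort(unique(as.character(x)))[length(unique(x))] else x)
  m1 <- mean(x[group == 1]); m0 <- mean(x[group == 0])
  s <- sqrt((var(x[group == 1]) + var(x[group == 0])) / 2)
  if (!is.finite(s) || s == 0) return(if (m1 == m0) 0 else Inf)
  (m1 - m0) / s
}

#' Greedy propensity-score matching within dataset
#'
#' Fits a propensity model (probability of genotype 1 given the covariates)
#' by logistic IRLS within each dataset, then performs greedy 1:1
#' nearest-neighbor matching without replacement on the logit of the
#' propensity score, processing treated (genotype 1) subjects in descending
#' propensity order.  Matching never crosses datasets and never reuses a
#' control.
#'
#' @param subjects subject table with `genotype`, `dataset`, and the matching
#'   covariates.
#' @param covariates covariate columns for the propensity model (binary or
#'   numeric; character columns are coded against their lexicographic first
#'   level).
#' @param ratio controls per treated subject (only 1 supported).
#' @return list with `matched` (subject table restricted to matched pairs,
#'   plus `pair_id` and `propensity`), `pairs`, and `balance` (per-covariate
#'   SMD before/after matching).
#' @export
propensity_match <- function(subjects,
                             covariates = c("age", "sex", "ad_status",
                                            "total_cell_count"),
                             ratio = 1) {
  if (ratio != 1) stop_config("only 1:1 matching is supported", "ratio")
  covariates <- intersect(covariates, names(subjects))
  if (!length(covariates)) stop_config("no matching covariates present",
                                       "covariates")
  if (is.null(subjects$dataset)) subjects$dataset <- "all"

  num_cov <- function(df, v) {
    x <- df[[v]]
    if (is.character(x) || is.factor(x))
      as.numeric(x == sort(unique(as.character(x)))[length(unique(x))])
    else as.numeric(x)
  }

  subjects$propensity <- NA_real_
  pairs <- NULL
  for (ds in unique(subjects$dataset)) {
    idx <- which(subjects$dataset == ds)
    sub <- subjects[idx, , drop = FALSE]
    treated <- which(sub$genotype == 1)
    control <- which(sub$genotype == 0)
    if (!length(treated) || !length(control))
      stop(sprintf("dataset '%s' lacks one genotype group", ds))
    if (length(control) < length(treated))
      stop(sprintf("dataset '%s': %d treated but only %d controls (shortfall %d)",
                   ds, length(treated), length(control),
                   length(treated) - length(control)))
    X <- cbind("(Intercept)" = 1,
               sapply(covariates, function(v) num_cov(sub, v)))
    # drop constant covariate columns within the dataset to keep full rank
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col)
      length(unique(col)) > 1))
    ps_fit <- suppressWarnings(
      fit_logistic_irls(X[, keep, drop = FALSE],
                        sub$genotype, 1 - sub$genotype))
    ps <- ps_fit$fitted
    subjects$propensity[idx] <- ps
    lp <- qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))

    avail <- control
    for (tr in treated[order(ps[treated], decreasing = TRUE)]) {
      d <- abs(lp[avail] - lp[tr])
      best <- avail[which.min(d)]
      pairs <- rbind(pairs, data.frame(
        dataset = ds,
        treated_id = sub$subject_id[tr],
        control_id = sub$subject_id[best],
        distance = min(d),
        stringsAsFactors = FALSE
      ))
      avail <- setdiff(avail, best)
    }
  }
  pairs$pair_id <- seq_len(nrow(pairs))
  matched_ids <- c(pairs$treated_id, pairs$control_id)
  matched <- subjects[subjects$subject_id %in% matched_ids, , drop = FALSE]
  matched$pair_id <- NA_integer_
  matched$pair_id[match(pairs$treated_id, matched$subject_id)] <- pairs$pair_id
  matched$pair_id[match(pairs$control_id, matched$subject_id)] <- pairs$pair_id

  balance <- data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v)
      smd(subjects[[v]], subjects$genotype), numeric(1)),
    smd_after = vapply(covariates, function(v)
      smd(matched[[v]], matched$genotype), numeric(1)),
    row.names = NULL
  )
  list(matched = matched, pairs = pairs, balance = balance)
}

#' Randomized-quantile residual uniformity check
#'
#' Simulates `n_sim` response vectors from the fitted binomial model; each
#' subject's residual is its observed count's randomized rank among the
#' simulations (uniform on the probability interval the observation occupies,
#' so exactly Uniform(0,1) under a correct model).  Residuals are compared to
#' Uniform(0,1) with a Kolmogorov-Smirnov test; small p-values indicate
#' misspecification such as overdispersion.
#'
#' @param fit a fitted `pmt_glm` (converged).
#' @param subjects subject table with `numerator` and `denominator` used in
#'   the fit (row order matching the fit).
#' @param n_sim simulated response sets (default 250).
#' @param seed integer.
#' @return list with `residuals`, `ks_statistic`, `p_value`.
#' @export
residual_check <- function(fit, subjects, n_sim = 250L, seed = 1L) {
  if (!isTRUE(fit$converged)) stop("residual check requires a converged fit")
  set.seed(derive_seed(seed, "residual_check"))
  n <- nrow(subjects)
  trials <- subjects$denominator
  obs <- subjects$numerator
  sims <- matrix(rbinom(n * n_sim, size = rep(trials, n_sim),
                        prob = rep(fit$fitted, n_sim)), nrow = n)
  p_lt <- rowMeans(sims < obs)
  p_le <- rowMeans(sims <= obs)
  res <- p_lt + runif(n) * (p_le - p_lt)
  ks <- suppressWarnings(ks.test(res, "punif"))
  list(residuals = res,
       ks_statistic = unname(ks$statistic),
       p_value = ks$p.value)
}
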