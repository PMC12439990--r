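test_that("natural spline basis is linear beyond its boundary knots", {
  set.seed(1)
  x <- runif(60, 60, 95)
  b <- natural_spline_basis(x, df = 3)
  expect_equal(ncol(b), 3)
  bk <- attr(b, "boundary_knots")
  eps <- 1e-4
  d2_at <- function(x0) {
    bb <- natural_spline_basis(c(x0 - eps, x0, x0 + eps), df = 3,
                               knots = attr(b, "knots"),
                               boundary_knots = bk)
    (bb[1, ] - 2 * bb[2, ] + bb[3, ]) / eps^2
  }
  expect_lt(max(abs(d2_at(bk[1]))), 1e-6)
  expect_lt(max(abs(d2_at(bk[2]))), 1e-6)
  expect_error(natural_spline_basis(rep(1, 10), df = 3), "distinct")
})

test_that("GLM proportions are invariant to affine age transforms and df=1 matches a linear fit", {
  set.seed(2)
  subj <- data.frame(subject_id = sprintf("S%02d", 1:40),
                     genotype = rbinom(40, 1, 0.5),
                     age = runif(40, 60, 90),
                     sex = sample(c("F", "M"), 40, TRUE),
                     denominator = 50)
  subj$numerator <- rbinom(40, 50, plogis(-1 + subj$genotype))
  f <- fit_proportion_glm(subj)
  subj2 <- subj
  subj2$age <- 3 * subj$age + 10
  f2 <- fit_proportion_glm(subj2)
  expect_equal(f$fitted, f2$fitted, tolerance = 1e-8)

  f1 <- fit_proportion_glm(subj, age_df = 1)
  g <- glm(cbind(numerator, denominator - numerator) ~ genotype + age + sex,
           family = binomial(), data = subj)
  expect_equal(unname(f1$fitted), unname(fitted(g)), tolerance = 1e-8)
})

test_that("IRLS matches the closed-form 2x2 odds ratio and the binomial MLE", {
  X <- cbind("(Intercept)" = 1, genotype = c(1, 0))
  f <- fit_logistic_irls(X, c(8, 2), c(12, 18))
  expect_equal(f$odds_ratios$estimate[f$odds_ratios$term == "genotype"],
               (8 * 18) / (12 * 2), tolerance = 1e-6)

  # intercept-only model: fitted proportion is the pooled MLE
  X0 <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f0 <- fit_logistic_irls(X0, c(3, 4, 5), c(7, 6, 5))
  expect_equal(unique(round(f0$fitted, 12)), 12 / 30)

  # CI brackets the estimate
  expect_true(all(f$odds_ratios$ci_low <= f$odds_ratios$estimate &
                  f$odds_ratios$estimate <= f$odds_ratios$ci_high))
})

test_that("IRLS agrees with brute-force likelihood maximization and stats::glm", {
  set.seed(3)
  for (rep in 1:3) {
    n <- 25
    X <- cbind("(Intercept)" = 1, g = rbinom(n, 1, 0.5), x1 = rnorm(n),
               x2 = rnorm(n))
    trials <- sample(20:60, n, TRUE)
    s <- rbinom(n, trials, plogis(drop(X %*% c(-1, 1.2, 0.5, -0.3))))
    f <- fit_logistic_irls(X, s, trials - s)

    nll <- function(b) -sum(dbinom(s, trials, plogis(drop(X %*% b)), log = TRUE))
    o <- optim(rep(0, 4), nll, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    expect_lt(max(abs(f$coefficients - o$par)), 1e-5)

    g <- glm(cbind(s, trials - s) ~ X - 1, family = binomial())
    expect_lt(max(abs(f$coefficients - unname(coef(g)))), 1e-8)
    expect_lt(max(abs(f$vcov - unname(vcov(g)))), 1e-8)
  }
})

test_that("odds ratios invert when the reference level is swapped", {
  X <- cbind("(Intercept)" = 1, genotype = c(1, 1, 0, 0))
  f1 <- fit_logistic_irls(X, c(8, 7, 2, 3), c(12, 13, 18, 17))
  X2 <- X; X2[, 2] <- 1 - X[, 2]
  f2 <- fit_logistic_irls(X2, c(8, 7, 2, 3), c(12, 13, 18, 17))
  o1 <- f1$odds_ratios[f1$odds_ratios$term == "genotype", ]
  o2 <- f2$odds_ratios[f2$odds_ratios$term == "genotype", ]
  expect_equal(o2$estimate, 1 / o1$estimate, tolerance = 1e-8)
  expect_equal(o2$ci_low, 1 / o1$ci_high, tolerance = 1e-8)
  expect_equal(o2$ci_high, 1 / o1$ci_low, tolerance = 1e-8)
})

test_that("rank deficiency and separation are reported", {
  X <- cbind("(Intercept)" = 1, a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))
  expect_error(fit_logistic_irls(X, c(5, 2, 6, 1), c(5, 8, 4, 9)), "aliased")
  Xs <- cbind("(Intercept)" = 1, g = c(1, 1, 0, 0))
  expect_warning(fit_logistic_irls(Xs, c(20, 20, 0, 0), c(0, 0, 20, 20)),
                 "separation")
})

test_that("predictions are inverse-logit, self-consistent, and guard levels", {
  set.seed(4)
  subj <- data.frame(subject_id = sprintf("S%02d", 1:30),
                     genotype = rbinom(30, 1, 0.5),
                     age = runif(30, 60, 90),
                     sex = sample(c("F", "M"), 30, TRUE),
                     dataset = sample(c("D1", "D2"), 30, TRUE),
                     denominator = 40)
  subj$numerator <- rbinom(30, 40, plogis(-1 + 0.8 * subj$genotype))
  f <- fit_proportion_glm(subj)
  p <- predict_proportions(f, subj)
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(p), unname(f$fitted), tolerance = 1e-10)
  # score-equation identity: denominator-weighted mean of fitted equals the
  # pooled observed proportion (intercept column in the design)
  expect_equal(sum(subj$denominator * p) / sum(subj$denominator),
               sum(subj$numerator) / sum(subj$denominator),
               tolerance = 1e-8)
  # monotone in genotype when only genotype differs
  s2 <- subj[1, ]; s2$genotype <- 1L
  s1 <- subj[1, ]; s1$genotype <- 0L
  beta_g <- f$coefficients[["genotype"]]
  preds <- predict_proportions(f, rbind(s1, s2))
  expect_equal(sign(diff(preds)), sign(beta_g))
  bad <- subj[1, ]; bad$dataset <- "D9"
  expect_error(predict_proportions(f, bad), "D9")
})

test_that("propensity matching pairs nearest neighbours within dataset", {
  # identical covariate vectors pairwise: perfect balance
  subj <- data.frame(subject_id = sprintf("S%02d", 1:8),
                     genotype = rep(c(1L, 0L), 4),
                     age = rep(c(70, 75, 80, 85), each = 2),
                     total_cell_count = rep(c(30, 55, 40, 60), each = 2),
                     dataset = "D1")
  m <- propensity_match(subj, covariates = c("age", "total_cell_count"))
  expect_equal(nrow(m$pairs), 4)
  expect_true(all(abs(m$balance$smd_after) < 1e-10))

  # matching never crosses datasets and never reuses a control
  set.seed(5)
  subj2 <- data.frame(subject_id = sprintf("S%02d", 1:24),
                      genotype = rep(c(1L, 0L, 0L), 8),
                      age = rnorm(24, 75, 6),
                      total_cell_count = rpois(24, 50),
                      dataset = rep(c("D1", "D2"), each = 12))
  m2 <- propensity_match(subj2, covariates = c("age", "total_cell_count"))
  expect_false(any(duplicated(m2$pairs$control_id)))
  ds_of <- function(id) subj2$dataset[match(id, subj2$subject_id)]
  expect_true(all(ds_of(m2$pairs$treated_id) == ds_of(m2$pairs$control_id)))

  # shortfall of controls is an error
  short <- subj2[subj2$genotype == 1 | subj2$subject_id == "S02", ]
  expect_error(propensity_match(short, covariates = "age"), "shortfall")
})

test_that("matching reduces confounder imbalance on a shifted cohort", {
  set.seed(6)
  n_t <- 15; n_c <- 30
  subj <- data.frame(subject_id = sprintf("S%02d", 1:(n_t + n_c)),
                     genotype = rep(c(1L, 0L), c(n_t, n_c)),
                     age = c(rnorm(n_t, 80, 5), rnorm(n_c, 75, 5)),
                     total_cell_count = rpois(n_t + n_c, 50),
                     dataset = "D1")
  m <- propensity_match(subj, covariates = c("age", "total_cell_count"))
  b <- m$balance
  expect_lt(abs(b$smd_after[b$covariate == "age"]),
            abs(b$smd_before[b$covariate == "age"]))
})

test_that("randomized-quantile residuals are uniform under the model and detect overdispersion", {
  set.seed(7)
  calib <- vapply(1:20, function(r) {
    cfg <- synth_config(n_subjects_per_genotype = 25, seed = 6000 + r)
    subj <- simulate_proportion_cohort(generate_cohort(cfg)$subjects, seed = r)
    fit <- fit_proportion_glm(subj)
    rc <- residual_check(fit, subj, seed = r)
    stopifnot(all(rc$residuals >= 0 & rc$residuals <= 1))
    rc$p_value
  }, numeric(1))
  expect_gte(mean(calib > 0.05), 0.9)

  power <- vapply(1:20, function(r) {
    cfg <- synth_config(n_subjects_per_genotype = 25, seed = 7000 + r)
    subj <- generate_cohort(cfg)$subjects
    set.seed(r)
    subj$denominator <- subj$n_cells
    rho <- 0.3
    subj$numerator <- rbinom(nrow(subj), subj$denominator,
                             rbeta(nrow(subj), 0.3 * (1 - rho) / rho,
                                   0.7 * (1 - rho) / rho))
    fit <- fit_proportion_glm(subj)
    residual_check(fit, subj, seed = r)$p_value
  }, numeric(1))
  expect_gte(mean(power < 0.05), 0.8)
})
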