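test_that("severe fatigue threshold sits at a CIS subjective score of 35", {
  expect_equal(severe_fatigue(c(0, 34, 35, 56)), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(is.na(severe_fatigue(NA_real_)))
  expect_error(severe_fatigue(-1), "negative")
})

test_that("transform policy pins the published log2 predictors", {
  expect_equal(transform_policy("taurine", "plasma"), "log2")
  expect_equal(transform_policy("alanine", "plasma"), "sd")
  expect_equal(transform_policy("taurine", "loss"), "log2")
  expect_equal(transform_policy("tryptophan", "loss"), "log2")
  expect_equal(transform_policy("tryptophan", "plasma"), "sd")
  expect_error(transform_policy("taurine", "plasma", values = c(1, 0)), "non-positive")
})

test_that("standardized betas reduce to Pearson correlations univariably", {
  y <- 1:20
  x <- 2 * (1:20)
  fit <- suppressWarnings(fit_linear_stdbeta(y, data.frame(x = x)))
  expect_equal(fit$std_beta, 1)
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(60)
    y <- -x + stats::rnorm(60, 0, 0.5)
    fit <- fit_linear_stdbeta(y, data.frame(x = x))
    expect_equal(fit$std_beta, stats::cor(x, y), tolerance = 1e-10)
  }
  expect_error(fit_linear_stdbeta(1:10, data.frame(x = rep(1, 10))), "zero-variance")
})

test_that("orthogonal predictors give equal univariable and multivariable betas", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4) # exactly orthogonal to x1
  set.seed(14)
  y <- 0.7 * x1 - 0.4 * x2 + stats::rnorm(n, 0, 0.3)
  multi <- fit_linear_stdbeta(y, data.frame(x1 = x1, x2 = x2))
  uni1 <- fit_linear_stdbeta(y, data.frame(x1 = x1))
  uni2 <- fit_linear_stdbeta(y, data.frame(x2 = x2))
  expect_equal(multi$std_beta[1], uni1$std_beta, tolerance = 1e-8)
  expect_equal(multi$std_beta[2], uni2$std_beta, tolerance = 1e-8)
  expect_true(all(multi$vif < 1.01))
})

test_that("univariable screening at p < 0.05 drives the multivariable fit", {
  set.seed(15)
  n <- 80
  x_strong <- stats::rnorm(n)
  x_mid <- stats::rnorm(n)
  x_null <- stats::rnorm(n)
  y <- 1.2 * x_strong + 0.5 * x_mid + stats::rnorm(n)
  sel <- select_multivariable(y, data.frame(
    x_strong = x_strong, x_mid = x_mid, x_null = x_null
  ))
  expect_true(all(c("x_strong", "x_mid") %in% sel$selected))
  expect_false("x_null" %in% sel$selected)
  expect_equal(sort(sel$multivariable$term), sort(sel$selected))
  # nothing significant -> documented empty selection
  y0 <- stats::rnorm(n)
  x_noise <- stats::rnorm(n)
  sel0 <- select_multivariable(y0, data.frame(x = x_noise))
  if (length(sel0$selected) == 0L) expect_null(sel0$multivariable)
})

test_that("unadjusted logistic OR on a binary predictor equals the cross-product ratio", {
  set.seed(16)
  for (i in 1:5) {
    n <- 120
    x <- stats::rbinom(n, 1, 0.45)
    p <- stats::plogis(-0.4 + 0.9 * x)
    y <- stats::runif(n) < p
    d <- data.frame(severe = y, x = x)
    fit <- fit_logistic(d, "x", model = 0, transform = "none")
    expect_equal(fit$or, crossprod_or(x, y), tolerance = 1e-6)
  }
})

test_that("a predictor independent of the outcome gives OR near 1 at large n", {
  set.seed(17)
  n <- 2000
  d <- data.frame(
    severe = stats::runif(n) < 0.35,
    x = stats::rlnorm(n, 4, 0.6),
    age = stats::rnorm(n, 65, 15), sex_male = stats::runif(n) < 0.6,
    bmi = stats::rnorm(n, 25, 4), vintage = stats::rlnorm(n, log(15), 1)
  )
  fit <- fit_logistic(d, "x", model = 1, transform = "log2")
  expect_lt(abs(fit$log_or), 0.12)
  expect_true(fit$ci_lo < 1 && fit$ci_hi > 1)
})

test_that("complete separation is flagged instead of reported as an estimate", {
  d <- data.frame(severe = c(rep(FALSE, 12), rep(TRUE, 12)), x = c(1:12, 51:62))
  fit <- fit_logistic(d, "x", model = 0, transform = "none")
  expect_true(fit$separation)
  expect_true(is.na(fit$or))
})

test_that("sensitivity rules only bite when their exclusion criterion is present", {
  set.seed(18)
  n <- 160
  # uniform draws keep every value within 2 SD of the mean (max |z| = sqrt(3)),
  # so no rule except the hemoglobin percentile can exclude anyone
  d <- data.frame(
    severe = stats::runif(n) < 0.35,
    x = stats::runif(n, 45, 55),
    age = stats::rnorm(n, 65, 10), sex_male = stats::runif(n) < 0.6,
    bmi = stats::runif(n, 22, 30), vintage = stats::runif(n, 1, 50),
    hemoglobin = stats::rnorm(n, 6.9, 0.7), crp = stats::rlnorm(n, log(5), 1),
    cvd = stats::runif(n) < 0.4, diabetes = stats::runif(n) < 0.25,
    n_per_week = 3
  )
  suite <- sensitivity_suite(d, "x", model = 1, transform = "sd")
  base <- suite[suite$rule == "base", ]
  for (r in c("outliers", "twice_weekly", "vintage_gt_60", "low_bmi")) {
    row <- suite[suite$rule == r, ]
    expect_equal(row$n_excluded, 0L)
    expect_equal(row$or, base$or, tolerance = 1e-9)
  }
  # the within-sex 5th-percentile hemoglobin rule always excludes someone
  expect_gt(suite$n_excluded[suite$rule == "low_hemoglobin"], 0)
  # a single injected extreme value moves only the outlier rule
  d2 <- d
  d2$x[1] <- 50 + 40 * stats::sd(d$x)
  suite2 <- sensitivity_suite(d2, "x", model = 1, transform = "sd")
  expect_equal(suite2$n_excluded[suite2$rule == "outliers"], 1L)
  expect_equal(suite2$n_excluded[suite2$rule == "twice_weekly"], 0L)
  expect_equal(suite2$n_excluded[suite2$rule == "low_bmi"], 0L)
})

test_that("probability curves are inverse-logit and monotone in the coefficient sign", {
  set.seed(19)
  n <- 300
  x <- stats::rnorm(n, 100, 15)
  severe <- stats::runif(n) < stats::plogis(0.2 - 0.06 * (x - 100))
  d <- data.frame(severe = severe, x = x)
  cur <- probability_curve(d, "x", model = 0, transform = "sd")
  expect_true(all(diff(cur$probability) < 0)) # negative slope -> decreasing
  expect_true(all(cur$probability > 0 & cur$probability < 1))
  # coefficient ~0 -> flat curve at the marginal probability
  severe0 <- stats::runif(n) < 0.3
  d0 <- data.frame(severe = severe0, x = x)
  cur0 <- probability_curve(d0, "x", model = 0, transform = "sd")
  expect_lt(max(cur0$probability) - min(cur0$probability), 0.2)
  expect_warning(
    probability_curve(d, "x", model = 0, grid = c(min(x) - 50, 100)),
    "extrapolation"
  )
})

test_that("the cohort association dataset wires panels, losses and covariates", {
  co <- tiny_cohort(seed = 20, n_hd = 59, n_ctrl = 0)
  ds <- association_dataset(co)
  expect_equal(nrow(ds), sum(co$subjects$arm == "hd"))
  expect_true(all(c(
    "severe", "age", "sex_male", "bmi", "vintage", "hemoglobin", "crp",
    "cvd", "diabetes", "protein_intake", "plasma_taurine", "loss_taurine",
    "plasma_total", "loss_total"
  ) %in% names(ds)))
  expect_equal(
    ds$loss_total,
    ds$loss_essential + ds$loss_non_essential,
    tolerance = 1e-9
  )
  res <- fit_logistic(ds, "loss_taurine", model = 1, transform = "log2")
  expect_true(res$converged)
  expect_equal(res$increment, "per-log2")
})
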