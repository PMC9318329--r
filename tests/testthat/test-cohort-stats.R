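test_that("distribution assessment flags bell-shaped vs heavy-tailed samples", {
  set.seed(1)
  expect_equal(assess_distribution(stats::rnorm(1000, 50, 5)), "normal")
  expect_equal(assess_distribution(stats::rlnorm(1000, 0, 1.2)), "skewed")
  expect_equal(assess_distribution(rep(3, 10)), "skewed-degenerate")
  expect_error(assess_distribution(c(1, 2)), "at least 3")
})

test_that("summaries populate the central/dispersion pair per flag", {
  s <- summarize_values(c(1, 2, 3), "normal")
  expect_equal(s$central, 2)
  expect_equal(s$dispersion, 1)
  expect_equal(s$n, 3L)
  sk <- summarize_values(c(1, 2, 3, 4, 100), "skewed")
  expect_equal(sk$central, 3)
  expect_equal(sk$dispersion, unname(stats::quantile(c(1, 2, 3, 4, 100), c(.25, .75))))
  one <- summarize_values(5, "normal")
  expect_equal(one$central, 5)
  expect_equal(one$dispersion, 0)
  expect_error(summarize_values(numeric(0), "normal"), "empty")
  # median path is invariant to input order
  set.seed(2)
  x <- stats::rlnorm(101)
  expect_equal(
    summarize_values(x, "skewed")$central,
    summarize_values(sample(x), "skewed")$central
  )
})

test_that("derived comparison columns reproduce their display rounding", {
  # identities
  expect_equal(proportional_difference(57, 57), 0)
  expect_equal(group_ratio(57, 57), 1.0)
  # half-away-from-zero at both signs
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.25, 1), 2.3)
  expect_equal(round_half_away(-2.25, 1), -2.3)
  # ratio rounding switches at 2: one decimal below, integer above
  expect_equal(group_ratio(3, 2), 1.5)
  expect_equal(group_ratio(5, 2), 3)
  expect_error(proportional_difference(10, 0), "positive")
  expect_error(group_ratio(10, 0), "positive")
})

test_that("two-group dispatch matches closed forms and permutation oracles", {
  # t path equals the hand-coded Welch statistic
  set.seed(7)
  a <- stats::rnorm(12, 10, 2)
  b <- stats::rnorm(15, 11, 2)
  res <- compare_groups(a, b, "continuous", dist_flag = "normal")
  tstat <- (mean(a) - mean(b)) / sqrt(stats::var(a) / 12 + stats::var(b) / 15)
  expect_equal(res$test, "t-test")
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  # rank-sum path agrees with full enumeration for small untied samples
  for (i in 1:5) {
    a <- stats::runif(5)
    b <- stats::runif(6) + 0.2
    res <- compare_groups(a, b, "continuous", dist_flag = "skewed")
    expect_equal(res$test, "wilcoxon-rank-sum")
    expect_equal(res$p, perm_ranksum_p(a, b), tolerance = 1e-12)
  }
  # chi-squared on a hand-computed 2x2 table (no continuity correction)
  res <- compare_groups(c(0, 0, 0, 1), c(1, 1, 1, 0), "nominal")
  tab <- matrix(c(3, 1, 1, 3), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("near-identical groups give a near-unity rank-sum p-value", {
  x <- c(1.1, 2.2, 3.3, 4.4, 5.5)
  res <- compare_groups(x, x, "continuous", dist_flag = "skewed")
  expect_gt(res$p, 0.9)
})

test_that("paired dispatch matches the sign-flip enumeration oracle", {
  set.seed(8)
  pre <- stats::runif(8, 10, 20)
  post <- pre + stats::rnorm(8, 0.5, 1)
  res <- compare_paired(pre, post, dist_flag = "skewed")
  expect_equal(res$test, "signed-rank")
  expect_equal(res$p, signflip_signedrank_p(post - pre), tolerance = 1e-12)
  # unchanged pairs: p = 1, statistic 0 by convention
  same <- compare_paired(pre, pre)
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 0)
  expect_true(same$degenerate)
  # constant shift: zero-variance differences flagged degenerate
  shift <- compare_paired(c(1, 2, 3), c(2, 3, 4))
  expect_true(shift$degenerate)
  expect_error(compare_paired(1:3, 1:4), "equal length")
})

test_that("report tables carry the expected rows and self-consistent derived columns", {
  co <- tiny_cohort(seed = 12)
  q <- quantify_cohort(co)
  t2 <- build_table(co, 2, q)
  t3 <- build_table(co, 3, q)
  t4 <- build_table(co, 4, q)
  for (tb in list(t2, t3, t4)) {
    expect_equal(nrow(tb), 25L)
    expect_equal(sum(tb$row_type == "species"), 21L)
    expect_equal(sum(tb$row_type == "group"), 4L)
  }
  # derived columns round-trip from the emitted central values
  expect_equal(t2$derived, proportional_difference(t2$hd_central, t2$ctrl_central))
  expect_equal(t3$derived, group_ratio(t3$hd_central, t3$ctrl_central))
  expect_equal(
    t4$proportional_change,
    round_half_away(t4$change_central / t4$pre_central * 100)
  )
  # preset skewed analytes are summarized as median(IQR)
  expect_equal(t2$dist_flag[t2$analyte == "taurine"], "skewed")
  expect_equal(t2$dist_flag[t2$analyte == "alanine"], "normal")
  t1 <- build_table(co, 1, q)
  expect_true(all(c("age_years", "ktv", "protein_intake_g") %in% t1$characteristic))
})
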