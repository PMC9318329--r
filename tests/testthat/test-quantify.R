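test_that("daily losses match hand-computed values and reject bad input", {
  expect_equal(daily_losses_hd(135, 20, 3, 100), 8100 / 7 + 100) # 1257.14
  expect_equal(daily_losses_hd(1, 0, 3, 0), 0)
  expect_equal(daily_losses_hd(100, 50, 3, 0), 15000 / 7) # anuric
  expect_error(daily_losses_hd(135, NA, 3, 0), "missing dialysate")
  expect_error(daily_losses_hd(135, -1, 3, 0), "non-negative")

  expect_equal(daily_losses_control(2.5, 100), 250)
  expect_equal(daily_losses_control(2.5, 0), 0)
  expect_equal(daily_losses_control(0, 100), 0)
  expect_error(daily_losses_control(-1, 100), "non-negative")
})

test_that("single-session losses relate to daily losses by the weekly factor", {
  expect_equal(single_session_losses(135, 20), 2700)
  expect_equal(single_session_losses(135, 0), 0)
  # algebraic identity when there is no urinary component
  for (n in c(2, 3)) {
    expect_equal(
      daily_losses_hd(120, 37.5, n, 0) * 7 / n,
      single_session_losses(120, 37.5)
    )
  }
})

test_that("Daugirdas Kt/V matches hand-derived values and domain rules", {
  expect_equal(ktv_daugirdas(0.3, 4, 2, 78),
    -log(0.3 - 0.032) + (4 - 3.5 * 0.3) * 2 / 78,
    tolerance = 1e-12
  )
  expect_equal(round(ktv_daugirdas(0.3, 4, 2, 78), 3), 1.392)
  expect_equal(ktv_daugirdas(1, 0, 0, 70), 0)
  expect_equal(round(ktv_daugirdas(0.4, 4, 1, 70), 3), 1.037)
  expect_error(ktv_daugirdas(0.03, 4, 0, 70), "log-domain")
  expect_error(ktv_daugirdas(0.5, 4, 0, 0), "positive")
  expect_error(ktv_daugirdas(1.2, 4, 0, 70), "urea ratio")
})

test_that("Kt/V is monotone: decreasing in R, increasing in UF", {
  set.seed(21)
  for (i in 1:50) {
    t <- stats::runif(1, 2.5, 5)
    UF <- stats::runif(1, 0, 4)
    W <- stats::runif(1, 45, 120)
    r1 <- stats::runif(1, 0.15, 0.9)
    r2 <- r1 + stats::runif(1, 0.01, 0.95 - r1)
    expect_gt(ktv_daugirdas(r1, t, UF, W), ktv_daugirdas(r2, t, UF, W))
    R <- stats::runif(1, 0.15, 0.95)
    expect_gt(
      ktv_daugirdas(R, t, UF + 0.5, W),
      ktv_daugirdas(R, t, UF, W)
    )
  }
})

test_that("Kt/V inversion round-trips through the forward formula", {
  set.seed(31)
  ktv <- stats::runif(40, 0.6, 2.2)
  t <- sample(c(3, 4), 40, replace = TRUE)
  UF <- stats::runif(40, 0, 4)
  W <- stats::runif(40, 45, 120)
  R <- ktv_invert(ktv, t, UF, W)
  expect_equal(ktv_daugirdas(R, t, UF, W), ktv, tolerance = 1e-6)
})

test_that("Maroni protein intake matches hand-derived values", {
  expect_equal(
    protein_intake_hd(135, 10, 3, 0, 78, 0)$intake_g,
    6.25 * (0.028 * (135 * 10 * 3 / 7) + 0.031 * 78)
  ) # 116.36
  expect_equal(round(protein_intake_hd(135, 10, 3, 0, 78, 0)$intake_g, 2), 116.36)
  expect_equal(round(protein_intake_hd(135, 10, 3, 100, 78, 0.7)$intake_g, 2), 134.56)
  expect_equal(protein_intake_hd(0, 0, 3, 0, 0, 0)$intake_g, 0)
  expect_equal(round(protein_intake_control(400, 77, 0)$intake_g, 2), 84.92)
  expect_equal(protein_intake_control(0, 0, 0)$intake_g, 0)
  expect_equal(round(protein_intake_control(400, 77, 0.5)$intake_g, 2), 85.42)
  expect_equal(
    protein_intake_hd(135, 10, 3, 50, 80, 0.5)$intake_g_kg,
    protein_intake_hd(135, 10, 3, 50, 80, 0.5)$intake_g / 80
  )
  expect_error(protein_intake_hd(135, -1, 3, 0, 78), "non-negative")
})

test_that("intradialytic change returns absolute and proportional components", {
  ch <- intradialytic_change(186, 148)
  expect_equal(ch$absolute, -38)
  expect_equal(round(ch$proportional, 1), -20.4)
  ch0 <- intradialytic_change(100, 100)
  expect_equal(ch0$absolute, 0)
  expect_equal(ch0$proportional, 0)
  expect_warning(chz <- intradialytic_change(0, 10), "undefined")
  expect_true(is.na(chz$proportional))
})

test_that("dialytic and fractional clearance match hand-derived values", {
  expect_equal(dialytic_clearance(135, 100, 4, 300, 200), 225)
  expect_equal(dialytic_clearance(135, 0, 4, 300, 200), 0)
  expect_equal(round(dialytic_clearance(120, 50, 4, 100, 80), 2), 277.78)
  expect_warning(out <- dialytic_clearance(135, 100, 4, 0, 0), "undefined")
  expect_true(is.na(out))
  # invariance under joint rescaling of dialysate and plasma concentrations
  set.seed(5)
  for (i in 1:20) {
    V <- stats::runif(1, 80, 200); D <- stats::runif(1, 1, 500)
    t <- stats::runif(1, 3, 5); p1 <- stats::runif(1, 10, 400)
    p2 <- stats::runif(1, 10, 400); k <- stats::runif(1, 0.1, 10)
    expect_equal(
      dialytic_clearance(V, k * D, t, k * p1, k * p2),
      dialytic_clearance(V, D, t, p1, p2),
      tolerance = 1e-12
    )
  }
  expect_equal(round(fractional_clearance(20, 137), 1), 14.6)
  expect_equal(fractional_clearance(137, 137), 100)
  expect_equal(fractional_clearance(0, 137), 0)
  expect_error(fractional_clearance(20, 0), "positive")
})

test_that("gram conversion uses free-molecule masses and is additive", {
  g <- losses_in_grams(c(glycine = 1000))
  expect_equal(unname(g$per_species["glycine"]), 0.07507)
  expect_equal(g$groups[["total"]], 0.07507)
  e <- losses_in_grams(stats::setNames(numeric(0), character(0)))
  expect_equal(e$groups[["total"]], 0)
  two <- losses_in_grams(c(glycine = 1000, taurine = 2000))
  expect_equal(
    two$groups[["total"]],
    losses_in_grams(c(glycine = 1000))$groups[["total"]] +
      losses_in_grams(c(taurine = 2000))$groups[["total"]]
  )
  expect_error(losses_in_grams(c(cysteine = 10)), "excluded")
})

test_that("percentage of intake and dialysis-to-urine ratio behave at the edges", {
  expect_equal(round(pct_of_protein_intake(4.0, 60), 2), 6.67)
  expect_equal(pct_of_protein_intake(0, 60), 0)
  expect_equal(round(pct_of_protein_intake(0.6, 84), 2), 0.71)
  expect_error(pct_of_protein_intake(4, 0), "positive")
  expect_equal(hd_to_urine_ratio(1320, 10), 132)
  expect_equal(hd_to_urine_ratio(55, 55), 1)
  expect_true(is.na(hd_to_urine_ratio(100, 0)))
})

test_that("every formula agrees with its single-expression oracle on random input", {
  set.seed(99)
  n <- 1000
  V <- stats::runif(n, 50, 250); D <- stats::runif(n, 0, 600)
  nw <- sample(c(2, 3), n, replace = TRUE); UE <- stats::runif(n, 0, 2000)
  expect_equal(daily_losses_hd(V, D, nw, UE), oracle_daily_hd(V, D, nw, UE),
    tolerance = 1e-9
  )
  Vu <- stats::runif(n, 0, 4); U <- stats::runif(n, 0, 800)
  expect_equal(daily_losses_control(Vu, U), oracle_daily_ctrl(Vu, U),
    tolerance = 1e-9
  )
  expect_equal(single_session_losses(V, D), oracle_session(V, D), tolerance = 1e-9)
  R <- stats::runif(n, 0.1, 0.95); t <- stats::runif(n, 2, 5)
  UF <- stats::runif(n, 0, 4); W <- stats::runif(n, 45, 130)
  expect_equal(ktv_daugirdas(R, t, UF, W), oracle_ktv(R, t, UF, W),
    tolerance = 1e-9
  )
  Du <- stats::runif(n, 1, 25); UUE <- stats::runif(n, 0, 500)
  UPE <- stats::runif(n, 0, 3)
  expect_equal(
    protein_intake_hd(V, Du, nw, UUE, W, UPE)$intake_g,
    oracle_intake_hd(V, Du, nw, UUE, W, UPE),
    tolerance = 1e-9
  )
  expect_equal(
    protein_intake_control(UUE, W, UPE)$intake_g,
    oracle_intake_ctrl(UUE, W, UPE),
    tolerance = 1e-9
  )
  p1 <- stats::runif(n, 5, 500); p2 <- stats::runif(n, 5, 500)
  expect_equal(
    dialytic_clearance(V, D, t, p1, p2),
    oracle_clearance(V, D, t, p1, p2),
    tolerance = 1e-9
  )
  cl <- stats::runif(n, 0, 250); clc <- stats::runif(n, 30, 250)
  expect_equal(fractional_clearance(cl, clc), oracle_fractional(cl, clc),
    tolerance = 1e-9
  )
})

test_that("cohort quantification conserves mass and closes group sums", {
  co <- tiny_cohort(seed = 3)
  q <- quantify_cohort(co)
  l <- q$losses
  expect_equal(l$daily_umol, l$dialytic_umol + l$urinary_umol)
  ps <- q$per_subject
  expect_equal(ps$loss_total_umol, ps$loss_essential_umol + ps$loss_non_essential_umol)
  expect_equal(ps$loss_total_g, ps$loss_essential_g + ps$loss_non_essential_g)
  expect_true(all(ps$loss_bcaa_umol <= ps$loss_essential_umol + 1e-9))
  # per-subject totals agree with the long table
  tot <- tapply(l$daily_umol, l$subject_id, sum)
  expect_equal(as.numeric(tot[ps$subject_id]), ps$loss_total_umol)
  # controls have no dialytic component and no Kt/V
  expect_true(all(l$dialytic_umol[l$arm == "control"] == 0))
  expect_true(all(is.na(ps$ktv[ps$arm == "control"])))
  expect_true(all(!is.na(ps$ktv[ps$arm == "hd"])))
})

test_that("a missing dialysate analyte is a hard error, not a silent zero", {
  co <- tiny_cohort(seed = 4)
  drop <- co$panels$compartment == "dialysate" & co$panels$analyte == "glycine" &
    co$panels$subject_id == "HD001"
  co$panels$value[drop] <- NA_real_
  expect_error(quantify_cohort(co), "missing dialysate")
})
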