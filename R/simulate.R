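#' Published cohort summary statistics used as generator targets
#'
#' Central values and dispersions of the per-analyte concentration and
#' daily-loss summaries for the hemodialysis and control arms, exactly as
#' displayed in the cohort comparison tables (plasma in µmol/L, daily
#' losses in µmol/24 h). Normal rows carry `mean`/`sd`; skewed rows carry
#' `median`/`q1`/`q3`. `central` is the displayed summary statistic (mean
#' if normal, median if skewed). These values parameterize
#' [default_config()] and are the inputs for recomputing the tables'
#' derived columns.
#'
#' @return A tibble: `analyte`, `quantity` (one of `plasma_hd`,
#'   `plasma_ctrl`, `loss_hd`, `loss_ctrl`), `dist`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `central`.
#' @export
reference_summaries <- function() {
  .reference_summaries
}

ref_row <- function(analyte, quantity, m = NA, s = NA, med = NA, q1 = NA, q3 = NA) {
  skewed <- is.na(m)
  tibble::tibble(
    analyte = analyte, quantity = quantity,
    dist = if (skewed) "skewed" else "normal",
    mean = m, sd = s, median = med, q1 = q1, q3 = q3,
    central = if (skewed) med else m
  )
}

.reference_summaries <- local({
  n <- function(a, m, s) list(a, m = m, s = s)
  sk <- function(a, med, q1, q3) list(a, med = med, q1 = q1, q3 = q3)
  build <- function(quantity, rows) {
    dplyr::bind_rows(lapply(rows, function(r) {
      do.call(ref_row, c(list(analyte = r[[1]], quantity = quantity), r[-1]))
    }))
  }
  plasma_hd <- build("plasma_hd", list(
    n("histidine", 69, 19), n("isoleucine", 63, 23), n("leucine", 103, 41),
    n("lysine", 141, 36), n("methionine", 19, 7), n("phenylalanine", 68, 22),
    n("threonine", 87, 29), sk("tryptophan", 22, 20, 28), n("valine", 186, 59),
    n("alanine", 351, 135), n("arginine", 77, 22), n("asparagine", 53, 16),
    sk("citrulline", 78, 61, 95), sk("glutamic acid", 101, 69, 161),
    n("glutamine", 514, 111), n("glycine", 260, 84), n("ornithine", 63, 20),
    sk("proline", 276, 223, 322), n("serine", 61, 19),
    sk("taurine", 58, 41, 87), n("tyrosine", 45, 16)
  ))
  plasma_ctrl <- build("plasma_ctrl", list(
    n("histidine", 74, 12), n("isoleucine", 61, 18), n("leucine", 110, 29),
    n("lysine", 171, 37), n("methionine", 21, 5), n("phenylalanine", 57, 9),
    n("threonine", 115, 24), sk("tryptophan", 54, 46, 57), n("valine", 213, 51),
    n("alanine", 423, 113), n("arginine", 78, 17), n("asparagine", 61, 11),
    sk("citrulline", 28, 24, 32), sk("glutamic acid", 57, 45, 81),
    n("glutamine", 575, 87), n("glycine", 202, 54), n("ornithine", 59, 16),
    sk("proline", 248, 197, 321), n("serine", 103, 19),
    sk("taurine", 40, 37, 50), n("tyrosine", 62, 18)
  ))
  loss_hd <- build("loss_hd", list(
    n("histidine", 862, 270), n("isoleucine", 799, 338), n("leucine", 1382, 587),
    sk("lysine", 1505, 1233, 1845), n("methionine", 172, 95),
    sk("phenylalanine", 729, 631, 967), sk("threonine", 1043, 731, 1279),
    n("tryptophan", 216, 63), sk("valine", 2017, 1606, 2614),
    n("alanine", 3926, 1548), n("arginine", 826, 377), n("asparagine", 747, 290),
    sk("citrulline", 463, 347, 570), n("glutamic acid", 966, 559),
    n("glutamine", 6954, 2410), n("glycine", 3502, 1271), n("ornithine", 541, 194),
    n("proline", 3601, 1351), sk("serine", 754, 572, 1004),
    sk("taurine", 132, 24, 235), n("tyrosine", 462, 192)
  ))
  loss_ctrl <- build("loss_ctrl", list(
    n("histidine", 698, 463), n("isoleucine", 12, 7), n("leucine", 67, 23),
    sk("lysine", 209, 157, 288), n("methionine", 5, 2),
    sk("phenylalanine", 68, 52, 103), sk("threonine", 105, 81, 161),
    n("tryptophan", 148, 57), sk("valine", 42, 35, 54),
    n("alanine", 361, 219), n("arginine", 34, 15), n("asparagine", 122, 82),
    sk("citrulline", 11, 7, 13), n("glutamic acid", 35, 33),
    n("glutamine", 449, 211), n("glycine", 1521, 848), n("ornithine", 22, 17),
    n("proline", 8, 5), sk("serine", 324, 236, 467),
    sk("taurine", 339, 204, 668), n("tyrosine", 105, 68)
  ))
  dplyr::bind_rows(plasma_hd, plasma_ctrl, loss_hd, loss_ctrl)
})

#' Intradialytic proportional-change targets
#'
#' Per-analyte mean proportional change of the predialysis plasma
#' concentration during a session (percent), as displayed in the pre/post
#' comparison table. Used by the generator to derive postdialysis plasma
#' from predialysis plasma.
#'
#' @return A tibble: `analyte`, `change_pct`.
#' @export
intradialytic_targets <- function() {
  tibble::tibble(
    analyte = c(
      "histidine", "isoleucine", "leucine", "lysine", "methionine",
      "phenylalanine", "threonine", "tryptophan", "valine",
      "alanine", "arginine", "asparagine", "citrulline", "glutamic acid",
      "glutamine", "glycine", "ornithine", "proline", "serine", "taurine",
      "tyrosine"
    ),
    change_pct = c(
      -22, 17, 20, -5, 5, -4, -8, 23, -20,
      -28, -22, -6, -54, 2, -11, -22, -19, -12, -2, -29, 0
    )
  )
}

# lognormal parameters from moment / quartile matching
lnorm_from_mean_sd <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}
lnorm_from_quartiles <- function(med, q1, q3) {
  list(mu = log(med), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}
lnorm_params <- function(ref_rows) {
  out <- lapply(seq_len(nrow(ref_rows)), function(i) {
    r <- ref_rows[i, ]
    if (r$dist == "normal") {
      lnorm_from_mean_sd(r$mean, r$sd)
    } else {
      lnorm_from_quartiles(r$median, r$q1, r$q3)
    }
  })
  list(
    mu = vapply(out, `[[`, numeric(1), "mu"),
    sigma = vapply(out, `[[`, numeric(1), "sigma"),
    analyte = ref_rows$analyte
  )
}

# n x K lognormal draws with exchangeable Gaussian-copula correlation rho
rlnorm_panel <- function(n, params, rho) {
  K <- length(params$mu)
  z0 <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * K), n, K)
  z <- sqrt(rho) * z0 + sqrt(1 - rho) * e
  x <- exp(sweep(sweep(z, 2, params$sigma, `*`), 2, params$mu, `+`))
  colnames(x) <- params$analyte
  x
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Default synthetic-cohort configuration
#'
#' Study conditions of the emulated cohort: 59 hemodialysis patients and 33
#' controls; per-analyte log-normal concentration models moment-matched to
#' the published plasma and daily-loss summaries; a session model
#' (dialysate volume ~ N(135, 27) L, 95% thrice-weekly, ultrafiltration ~
#' N(1.9, 0.9) L, Kt/V target ~ N(1.4, 0.3), 81% four-hour sessions);
#' residual-diuresis prevalence 0.54 with urine volume ~ N(0.9, 0.6) L
#' truncated above 0.2 L; and a fatigue model
#' `logit P(severe) = alpha + log(0.64) * log2(taurine loss)
#'  + log(2.97) * z(plasma proline) + log(0.18) * z(protein intake)`
#' with the intercept calibrated to a severe-fatigue prevalence of 20/59.
#'
#' @param n_hd,n_ctrl Cohort sizes.
#' @param seed RNG seed; the same configuration yields an identical cohort.
#' @param rho Exchangeable between-analyte copula correlation within a
#'   compartment.
#' @param or_taurine_log2 True odds ratio of severe fatigue per doubling of
#'   the daily taurine loss.
#' @param or_proline_sd True odds ratio per population-SD of predialysis
#'   plasma proline.
#' @param or_protein_sd True odds ratio per population-SD of protein intake.
#' @param fatigue_prevalence Target severe-fatigue prevalence among
#'   hemodialysis patients.
#' @return A list of class `aa_generator_config`.
#' @export
default_config <- function(n_hd = 59, n_ctrl = 33, seed = 1L, rho = 0.3,
                           or_taurine_log2 = 0.64, or_proline_sd = 2.97,
                           or_protein_sd = 0.18, fatigue_prevalence = 20 / 59) {
  stopifnot(
    n_hd >= 1, n_ctrl >= 0, rho >= 0, rho < 1,
    or_taurine_log2 > 0, or_proline_sd > 0, or_protein_sd > 0,
    fatigue_prevalence > 0, fatigue_prevalence < 1
  )
  structure(list(
    n_hd = as.integer(n_hd), n_ctrl = as.integer(n_ctrl),
    seed = as.integer(seed), rho = rho,
    summaries = reference_summaries(),
    changes = intradialytic_targets(),
    change_noise_sd = 0.12, # relative intradialytic noise around the target
    session = list(
      v_dialysate_mean = 135, v_dialysate_sd = 27,
      p_thrice_weekly = 0.95, p_four_hours = 0.81,
      uf_mean = 1.9, uf_sd = 0.9,
      ktv_mean = 1.4, ktv_sd = 0.3,
      weight_post_mean = 78, weight_post_sd = 16
    ),
    diuresis = list(prevalence = 0.54, vol_mean = 0.9, vol_sd = 0.6, vol_min = 0.2),
    urinary_scale = 0.35, # HD residual urinary AA excretion vs control kidneys
    intake = list(
      hd_mean = 64, hd_sd = 21, ctrl_mean = 84, ctrl_sd = 21,
      upe_median = 0.7, upe_q1 = 0.3, upe_q3 = 1.3
    ),
    creatinine = list(
      plasma_mean = 800, plasma_sd = 200,
      clearance_mean = 137, clearance_sd = 68
    ),
    demographics = list(
      hd = list(
        age_mean = 65, age_sd = 15, p_male = 0.63,
        height_mean = 1.75, height_sd = 0.09,
        vintage_median = 15, vintage_q1 = 6, vintage_q3 = 39,
        hemoglobin_mean = 6.9, hemoglobin_sd = 0.7,
        crp_median = 5, crp_q1 = 2, crp_q3 = 12,
        p_cvd = 0.40, p_diabetes = 0.25
      ),
      ctrl = list(
        age_mean = 54, age_sd = 10, p_male = 0.45,
        height_mean = 1.72, height_sd = 0.10,
        weight_mean = 77, weight_sd = 17,
        urine_vol_mean = 2.5, urine_vol_sd = 0.9,
        hemoglobin_mean = 8.8, hemoglobin_sd = 0.8
      )
    ),
    fatigue = list(
      beta_taurine_log2 = log(or_taurine_log2),
      beta_proline_sd = log(or_proline_sd),
      beta_protein_sd = log(or_protein_sd),
      prevalence = fatigue_prevalence
    )
  ), class = "aa_generator_config")
}

#' True simulated effect sizes of a configuration
#'
#' Exposes the generating coefficients and distribution parameters for test
#' assertions, without generating data.
#'
#' @param config An `aa_generator_config`.
#' @return A list: fatigue-model log-odds coefficients (per log2 of taurine
#'   loss, per SD of plasma proline, per SD of protein intake), the target
#'   prevalence, and the per-analyte lognormal parameters by quantity.
#' @export
ground_truth <- function(config = default_config()) {
  stopifnot(inherits(config, "aa_generator_config"))
  by_q <- split(config$summaries, config$summaries$quantity)
  list(
    beta_taurine_log2 = config$fatigue$beta_taurine_log2,
    beta_proline_sd = config$fatigue$beta_proline_sd,
    beta_protein_sd = config$fatigue$beta_protein_sd,
    fatigue_prevalence = config$fatigue$prevalence,
    change_pct = config$changes,
    lnorm = lapply(by_q, lnorm_params),
    n_hd = config$n_hd, n_ctrl = config$n_ctrl, seed = config$seed
  )
}

#' Generate a synthetic dialysis cohort
#'
#' Draws an internally consistent cohort under `config`: predialysis plasma
#' panels and total daily-loss targets are sampled from the configured
#' log-normal models; postdialysis plasma is the predialysis value moved by
#' the configured intradialytic proportional change plus noise; dialysate
#' concentrations are back-solved from the loss targets (so the mass-balance
#' identity holds exactly); the urea ratio is the inversion of the Daugirdas
#' formula at the sampled Kt/V target; dialysate urea is back-solved from
#' the sampled protein-intake target via the Maroni formula; and the severe
#' fatigue flag is drawn from the configured logistic model with the
#' intercept calibrated so the expected prevalence matches the target.
#'
#' @param config An `aa_generator_config` from [default_config()].
#' @return A list of class `aa_cohort`: tibbles `subjects`, `sessions`,
#'   `urine`, `panels`, plus `truth` (see [ground_truth()]) and the
#'   calibrated fatigue intercept `alpha`.
#' @export
generate_cohort <- function(config = default_config()) {
  stopifnot(inherits(config, "aa_generator_config"))
  set.seed(config$seed)
  species <- aa_names()
  sm <- config$summaries
  par_plasma_hd <- lnorm_params(sm[sm$quantity == "plasma_hd", ])
  par_plasma_ctrl <- lnorm_params(sm[sm$quantity == "plasma_ctrl", ])
  par_loss_hd <- lnorm_params(sm[sm$quantity == "loss_hd", ])
  par_loss_ctrl <- lnorm_params(sm[sm$quantity == "loss_ctrl", ])

  n_hd <- config$n_hd
  n_ctrl <- config$n_ctrl
  dm <- config$demographics
  ses_cfg <- config$session

  ## --- hemodialysis arm ----------------------------------------------
  hd_ids <- sprintf("HD%03d", seq_len(n_hd))
  age <- rnorm_trunc(n_hd, dm$hd$age_mean, dm$hd$age_sd, 18, 95)
  sex <- ifelse(stats::runif(n_hd) < dm$hd$p_male, "male", "female")
  height <- rnorm_trunc(n_hd, dm$hd$height_mean, dm$hd$height_sd, 1.4, 2.1)
  weight_post <- rnorm_trunc(
    n_hd, ses_cfg$weight_post_mean, ses_cfg$weight_post_sd, 40, 140
  )
  vint_par <- lnorm_from_quartiles(
    dm$hd$vintage_median, dm$hd$vintage_q1, dm$hd$vintage_q3
  )
  vintage <- stats::rlnorm(n_hd, vint_par$mu, vint_par$sigma)
  hemoglobin <- rnorm_trunc(n_hd, dm$hd$hemoglobin_mean, dm$hd$hemoglobin_sd, 3, 12)
  crp_par <- lnorm_from_quartiles(dm$hd$crp_median, dm$hd$crp_q1, dm$hd$crp_q3)
  crp <- stats::rlnorm(n_hd, crp_par$mu, crp_par$sigma)
  cvd <- stats::runif(n_hd) < dm$hd$p_cvd
  diabetes <- stats::runif(n_hd) < dm$hd$p_diabetes

  v_dial <- rnorm_trunc(n_hd, ses_cfg$v_dialysate_mean, ses_cfg$v_dialysate_sd, 40, 260)
  n_per_week <- ifelse(stats::runif(n_hd) < ses_cfg$p_thrice_weekly, 3, 2)
  duration <- ifelse(stats::runif(n_hd) < ses_cfg$p_four_hours, 4, 3)
  uf <- rnorm_trunc(n_hd, ses_cfg$uf_mean, ses_cfg$uf_sd, 0, 5)
  ktv_target <- rnorm_trunc(n_hd, ses_cfg$ktv_mean, ses_cfg$ktv_sd, 0.5, 2.6)
  urea_ratio <- ktv_invert(ktv_target, duration, uf, weight_post)

  has_diuresis <- stats::runif(n_hd) < config$diuresis$prevalence
  urine_vol <- rnorm_trunc(
    n_hd, config$diuresis$vol_mean, config$diuresis$vol_sd,
    config$diuresis$vol_min + 1e-6, 4
  )
  urine_vol[!has_diuresis] <- 0

  # plasma panels
  plasma_pre <- rlnorm_panel(n_hd, par_plasma_hd, config$rho)
  chg <- config$changes
  delta <- chg$change_pct[match(colnames(plasma_pre), chg$analyte)] / 100
  eps <- matrix(
    stats::rnorm(n_hd * ncol(plasma_pre), 0, config$change_noise_sd),
    n_hd, ncol(plasma_pre)
  )
  plasma_post <- plasma_pre * pmax(1 + rep(delta, each = n_hd) + eps, 0.02)

  # total daily-loss targets and their dialytic/urinary split
  loss_total <- rlnorm_panel(n_hd, par_loss_hd, config$rho)
  urinary <- rlnorm_panel(n_hd, par_loss_ctrl, config$rho) *
    config$urinary_scale * (urine_vol / dm$ctrl$urine_vol_mean)
  urinary[!has_diuresis, ] <- 0
  over <- urinary > 0.5 * loss_total
  urinary[over] <- 0.5 * loss_total[over]
  dialytic <- loss_total - urinary
  d_conc <- dialytic * 7 / (n_per_week * v_dial) # back-solved dialysate panel
  u_conc <- urinary / ifelse(urine_vol > 0, urine_vol, NA_real_)
  u_conc[!has_diuresis, ] <- 0

  # protein intake via back-solved urea appearance
  intake_target <- rnorm_trunc(n_hd, config$intake$hd_mean, config$intake$hd_sd, 25, 140)
  upe_par <- lnorm_from_quartiles(
    config$intake$upe_median, config$intake$upe_q1, config$intake$upe_q3
  )
  upe <- stats::rlnorm(n_hd, upe_par$mu, upe_par$sigma)
  upe[!has_diuresis] <- 0
  urea_appearance <- ((intake_target - upe) / 6.25 - 0.031 * weight_post) / 0.028
  urea_appearance <- pmax(urea_appearance, 20)
  uue_frac <- stats::runif(n_hd, 0.05, 0.30)
  uue <- ifelse(has_diuresis, urea_appearance * uue_frac, 0)
  dialysate_urea <- (urea_appearance - uue) * 7 / (n_per_week * v_dial)

  # creatinine: plasma sampled, dialysate back-solved from a clearance target
  creat_pre <- rnorm_trunc(
    n_hd, config$creatinine$plasma_mean, config$creatinine$plasma_sd, 250, 1600
  )
  creat_ratio <- pmin(pmax(urea_ratio + stats::rnorm(n_hd, 0, 0.05), 0.15), 0.85)
  creat_post <- creat_pre * creat_ratio
  cl_target <- rnorm_trunc(
    n_hd, config$creatinine$clearance_mean, config$creatinine$clearance_sd, 40, 350
  )
  creat_dial <- cl_target / (1000 / 60) * ((creat_pre + creat_post) / 2) *
    duration / v_dial

  # fatigue outcome
  tau_loss <- loss_total[, "taurine"]
  pro_pre <- plasma_pre[, "proline"]
  pro_par <- lnorm_params(sm[sm$quantity == "plasma_hd" & sm$analyte == "proline", ])
  pro_mean <- exp(pro_par$mu + pro_par$sigma^2 / 2)
  pro_sd <- pro_mean * sqrt(exp(pro_par$sigma^2) - 1)
  tau_par <- lnorm_params(sm[sm$quantity == "loss_hd" & sm$analyte == "taurine", ])
  fb <- config$fatigue
  eta <- fb$beta_taurine_log2 * (log2(tau_loss) - tau_par$mu / log(2)) +
    fb$beta_proline_sd * (pro_pre - pro_mean) / pro_sd +
    fb$beta_protein_sd * (intake_target - config$intake$hd_mean) / config$intake$hd_sd
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - fb$prevalence,
    c(-30, 30), tol = 1e-10
  )$root
  severe <- stats::runif(n_hd) < stats::plogis(alpha + eta)
  cis_fatigue <- ifelse(
    severe, 35 + floor(stats::runif(n_hd) * 22), 8 + floor(stats::runif(n_hd) * 27)
  )

  subjects_hd <- tibble::tibble(
    subject_id = hd_ids, arm = "hd", age = age, sex = sex,
    height = height, weight = weight_post + uf, # predialysis weight
    bmi = weight_post / height^2, vintage = vintage,
    hemoglobin = hemoglobin, crp = crp, cvd = cvd, diabetes = diabetes,
    cis_fatigue = as.numeric(cis_fatigue)
  )
  sessions <- tibble::tibble(
    subject_id = hd_ids, v_dialysate = v_dial, duration_h = duration,
    n_per_week = n_per_week, uf_volume = uf, weight_post = weight_post,
    dialysate_urea = dialysate_urea, urea_ratio = urea_ratio
  )
  urine_hd <- tibble::tibble(
    subject_id = hd_ids[has_diuresis], volume = urine_vol[has_diuresis],
    urea = uue[has_diuresis], protein = upe[has_diuresis],
    n_collections = 2L
  )

  long_panel <- function(mat, ids, compartment, unit = "umol/L") {
    tibble::tibble(
      subject_id = rep(ids, times = ncol(mat)),
      compartment = compartment,
      analyte = rep(colnames(mat), each = length(ids)),
      value = as.numeric(mat), unit = unit
    )
  }
  panels_hd <- dplyr::bind_rows(
    long_panel(plasma_pre, hd_ids, "plasma_pre"),
    long_panel(plasma_post, hd_ids, "plasma_post"),
    long_panel(d_conc, hd_ids, "dialysate"),
    long_panel(
      u_conc[has_diuresis, , drop = FALSE], hd_ids[has_diuresis], "urine"
    ),
    tibble::tibble(
      subject_id = rep(hd_ids, 3),
      compartment = rep(c("plasma_pre", "plasma_post", "dialysate"), each = n_hd),
      analyte = "creatinine",
      value = c(creat_pre, creat_post, creat_dial), unit = "umol/L"
    )
  )

  ## --- control arm ----------------------------------------------------
  if (n_ctrl > 0) {
    ct_ids <- sprintf("CT%03d", seq_len(n_ctrl))
    ct_age <- rnorm_trunc(n_ctrl, dm$ctrl$age_mean, dm$ctrl$age_sd, 18, 85)
    ct_sex <- ifelse(stats::runif(n_ctrl) < dm$ctrl$p_male, "male", "female")
    ct_height <- rnorm_trunc(n_ctrl, dm$ctrl$height_mean, dm$ctrl$height_sd, 1.4, 2.1)
    ct_weight <- rnorm_trunc(n_ctrl, dm$ctrl$weight_mean, dm$ctrl$weight_sd, 40, 140)
    ct_hb <- rnorm_trunc(n_ctrl, dm$ctrl$hemoglobin_mean, dm$ctrl$hemoglobin_sd, 5, 12)
    ct_plasma <- rlnorm_panel(n_ctrl, par_plasma_ctrl, config$rho)
    ct_loss <- rlnorm_panel(n_ctrl, par_loss_ctrl, config$rho)
    ct_vol <- rnorm_trunc(
      n_ctrl, dm$ctrl$urine_vol_mean, dm$ctrl$urine_vol_sd, 0.5, 5
    )
    ct_uconc <- ct_loss / ct_vol
    ct_intake <- rnorm_trunc(
      n_ctrl, config$intake$ctrl_mean, config$intake$ctrl_sd, 30, 160
    )
    ct_upe <- stats::rlnorm(n_ctrl, log(0.05), 0.5) # physiological proteinuria
    ct_uue <- pmax((ct_intake - ct_upe) / 6.25 - 0.031 * ct_weight, 1) / 0.028

    subjects_ct <- tibble::tibble(
      subject_id = ct_ids, arm = "control", age = ct_age, sex = ct_sex,
      height = ct_height, weight = ct_weight, bmi = ct_weight / ct_height^2,
      vintage = NA_real_, hemoglobin = ct_hb, crp = NA_real_,
      cvd = FALSE, diabetes = FALSE, cis_fatigue = NA_real_
    )
    urine_ct <- tibble::tibble(
      subject_id = ct_ids, volume = ct_vol, urea = ct_uue, protein = ct_upe,
      n_collections = 1L
    )
    panels_ct <- dplyr::bind_rows(
      long_panel(ct_plasma, ct_ids, "plasma_pre"),
      long_panel(ct_uconc, ct_ids, "urine")
    )
  } else {
    subjects_ct <- subjects_hd[0, ]
    urine_ct <- urine_hd[0, ]
    panels_ct <- panels_hd[0, ]
  }

  structure(list(
    subjects = dplyr::bind_rows(subjects_hd, subjects_ct),
    sessions = sessions,
    urine = dplyr::bind_rows(urine_hd, urine_ct),
    panels = dplyr::bind_rows(panels_hd, panels_ct),
    truth = ground_truth(config),
    alpha = alpha,
    config = config
  ), class = "aa_cohort")
}

#' @export
print.aa_cohort <- function(x, ...) {
  n_hd <- sum(x$subjects$arm == "hd")
  n_ct <- sum(x$subjects$arm == "control")
  cat(
    "<aa_cohort>", n_hd, "hemodialysis patients,", n_ct, "controls;",
    length(unique(x$panels$analyte)), "analytes; seed", x$config$seed, "\n"
  )
  invisible(x)
}
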