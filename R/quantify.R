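#' @importFrom rlang .data
NULL

# Unit contracts throughout this file:
#   volumes L, durations hours, weights kg, amino acids µmol/L,
#   urea mmol/L (dialysate) or mmol/24 h (urinary excretion),
#   urinary protein g/24 h. No unit inference is attempted.

check_nonneg <- function(..., .what = NULL) {
  vals <- list(...)
  nms <- if (is.null(.what)) names(vals) else .what
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(nms[i], " must be finite and non-negative", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Daily amino-acid losses of a hemodialysis patient
#'
#' Total daily loss of one amino acid by dialysis and residual kidney
#' function: the week's dialytic removal averaged per day plus the 24-h
#' urinary excretion,
#' `(v_dialysate * d_conc * n_per_week) / 7 + urinary_excretion`.
#'
#' @param v_dialysate Total spent dialysate volume of the session, L.
#' @param d_conc Concentration of the amino acid in the pooled dialysate,
#'   µmol/L.
#' @param n_per_week Number of dialysis sessions per week (2 or 3).
#' @param urinary_excretion 24-h urinary excretion of the amino acid,
#'   µmol/24 h (0 for anuric patients, i.e. no urine collection).
#' @return Daily loss in µmol/24 h.
#' @export
#' @examples
#' daily_losses_hd(135, 20, 3, 100) # 8100/7 + 100
daily_losses_hd <- function(v_dialysate, d_conc, n_per_week, urinary_excretion = 0) {
  if (any(is.na(d_conc))) {
    stop("missing dialysate concentration; refusing to treat as zero",
      call. = FALSE
    )
  }
  check_nonneg(
    v_dialysate = v_dialysate, d_conc = d_conc,
    urinary_excretion = urinary_excretion
  )
  stopifnot(all(n_per_week %in% c(2, 3)))
  (v_dialysate * d_conc * n_per_week) / 7 + urinary_excretion
}

#' Daily amino-acid losses of a control subject
#'
#' Urinary excretion from a single 24-h collection:
#' `volume * concentration`.
#'
#' @param v_urine 24-h urine volume, L.
#' @param u_conc Urinary amino-acid concentration, µmol/L.
#' @return Daily loss in µmol/24 h.
#' @export
daily_losses_control <- function(v_urine, u_conc) {
  check_nonneg(v_urine = v_urine, u_conc = u_conc)
  v_urine * u_conc
}

#' Amino-acid losses during a single dialysis session
#'
#' Dialytic removal of one session, `v_dialysate * d_conc`, with no weekly
#' averaging and no urinary term.
#'
#' @inheritParams daily_losses_hd
#' @return Loss in µmol/session.
#' @export
single_session_losses <- function(v_dialysate, d_conc) {
  if (any(is.na(d_conc))) {
    stop("missing dialysate concentration; refusing to treat as zero",
      call. = FALSE
    )
  }
  check_nonneg(v_dialysate = v_dialysate, d_conc = d_conc)
  v_dialysate * d_conc
}

#' Single-pool Kt/V (Daugirdas)
#'
#' Dialysis-adequacy dose from the second-generation Daugirdas formula,
#' `-ln(R - 0.008 t) + (4 - 3.5 R) * UF / W`, where `R` is the post/pre
#' plasma urea ratio, `t` the session duration in hours, `UF` the
#' ultrafiltration volume in L and `W` the post-dialysis weight in kg.
#'
#' @param R Post/pre dialysis plasma urea ratio, in (0, 1].
#' @param t Session duration, hours.
#' @param UF Ultrafiltration volume, L.
#' @param W Post-dialysis body weight, kg.
#' @return Dimensionless Kt/V.
#' @export
#' @examples
#' ktv_daugirdas(R = 0.3, t = 4, UF = 2, W = 78)
ktv_daugirdas <- function(R, t, UF, W) {
  check_nonneg(t = t, UF = UF)
  if (any(R <= 0) || any(R > 1)) {
    stop("urea ratio R must lie in (0, 1]", call. = FALSE)
  }
  if (any(W <= 0)) stop("post-dialysis weight must be positive", call. = FALSE)
  arg <- R - 0.008 * t
  if (any(arg <= 0)) {
    stop("R - 0.008 * t must be positive (log-domain)", call. = FALSE)
  }
  -log(arg) + (4 - 3.5 * R) * UF / W
}

#' Invert the Daugirdas formula for the urea ratio
#'
#' Finds the post/pre urea ratio `R` that yields a target Kt/V at given
#' session parameters. Used by the cohort generator so that simulated urea
#' ratios and adequacy targets are mutually consistent.
#'
#' @param ktv Target Kt/V (> 0).
#' @inheritParams ktv_daugirdas
#' @return The urea ratio R in (0.008 t, 1].
#' @export
ktv_invert <- function(ktv, t, UF, W) {
  stopifnot(length(ktv) == length(t) || length(t) == 1L)
  f <- function(ktv1, t1, UF1, W1) {
    lo <- 0.008 * t1 + 1e-9
    g <- function(R) ktv_daugirdas(R, t1, UF1, W1) - ktv1
    if (g(1) > 0) {
      return(1)
    } # Kt/V below the no-removal bound: saturate at R = 1
    stats::uniroot(g, c(lo + 1e-9, 1), tol = 1e-12)$root
  }
  mapply(f, ktv, t, UF, W)
}

#' Dietary protein intake from urea kinetics (Maroni), dialysis variant
#'
#' `6.25 * (0.028 * ((v_dialysate * d_urea * n)/7 + uue) + 0.031 * weight)
#'  + upe`: total urea appearance (dialytic + urinary, mmol/24 h) converted
#' to nitrogen, plus non-urea nitrogen proportional to body weight, times
#' 6.25 g protein per g nitrogen, plus urinary protein losses.
#'
#' @param v_dialysate Spent dialysate volume, L.
#' @param d_urea Urea concentration in pooled dialysate, mmol/L.
#' @param n_per_week Dialysis sessions per week (2 or 3).
#' @param uue 24-h urinary urea excretion, mmol/24 h (0 if anuric).
#' @param weight Post-dialysis body weight, kg.
#' @param upe 24-h urinary protein excretion, g/24 h (0 if anuric).
#' @return A list with `intake_g` (g/24 h) and `intake_g_kg` (g/kg/24 h).
#' @export
protein_intake_hd <- function(v_dialysate, d_urea, n_per_week, uue, weight, upe = 0) {
  check_nonneg(
    v_dialysate = v_dialysate, d_urea = d_urea, uue = uue,
    weight = weight, upe = upe
  )
  stopifnot(all(n_per_week %in% c(2, 3)))
  g <- 6.25 * (0.028 * ((v_dialysate * d_urea * n_per_week) / 7 + uue) +
    0.031 * weight) + upe
  list(intake_g = g, intake_g_kg = ifelse(weight > 0, g / weight, NA_real_))
}

#' Dietary protein intake (Maroni), control variant
#'
#' `6.25 * (0.028 * uue + 0.031 * weight) + upe` from a single 24-h urine
#' collection.
#'
#' @inheritParams protein_intake_hd
#' @export
protein_intake_control <- function(uue, weight, upe = 0) {
  check_nonneg(uue = uue, weight = weight, upe = upe)
  g <- 6.25 * (0.028 * uue + 0.031 * weight) + upe
  list(intake_g = g, intake_g_kg = ifelse(weight > 0, g / weight, NA_real_))
}

#' Intradialytic change in a plasma concentration
#'
#' Absolute change is post minus pre (µmol/L); proportional change is the
#' absolute change divided by the predialysis concentration, in percent.
#'
#' @param pre,post Plasma concentration before / after the session, µmol/L.
#' @return A list with `absolute` (µmol/L) and `proportional` (%;
#'   `NA` with a warning when `pre` is 0).
#' @export
#' @examples
#' intradialytic_change(pre = 186, post = 148)
intradialytic_change <- function(pre, post) {
  check_nonneg(pre = pre, post = post)
  absolute <- post - pre
  proportional <- ifelse(pre > 0, absolute / pre * 100, NA_real_)
  if (any(pre == 0)) {
    warning("proportional change undefined for zero predialysis concentration")
  }
  list(absolute = absolute, proportional = proportional)
}

#' Dialytic clearance of a solute
#'
#' Total dialysate recovery over the session divided by the mean plasma
#' concentration, converted from L/h to mL/min:
#' `((v_dialysate * d_conc)/t) / ((p_pre + p_post)/2) * (1000/60)`.
#' Applies to amino acids and to creatinine alike (same units, µmol/L).
#'
#' @param v_dialysate Spent dialysate volume, L.
#' @param d_conc Dialysate concentration, µmol/L.
#' @param t Session duration, hours.
#' @param p_pre,p_post Plasma concentration before / after the session,
#'   µmol/L.
#' @return Clearance in mL/min (`NA` with a warning if the mean plasma
#'   concentration is 0).
#' @export
dialytic_clearance <- function(v_dialysate, d_conc, t, p_pre, p_post) {
  check_nonneg(
    v_dialysate = v_dialysate, d_conc = d_conc,
    p_pre = p_pre, p_post = p_post
  )
  if (any(t <= 0)) stop("session duration must be positive", call. = FALSE)
  pbar <- (p_pre + p_post) / 2
  out <- ifelse(pbar > 0, ((v_dialysate * d_conc) / t) / pbar * (1000 / 60),
    NA_real_
  )
  if (any(pbar == 0)) {
    warning("clearance undefined for zero mean plasma concentration")
  }
  out
}

#' Fractional clearance relative to creatinine
#'
#' A solute's dialytic clearance as a percentage of the simultaneous dialytic
#' creatinine clearance; values well below 100% suggest protein binding or
#' compartmental sequestration.
#'
#' @param cl_species,cl_creatinine Clearances in mL/min.
#' @return Percentage.
#' @export
fractional_clearance <- function(cl_species, cl_creatinine) {
  check_nonneg(cl_species = cl_species)
  if (any(cl_creatinine <= 0)) {
    stop("creatinine clearance must be positive", call. = FALSE)
  }
  cl_species / cl_creatinine * 100
}

#' Convert micromolar losses to grams
#'
#' Multiplies per-species daily losses (µmol/24 h) by the free-molecule
#' molecular mass and 1e-6 to obtain g/24 h, and sums into groups.
#'
#' @param per_species Named numeric vector of losses, µmol/24 h, keyed by
#'   reported amino-acid names.
#' @return A list with `per_species` (named g/24 h vector) and `groups`
#'   (named vector: `bcaa`, `essential`, `non_essential`, `total`, g/24 h).
#' @export
#' @examples
#' losses_in_grams(c(glycine = 1000))
losses_in_grams <- function(per_species) {
  stopifnot(is.numeric(per_species))
  if (length(per_species) == 0L) {
    z <- c(bcaa = 0, essential = 0, non_essential = 0, total = 0)
    return(list(per_species = numeric(0), groups = z))
  }
  nm <- aa_canonicalize(names(per_species))
  reg <- aa_registry()
  if (any(!reg$reported[match(nm, reg$name)])) {
    stop("excluded analyte: ",
      paste(nm[!reg$reported[match(nm, reg$name)]], collapse = ", "),
      call. = FALSE
    )
  }
  mass <- reg$mol_mass[match(nm, reg$name)]
  grams <- as.numeric(per_species) * mass * 1e-6
  names(grams) <- nm
  list(per_species = grams, groups = aa_group_sums(grams))
}

#' Losses as a percentage of protein intake
#'
#' @param loss_g Daily amino-acid loss, g/24 h.
#' @param intake_g Daily protein intake, g/24 h (> 0).
#' @return Percentage of intake.
#' @export
pct_of_protein_intake <- function(loss_g, intake_g) {
  check_nonneg(loss_g = loss_g)
  if (any(intake_g <= 0)) {
    stop("protein intake must be positive", call. = FALSE)
  }
  loss_g / intake_g * 100
}

#' Ratio of dialytic to urinary daily losses
#'
#' Defined only for subjects with residual diuresis and a positive urinary
#' component; others are excluded (NA), never mapped to infinity.
#'
#' @param dialytic_daily Dialytic component of the daily loss, µmol/24 h.
#' @param urinary_daily Urinary component, µmol/24 h.
#' @return Ratio, or `NA` where `urinary_daily` is 0.
#' @export
hd_to_urine_ratio <- function(dialytic_daily, urinary_daily) {
  check_nonneg(dialytic_daily = dialytic_daily, urinary_daily = urinary_daily)
  ifelse(urinary_daily > 0, dialytic_daily / urinary_daily, NA_real_)
}

#' Per-subject quantification of a cohort
#'
#' Runs the full mass-balance pipeline over a cohort (see
#' [generate_cohort()] or [read_cohort()]): daily per-species losses, group
#' sums in µmol and grams, single-session losses, Kt/V, protein intake, and
#' the percentage of intake lost.
#'
#' Hemodialysis subjects without a urine collection (anuric, residual
#' diuresis at or below 0.2 L/24 h) contribute zero urinary amino acid,
#' urea and protein terms.
#'
#' @param cohort An `aa_cohort` list (tibbles `subjects`, `sessions`,
#'   `urine`, `panels`).
#' @return A list with `per_subject` (one row per subject: Kt/V, protein
#'   intake, group losses in µmol and g, `pct_of_intake`) and `losses`
#'   (long tibble: subject, species, daily loss, dialytic and urinary
#'   components).
#' @export
quantify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "aa_cohort"))
  species <- aa_names()
  subjects <- cohort$subjects
  sessions <- cohort$sessions
  urine <- cohort$urine
  panels <- cohort$panels

  uidx <- match(subjects$subject_id, urine$subject_id)
  u_vol <- ifelse(is.na(uidx), 0, urine$volume[uidx])
  has_urine <- !is.na(uidx) & u_vol > 0.2
  u_urea <- ifelse(has_urine, urine$urea[uidx], 0)
  u_prot <- ifelse(has_urine, urine$protein[uidx], 0)

  hd <- subjects$arm == "hd"
  sidx <- match(subjects$subject_id, sessions$subject_id)
  if (any(hd & is.na(sidx))) {
    stop("missing dialysis session for subject ",
      paste(subjects$subject_id[hd & is.na(sidx)], collapse = ", "),
      call. = FALSE
    )
  }
  ctrl_no_urine <- !hd & !has_urine
  if (any(ctrl_no_urine)) {
    stop("control subject lacks a urine collection: ",
      paste(subjects$subject_id[ctrl_no_urine], collapse = ", "),
      call. = FALSE
    )
  }

  # wide per-subject concentration matrices (rows aligned to subjects)
  wide_of <- function(compartment) {
    p <- panels[panels$compartment == compartment & panels$analyte %in% species, ]
    w <- tidyr::pivot_wider(p[, c("subject_id", "analyte", "value")],
      names_from = "analyte", values_from = "value"
    )
    w[match(subjects$subject_id, w$subject_id), , drop = FALSE]
  }
  dial_w <- wide_of("dialysate")
  urine_w <- wide_of("urine")

  miss_d <- setdiff(species, names(dial_w))
  dial_m <- as.matrix(dial_w[, intersect(species, names(dial_w)), drop = FALSE])
  if (length(miss_d) > 0L || any(hd & !stats::complete.cases(dial_m))) {
    bad <- if (length(miss_d) > 0L) {
      species
    } else {
      species[colSums(is.na(dial_m[hd, , drop = FALSE])) > 0]
    }
    stop("missing dialysate concentration for ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dial_m <- dial_m[, species]
  urine_m <- matrix(0, nrow(subjects), length(species),
    dimnames = list(NULL, species)
  )
  for (sp in intersect(species, names(urine_w))) {
    v <- urine_w[[sp]]
    urine_m[, sp] <- ifelse(has_urine & !is.na(v), v, 0)
  }

  ue_m <- urine_m * u_vol # µmol/24 h urinary component
  daily_m <- matrix(NA_real_, nrow(subjects), length(species),
    dimnames = list(NULL, species)
  )
  dialytic_m <- matrix(0, nrow(subjects), length(species),
    dimnames = list(NULL, species)
  )
  if (any(hd)) {
    ses <- sessions[sidx[hd], ]
    dialytic_m[hd, ] <- dial_m[hd, , drop = FALSE] *
      (ses$v_dialysate * ses$n_per_week / 7)
    daily_m[hd, ] <- dialytic_m[hd, , drop = FALSE] + ue_m[hd, , drop = FALSE]
  }
  if (any(!hd)) {
    daily_m[!hd, ] <- ue_m[!hd, , drop = FALSE]
  }

  reg <- aa_registry()
  mass <- reg$mol_mass[match(species, reg$name)]
  grams_m <- sweep(daily_m, 2, mass * 1e-6, `*`)
  gsum <- function(m) {
    cbind(
      bcaa = rowSums(m[, aa_names("bcaa"), drop = FALSE]),
      essential = rowSums(m[, aa_names("essential"), drop = FALSE]),
      non_essential = rowSums(m[, aa_names("non-essential"), drop = FALSE])
    )
  }
  g_umol <- gsum(daily_m)
  g_gram <- gsum(grams_m)

  # adequacy and intake
  ktv <- rep(NA_real_, nrow(subjects))
  intake_g <- intake_g_kg <- rep(NA_real_, nrow(subjects))
  session_total_g <- session_bcaa_g <- session_ess_g <- session_ness_g <-
    rep(NA_real_, nrow(subjects))
  if (any(hd)) {
    ses <- sessions[sidx[hd], ]
    ktv[hd] <- ktv_daugirdas(
      ses$urea_ratio, ses$duration_h, ses$uf_volume, ses$weight_post
    )
    pi_hd <- protein_intake_hd(
      ses$v_dialysate, ses$dialysate_urea, ses$n_per_week,
      uue = u_urea[hd], weight = ses$weight_post, upe = u_prot[hd]
    )
    intake_g[hd] <- pi_hd$intake_g
    intake_g_kg[hd] <- pi_hd$intake_g_kg
    sess_m <- dial_m[hd, , drop = FALSE] * ses$v_dialysate # µmol/session
    sess_g <- gsum(sweep(sess_m, 2, mass * 1e-6, `*`))
    session_bcaa_g[hd] <- sess_g[, "bcaa"]
    session_ess_g[hd] <- sess_g[, "essential"]
    session_ness_g[hd] <- sess_g[, "non_essential"]
    session_total_g[hd] <- sess_g[, "essential"] + sess_g[, "non_essential"]
  }
  if (any(!hd)) {
    pi_ct <- protein_intake_control(
      uue = u_urea[!hd], weight = subjects$weight[!hd], upe = u_prot[!hd]
    )
    intake_g[!hd] <- pi_ct$intake_g
    intake_g_kg[!hd] <- pi_ct$intake_g_kg
  }

  per_subject <- tibble::tibble(
    subject_id = subjects$subject_id,
    arm = subjects$arm,
    has_residual_diuresis = has_urine,
    ktv = ktv,
    protein_intake_g = intake_g,
    protein_intake_g_kg = intake_g_kg,
    loss_bcaa_umol = g_umol[, "bcaa"],
    loss_essential_umol = g_umol[, "essential"],
    loss_non_essential_umol = g_umol[, "non_essential"],
    loss_total_umol = g_umol[, "essential"] + g_umol[, "non_essential"],
    loss_bcaa_g = g_gram[, "bcaa"],
    loss_essential_g = g_gram[, "essential"],
    loss_non_essential_g = g_gram[, "non_essential"],
    loss_total_g = g_gram[, "essential"] + g_gram[, "non_essential"],
    session_loss_bcaa_g = session_bcaa_g,
    session_loss_essential_g = session_ess_g,
    session_loss_non_essential_g = session_ness_g,
    session_loss_total_g = session_total_g,
    pct_of_intake = pct_of_protein_intake(
      g_gram[, "essential"] + g_gram[, "non_essential"], intake_g
    )
  )
  losses <- tibble::tibble(
    subject_id = rep(subjects$subject_id, times = length(species)),
    arm = rep(subjects$arm, times = length(species)),
    species = rep(species, each = nrow(subjects)),
    daily_umol = as.numeric(daily_m),
    dialytic_umol = as.numeric(dialytic_m),
    urinary_umol = as.numeric(ue_m)
  )
  list(per_subject = per_subject, losses = losses)
}
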