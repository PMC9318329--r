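#' Severe-fatigue flag from the CIS subjective-fatigue score
#'
#' A Checklist Individual Strength subjective-fatigue subscale score of 35
#' or higher defines severe fatigue.
#'
#' @param score Numeric CIS subjective-fatigue scores; `NA` propagates.
#' @return Logical vector.
#' @export
#' @examples
#' severe_fatigue(c(34, 35, 50))
severe_fatigue <- function(score) {
  stopifnot(is.numeric(score))
  if (any(score < 0, na.rm = TRUE)) {
    stop("CIS scores cannot be negative", call. = FALSE)
  }
  score >= 35
}

#' Transform policy for regression predictors
#'
#' Skewed predictors enter regressions on the log2 scale (odds ratios per
#' doubling); normal predictors enter per sample-SD increment. The preset
#' list pins the published choices: plasma taurine, and the daily losses of
#' taurine and tryptophan, are log2-transformed.
#'
#' @param analyte Analyte name.
#' @param quantity `"plasma"` or `"loss"`.
#' @param values Optional numeric vector; when the policy is `log2`,
#'   non-positive values raise an error.
#' @return `"log2"` or `"sd"`.
#' @export
transform_policy <- function(analyte, quantity = c("plasma", "loss"), values = NULL) {
  quantity <- match.arg(quantity)
  analyte <- aa_canonicalize(analyte)
  log2_set <- list(
    plasma = "taurine",
    loss = c("taurine", "tryptophan")
  )
  policy <- if (analyte %in% log2_set[[quantity]]) "log2" else "sd"
  if (policy == "log2" && !is.null(values) && any(values <= 0, na.rm = TRUE)) {
    stop("non-positive value cannot be log2-transformed", call. = FALSE)
  }
  policy
}

# variance inflation factors of a numeric design matrix (no intercept column)
vif_of <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) {
    return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  }
  R <- stats::cor(X)
  stats::setNames(diag(solve(R)), colnames(X))
}

#' Linear regression with standardized coefficients
#'
#' Fits `y ~ X` on z-scored outcome and predictors and reports standardized
#' betas: the number of outcome SDs per predictor-SD increment. In the
#' univariable case the standardized beta equals the Pearson correlation.
#'
#' @param y Numeric outcome.
#' @param X Data frame or matrix of numeric predictors.
#' @return A tibble: `term`, `std_beta`, `ci_lo`, `ci_hi`, `p`, `vif`.
#' @export
fit_linear_stdbeta <- function(y, X) {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]
  X <- X[cc, , drop = FALSE]
  if (length(y) <= ncol(X) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop(
      "zero-variance predictor: ",
      paste(names(sds)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  Z <- as.data.frame(lapply(X, function(v) as.numeric(scale(v))))
  names(Z) <- names(X)
  zy <- as.numeric(scale(y))
  fit <- stats::lm(zy ~ ., data = Z)
  sm <- summary(fit)$coefficients
  est <- sm[-1, 1]
  se <- sm[-1, 2]
  vifs <- vif_of(Z)
  tibble::tibble(
    term = names(X),
    std_beta = unname(est),
    ci_lo = unname(est - stats::qnorm(0.975) * se),
    ci_hi = unname(est + stats::qnorm(0.975) * se),
    p = unname(sm[-1, 4]),
    vif = unname(vifs[names(X)])
  )
}

#' Select predictors for a multivariable model
#'
#' Keeps the predictors whose univariable p-value is below `alpha` and, when
#' any survive, fits the joint standardized-beta model.
#'
#' @param y Outcome vector.
#' @param X Data frame of candidate predictors.
#' @param alpha Univariable screening threshold.
#' @return A list: `univariable` (tibble of single-predictor fits),
#'   `selected` (names), `multivariable` (tibble or `NULL` when nothing is
#'   selected).
#' @export
select_multivariable <- function(y, X, alpha = 0.05) {
  X <- as.data.frame(X)
  uni <- dplyr::bind_rows(lapply(names(X), function(nm) {
    fit_linear_stdbeta(y, X[, nm, drop = FALSE])
  }))
  selected <- uni$term[uni$p < alpha]
  multi <- if (length(selected) > 0L) {
    fit_linear_stdbeta(y, X[, selected, drop = FALSE])
  } else {
    NULL
  }
  list(univariable = uni, selected = selected, multivariable = multi)
}

model_covariates <- function(model) {
  base <- c("age", "sex_male", "bmi", "vintage")
  switch(as.character(model),
    "0" = character(0),
    "1" = base,
    "2" = c(base, "hemoglobin", "crp", "cvd", "diabetes"),
    stop("model must be 0 (unadjusted), 1 or 2", call. = FALSE)
  )
}

#' Logistic regression of severe fatigue on one predictor
#'
#' Fits `severe fatigue ~ predictor + covariates` by maximum likelihood and
#' reports the odds ratio per 1-SD increment (`transform = "sd"`, the SD
#' being the sample SD of the analysis dataset) or per doubling
#' (`transform = "log2"`), with a Wald 95% CI by default.
#'
#' Covariate sets: model 1 adjusts for age, sex, BMI and dialysis vintage;
#' model 2 adds hemoglobin, C-reactive protein, cardiovascular disease and
#' diabetes; model 0 is unadjusted.
#'
#' @param data Data frame containing `severe` (logical) plus the covariate
#'   columns `age`, `sex_male`, `bmi`, `vintage`, `hemoglobin`, `crp`,
#'   `cvd`, `diabetes` as needed by `model`.
#' @param predictor Name of the predictor column in `data`.
#' @param model 0, 1 or 2.
#' @param transform `"sd"`, `"log2"`, or `"none"` (raw scale, e.g. for a
#'   binary predictor, where the unadjusted odds ratio equals the
#'   contingency-table cross-product ratio).
#' @param ci `"wald"` (default) or `"profile"`.
#' @return A tibble of class `association_result`: `predictor`, `model`,
#'   `increment`, `or`, `ci_lo`, `ci_hi`, `p`, `n`, `n_events`, `vif_max`,
#'   `converged`, `separation`.
#' @export
fit_logistic <- function(data, predictor, model = 2,
                         transform = c("sd", "log2", "none"),
                         ci = c("wald", "profile")) {
  transform <- match.arg(transform)
  ci <- match.arg(ci)
  covs <- model_covariates(model)
  need <- c("severe", predictor, covs)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  x <- d[[predictor]]
  if (stats::sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  d$.x <- switch(transform,
    log2 = {
      if (any(x <= 0)) {
        stop("non-positive value cannot be log2-transformed", call. = FALSE)
      }
      log2(x)
    },
    sd = (x - mean(x)) / stats::sd(x),
    none = as.numeric(x)
  )
  d[covs] <- lapply(d[covs], as.numeric)
  form <- stats::as.formula(paste(
    "severe ~ .x",
    if (length(covs) > 0L) paste("+", paste(covs, collapse = " + ")) else ""
  ))
  fit <- suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  est <- sm[".x", 1]
  se <- sm[".x", 2]
  separation <- !fit$converged || se > 50 || abs(est) > 25
  cint <- if (ci == "wald") {
    est + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    suppressMessages(stats::confint(fit, ".x"))
  }
  Xm <- stats::model.matrix(fit)[, -1, drop = FALSE]
  out <- tibble::tibble(
    predictor = predictor, model = as.character(model),
    increment = switch(transform,
      log2 = "per-log2", sd = "per-SD", none = "per-unit"
    ),
    or = if (separation) NA_real_ else exp(est),
    ci_lo = if (separation) NA_real_ else exp(cint[1]),
    ci_hi = if (separation) NA_real_ else exp(cint[2]),
    p = if (separation) NA_real_ else sm[".x", 4],
    log_or = if (separation) NA_real_ else est,
    n = nrow(d), n_events = sum(d$severe),
    vif_max = max(vif_of(Xm)),
    converged = fit$converged, separation = separation
  )
  class(out) <- c("association_result", class(out))
  out
}

#' Sensitivity-exclusion suite for a fatigue association
#'
#' Refits a [fit_logistic()] analysis under five exclusion rules:
#' 1. predictor outliers removed (|z| > 2 from the mean);
#' 2. subjects with two dialysis sessions per week excluded;
#' 3. dialysis vintage > 60 months excluded;
#' 4. BMI < 18.5 kg/m2 excluded;
#' 5. hemoglobin below the within-sex 5th percentile of the analysis
#'    cohort excluded.
#'
#' The per-SD scaling (when used) is recomputed on each restricted dataset.
#'
#' @inheritParams fit_logistic
#' @param extra_cols Additional columns required by the rules
#'   (`n_per_week`); joined in from `data` if present.
#' @return A tibble: one row per rule with the rule label, `n_excluded`,
#'   and the refitted association columns; the unrestricted fit is the
#'   first row (`rule = "base"`).
#' @export
sensitivity_suite <- function(data, predictor, model = 2,
                              transform = c("sd", "log2")) {
  transform <- match.arg(transform)
  rules <- list(
    base = function(d) rep(TRUE, nrow(d)),
    outliers = function(d) {
      x <- d[[predictor]]
      abs(x - mean(x, na.rm = TRUE)) <= 2 * stats::sd(x, na.rm = TRUE)
    },
    twice_weekly = function(d) is.na(d$n_per_week) | d$n_per_week == 3,
    vintage_gt_60 = function(d) is.na(d$vintage) | d$vintage <= 60,
    low_bmi = function(d) is.na(d$bmi) | d$bmi >= 18.5,
    low_hemoglobin = function(d) {
      ok <- rep(TRUE, nrow(d))
      for (s in unique(d$sex_male)) {
        idx <- d$sex_male == s
        thr <- stats::quantile(d$hemoglobin[idx], 0.05, na.rm = TRUE, type = 7)
        ok[idx] <- d$hemoglobin[idx] >= thr
      }
      ok
    }
  )
  out <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    keep <- rules[[i]](data)
    d <- data[keep, , drop = FALSE]
    res <- if (nrow(d) < 10L || length(unique(d$severe)) < 2L) {
      tibble::tibble(
        predictor = predictor, model = as.character(model),
        increment = if (transform == "log2") "per-log2" else "per-SD",
        or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
        log_or = NA_real_, n = nrow(d), n_events = sum(d$severe),
        vif_max = NA_real_, converged = FALSE, separation = FALSE
      )
    } else {
      fit_logistic(d, predictor, model = model, transform = transform)
    }
    res$rule <- names(rules)[i]
    res$n_excluded <- nrow(data) - nrow(d)
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}

#' Predicted-probability curve from a fitted fatigue model
#'
#' Inverse-logit predicted probability of severe fatigue over a grid of
#' predictor values, with all covariates held at their means (the reference
#' point of the display). Values outside the observed predictor range
#' trigger an extrapolation warning.
#'
#' @inheritParams fit_logistic
#' @param grid Numeric vector of predictor values on the original scale;
#'   defaults to an even grid over the observed range.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @return A tibble: `x` (predictor value), `probability`.
#' @export
probability_curve <- function(data, predictor, model = 2,
                              transform = c("sd", "log2"),
                              grid = NULL, n_grid = 100L) {
  transform <- match.arg(transform)
  covs <- model_covariates(model)
  need <- c("severe", predictor, covs)
  d <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  x <- d[[predictor]]
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = n_grid)
  if (any(grid < min(x)) || any(grid > max(x))) {
    warning("grid extends beyond the observed predictor range (extrapolation)")
  }
  mu <- mean(x)
  sdx <- stats::sd(x)
  if (transform == "log2") {
    if (any(c(x, grid) <= 0)) {
      stop("non-positive value cannot be log2-transformed", call. = FALSE)
    }
    d$.x <- log2(x)
    gx <- log2(grid)
  } else {
    d$.x <- (x - mu) / sdx
    gx <- (grid - mu) / sdx
  }
  d[covs] <- lapply(d[covs], as.numeric)
  form <- stats::as.formula(paste(
    "severe ~ .x",
    if (length(covs) > 0L) paste("+", paste(covs, collapse = " + ")) else ""
  ))
  fit <- suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  beta <- stats::coef(fit)
  ref <- c(1, mean(d$.x), vapply(d[covs], mean, numeric(1)))
  lp_ref <- sum(beta * ref)
  lp <- lp_ref + beta[".x"] * (gx - mean(d$.x))
  tibble::tibble(x = grid, probability = stats::plogis(lp))
}

#' Assemble the per-subject association dataset of a cohort
#'
#' One row per hemodialysis subject with the severe-fatigue flag, the
#' adjustment covariates, protein intake, per-analyte predialysis plasma
#' concentrations (`plasma_<analyte>`), daily losses (`loss_<analyte>`),
#' and group sums of both.
#'
#' @param cohort An `aa_cohort`.
#' @param quantified Optional precomputed [quantify_cohort()] result.
#' @return A tibble.
#' @export
association_dataset <- function(cohort, quantified = NULL) {
  stopifnot(inherits(cohort, "aa_cohort"))
  if (is.null(quantified)) quantified <- quantify_cohort(cohort)
  subj <- cohort$subjects[cohort$subjects$arm == "hd", ]
  ps <- quantified$per_subject
  ps <- ps[match(subj$subject_id, ps$subject_id), ]
  ses <- cohort$sessions[match(subj$subject_id, cohort$sessions$subject_id), ]

  plasma <- with_group_sums(panel_wide(cohort, "plasma_pre", "hd"))
  plasma <- plasma[match(subj$subject_id, plasma$subject_id), ]
  losses <- tidyr::pivot_wider(
    quantified$losses[
      quantified$losses$arm == "hd",
      c("subject_id", "species", "daily_umol")
    ],
    names_from = "species", values_from = "daily_umol"
  )
  losses <- with_group_sums(losses[match(subj$subject_id, losses$subject_id), ])

  prefix <- function(tb, pre) {
    tb <- tb[, setdiff(names(tb), c("subject_id", "arm"))]
    names(tb) <- paste0(pre, "_", gsub(" ", "_", names(tb)))
    tb
  }
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = subj$subject_id,
      severe = severe_fatigue(subj$cis_fatigue),
      age = subj$age, sex_male = subj$sex == "male", bmi = subj$bmi,
      vintage = subj$vintage, hemoglobin = subj$hemoglobin, crp = subj$crp,
      cvd = subj$cvd, diabetes = subj$diabetes,
      n_per_week = ses$n_per_week, ktv = ps$ktv,
      protein_intake = ps$protein_intake_g,
      protein_intake_kg = ps$protein_intake_g_kg,
      loss_total_g = ps$loss_total_g
    ),
    prefix(plasma, "plasma"),
    prefix(losses, "loss")
  )
}

#' Fatigue association table across analytes
#'
#' Reproduces the layout of the published fatigue tables: for each
#' predialysis plasma analyte (or each daily loss, plus protein intake),
#' the model-1 and model-2 odds ratios of severe fatigue with 95% CI and
#' p-value, using the [transform_policy()] increment per analyte.
#'
#' @param dataset Output of [association_dataset()].
#' @param quantity `"plasma"` (table-5 layout) or `"loss"` (table-6 layout,
#'   which appends the protein-intake rows).
#' @return A tibble with one row per analyte x model.
#' @export
fatigue_table <- function(dataset, quantity = c("plasma", "loss")) {
  quantity <- match.arg(quantity)
  groups <- c("bcaa", "essential", "non_essential", "total")
  analytes <- c(gsub(" ", "_", aa_names()), groups)
  rows <- list()
  for (an in analytes) {
    col <- paste0(quantity, "_", an)
    tr <- if (an %in% groups) {
      "sd"
    } else {
      transform_policy(gsub("_", " ", an), quantity)
    }
    for (m in c(1, 2)) {
      rows[[length(rows) + 1L]] <-
        fit_logistic(dataset, col, model = m, transform = tr)
    }
  }
  if (quantity == "loss") {
    for (col in c("protein_intake", "protein_intake_kg")) {
      for (m in c(1, 2)) {
        rows[[length(rows) + 1L]] <-
          fit_logistic(dataset, col, model = m, transform = "sd")
      }
    }
  }
  dplyr::bind_rows(rows)
}
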