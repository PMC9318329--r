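#' Round half away from zero
#'
#' Commercial rounding used for the display columns of the comparison
#' tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify a sample as normal or skewed
#'
#' The published tables were assembled after visual inspection of histograms
#' and quantile-quantile plots; as a reproducible stand-in the default rule
#' is a Shapiro-Wilk test at `alpha`, overridable per analyte via the
#' presets in [distribution_presets()].
#'
#' @param values Numeric vector, `n >= 3`, NAs dropped.
#' @param alpha Shapiro-Wilk significance threshold.
#' @return `"normal"`, `"skewed"`, or `"skewed-degenerate"` for a
#'   zero-variance sample.
#' @export
assess_distribution <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) {
    stop("need at least 3 observations to assess a distribution", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return("skewed-degenerate")
  }
  n <- length(values)
  if (n > 5000L) values <- values[seq(1L, n, length.out = 5000L)]
  p <- stats::shapiro.test(values)$p.value
  if (p >= alpha) "normal" else "skewed"
}

#' Distribution presets matching the published table layout
#'
#' Analytes displayed as median (IQR) per compartment; everything else is
#' displayed as mean +/- SD. Keeping these fixed makes the table layout
#' reproducible instead of depending on a re-derived normality test.
#'
#' @return Named list of character vectors of skewed analytes, by
#'   compartment: `plasma_pre`/`plasma_ctrl` (predialysis and control
#'   plasma), `loss` (daily losses), `change` (intradialytic changes).
#' @export
distribution_presets <- function() {
  plasma_skewed <- c("tryptophan", "citrulline", "glutamic acid", "proline", "taurine")
  list(
    plasma_pre = plasma_skewed,
    plasma_ctrl = plasma_skewed,
    loss = c(
      "lysine", "phenylalanine", "threonine", "valine",
      "citrulline", "serine", "taurine"
    ),
    change = plasma_skewed
  )
}

#' Summarize a sample under a distribution flag
#'
#' @param values Numeric vector (NAs dropped).
#' @param dist_flag `"normal"` or `"skewed"` (any `"skewed-*"` flag takes
#'   the median path).
#' @return A list of class `summary_stat`: `central`, `dispersion`
#'   (SD or `c(q1, q3)`), `dist_flag`, `n`.
#' @export
summarize_values <- function(values, dist_flag) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  normal <- identical(dist_flag, "normal")
  out <- if (normal) {
    list(
      central = mean(values),
      dispersion = if (length(values) > 1L) stats::sd(values) else 0,
      dist_flag = "normal", n = length(values)
    )
  } else {
    list(
      central = stats::median(values),
      dispersion = unname(stats::quantile(values, c(0.25, 0.75), type = 7)),
      dist_flag = "skewed", n = length(values)
    )
  }
  structure(out, class = "summary_stat")
}

#' @export
format.summary_stat <- function(x, digits = 3, ...) {
  if (x$dist_flag == "normal") {
    sprintf(
      "%s ± %s", signif(x$central, digits),
      signif(x$dispersion, digits)
    )
  } else {
    sprintf(
      "%s (%s; %s)", signif(x$central, digits),
      signif(x$dispersion[1], digits), signif(x$dispersion[2], digits)
    )
  }
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Proportional difference between two group summaries
#'
#' `(hd - ctrl) / ctrl * 100`, rounded half-away-from-zero to an integer
#' percent — the derived comparison column of the plasma-concentration
#' table. The inputs are the displayed central values (mean if normal,
#' median if skewed).
#'
#' @param stat_hd,stat_ctrl Central values of the two groups; `stat_ctrl`
#'   must be positive.
#' @return Integer percent.
#' @export
#' @examples
#' proportional_difference(78, 28) # +179
proportional_difference <- function(stat_hd, stat_ctrl) {
  if (any(stat_ctrl <= 0)) {
    stop("control summary must be positive", call. = FALSE)
  }
  round_half_away((stat_hd - stat_ctrl) / stat_ctrl * 100)
}

#' Ratio of group summaries with display rounding
#'
#' `hd / ctrl`, rounded half-away-from-zero to one decimal when below 2 and
#' to the nearest integer otherwise — the derived column of the daily-loss
#' comparison table.
#'
#' @inheritParams proportional_difference
#' @return Rounded ratio.
#' @export
#' @examples
#' group_ratio(799, 12) # 67
#' group_ratio(132, 339) # 0.4
group_ratio <- function(stat_hd, stat_ctrl) {
  if (any(stat_ctrl <= 0)) {
    stop("control summary must be positive", call. = FALSE)
  }
  r <- stat_hd / stat_ctrl
  ifelse(r < 2, round_half_away(r, 1), round_half_away(r))
}

#' Two-group comparison with distribution-aware dispatch
#'
#' Continuous data go to a two-sided independent-samples t-test when both
#' samples look normal and to a Wilcoxon rank-sum test otherwise (normal
#' approximation with continuity correction when either n exceeds 25, exact
#' otherwise, ties mid-ranked); nominal data go to a chi-squared test on
#' the contingency table (no Yates correction by default).
#'
#' @param a,b The two samples (numeric, or values to tabulate when
#'   `dtype = "nominal"`).
#' @param dtype `"continuous"` or `"nominal"`.
#' @param dist_flag Optional override (`"normal"`/`"skewed"`); when `NULL`
#'   both samples are assessed with [assess_distribution()].
#' @param correct Yates continuity correction for the chi-squared path.
#' @return A list: `test` (label), `statistic`, `p`.
#' @export
compare_groups <- function(a, b, dtype = c("continuous", "nominal"),
                           dist_flag = NULL, correct = FALSE) {
  dtype <- match.arg(dtype)
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty group", call. = FALSE)
  }
  if (dtype == "nominal") {
    tab <- table(c(rep("a", length(a)), rep("b", length(b))), c(a, b))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    return(list(
      test = "chi-squared", statistic = unname(ht$statistic),
      p = ht$p.value
    ))
  }
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (is.null(dist_flag)) {
    dist_flag <- if (assess_distribution(a) == "normal" &&
      assess_distribution(b) == "normal") {
      "normal"
    } else {
      "skewed"
    }
  }
  if (dist_flag == "normal") {
    ht <- stats::t.test(a, b)
    list(test = "t-test", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    exact <- max(length(a), length(b)) <= 25
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    list(
      test = "wilcoxon-rank-sum", statistic = unname(ht$statistic),
      p = ht$p.value
    )
  }
}

#' Paired comparison with distribution-aware dispatch
#'
#' Dispatches on the distribution of the pairwise differences: paired
#' t-test when normal, Wilcoxon signed-rank otherwise. Pairs with a missing
#' member are dropped. All-zero differences return p = 1 with statistic 0
#' (no evidence of change) rather than an error.
#'
#' @param pre,post Paired samples of equal length.
#' @param dist_flag Optional override of the difference distribution.
#' @return A list: `test`, `statistic`, `p`, `n_pairs`, and `degenerate`
#'   (TRUE when the differences have zero variance).
#' @export
compare_paired <- function(pre, post, dist_flag = NULL) {
  if (length(pre) != length(post)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]
  post <- post[keep]
  d <- post - pre
  if (length(d) == 0L) stop("no complete pairs", call. = FALSE)
  if (stats::sd(d) == 0 || all(d == 0)) {
    return(list(
      test = if (all(d == 0)) "signed-rank" else "paired-t",
      statistic = 0, p = 1, n_pairs = length(d), degenerate = TRUE
    ))
  }
  if (is.null(dist_flag)) dist_flag <- assess_distribution(d)
  if (dist_flag == "normal") {
    ht <- stats::t.test(post, pre, paired = TRUE)
    list(
      test = "paired-t", statistic = unname(ht$statistic), p = ht$p.value,
      n_pairs = length(d), degenerate = FALSE
    )
  } else {
    exact <- length(d) <= 25
    ht <- suppressWarnings(
      stats::wilcox.test(post, pre,
        paired = TRUE, exact = exact,
        correct = TRUE
      )
    )
    list(
      test = "signed-rank", statistic = unname(ht$statistic), p = ht$p.value,
      n_pairs = length(d), degenerate = FALSE
    )
  }
}

summary_cols <- function(stat) {
  if (stat$dist_flag == "normal") {
    tibble::tibble(
      central = stat$central, spread_lo = NA_real_, spread_hi = NA_real_,
      sd = stat$dispersion, display = format(stat)
    )
  } else {
    tibble::tibble(
      central = stat$central, spread_lo = stat$dispersion[1],
      spread_hi = stat$dispersion[2], sd = NA_real_, display = format(stat)
    )
  }
}

analyte_rows <- function() {
  tibble::tibble(
    analyte = c(aa_names(), "bcaa", "essential", "non_essential", "total"),
    row_type = c(rep("species", 21), rep("group", 4))
  )
}

panel_wide <- function(cohort, compartment, arm) {
  p <- cohort$panels
  p <- p[p$compartment == compartment & p$analyte %in% aa_names(), ]
  ids <- cohort$subjects$subject_id[cohort$subjects$arm == arm]
  p <- p[p$subject_id %in% ids, ]
  tidyr::pivot_wider(p[, c("subject_id", "analyte", "value")],
    names_from = "analyte", values_from = "value"
  )
}

with_group_sums <- function(wide) {
  sp <- intersect(names(wide), aa_names())
  m <- as.matrix(wide[, sp])
  wide$bcaa <- rowSums(m[, aa_names("bcaa"), drop = FALSE])
  wide$essential <- rowSums(m[, aa_names("essential"), drop = FALSE])
  wide$non_essential <- rowSums(m[, aa_names("non-essential"), drop = FALSE])
  wide$total <- wide$essential + wide$non_essential
  wide
}

two_group_table <- function(hd_wide, ctrl_wide, skewed, derived = c("pct", "ratio")) {
  derived <- match.arg(derived)
  rows <- analyte_rows()
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    an <- rows$analyte[i]
    a <- hd_wide[[an]]
    b <- ctrl_wide[[an]]
    flag <- if (an %in% skewed) "skewed" else "normal"
    sa <- summarize_values(a, flag)
    sb <- summarize_values(b, flag)
    cmp <- compare_groups(a, b, "continuous", dist_flag = flag)
    der <- if (derived == "pct") {
      proportional_difference(sa$central, sb$central)
    } else {
      group_ratio(sa$central, sb$central)
    }
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(analyte = an, row_type = rows$row_type[i], dist_flag = flag),
      stats::setNames(summary_cols(sa), paste0("hd_", names(summary_cols(sa)))),
      stats::setNames(summary_cols(sb), paste0("ctrl_", names(summary_cols(sb)))),
      tibble::tibble(derived = der, test = cmp$test, p = cmp$p)
    )
  }
  dplyr::bind_rows(out)
}

#' Build a cohort report table
#'
#' Reproduces the row/column structure of the four descriptive tables of
#' the analysis:
#' * `1` — baseline characteristics (demographics, dialysis parameters,
#'   protein intake) by arm with dispatch tests;
#' * `2` — predialysis plasma amino-acid concentrations vs controls, with
#'   the proportional-difference column;
#' * `3` — daily amino-acid losses vs controls, with the ratio column;
#' * `4` — pre- vs post-dialysis plasma concentrations, with paired tests
#'   and the proportional-change column.
#'
#' @param cohort An `aa_cohort`.
#' @param table_id 1, 2, 3 or 4.
#' @param quantified Optional precomputed result of [quantify_cohort()]
#'   (computed on the fly if omitted; needed for tables 1 and 3).
#' @return A tibble; one row per analyte plus the four group rows for
#'   tables 2-4, one row per characteristic for table 1.
#' @export
build_table <- function(cohort, table_id, quantified = NULL) {
  stopifnot(inherits(cohort, "aa_cohort"), table_id %in% 1:4)
  presets <- distribution_presets()
  if (table_id %in% c(1, 3) && is.null(quantified)) {
    quantified <- quantify_cohort(cohort)
  }

  if (table_id == 2) {
    hd <- with_group_sums(panel_wide(cohort, "plasma_pre", "hd"))
    ctrl <- with_group_sums(panel_wide(cohort, "plasma_pre", "control"))
    return(two_group_table(hd, ctrl, presets$plasma_pre, derived = "pct"))
  }

  if (table_id == 3) {
    l <- quantified$losses
    wide <- tidyr::pivot_wider(
      l[, c("subject_id", "arm", "species", "daily_umol")],
      names_from = "species", values_from = "daily_umol"
    )
    hd <- with_group_sums(wide[wide$arm == "hd", ])
    ctrl <- with_group_sums(wide[wide$arm == "control", ])
    return(two_group_table(hd, ctrl, presets$loss, derived = "ratio"))
  }

  if (table_id == 4) {
    pre <- with_group_sums(panel_wide(cohort, "plasma_pre", "hd"))
    post <- with_group_sums(panel_wide(cohort, "plasma_post", "hd"))
    post <- post[match(pre$subject_id, post$subject_id), ]
    rows <- analyte_rows()
    out <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      an <- rows$analyte[i]
      flag <- if (an %in% presets$change) "skewed" else "normal"
      a <- pre[[an]]
      b <- post[[an]]
      sa <- summarize_values(a, flag)
      sb <- summarize_values(b, flag)
      ch <- intradialytic_change(a, b)
      sc <- summarize_values(ch$absolute, flag)
      cmp <- compare_paired(a, b, dist_flag = flag)
      out[[i]] <- dplyr::bind_cols(
        tibble::tibble(analyte = an, row_type = rows$row_type[i], dist_flag = flag),
        stats::setNames(summary_cols(sa), paste0("pre_", names(summary_cols(sa)))),
        stats::setNames(summary_cols(sb), paste0("post_", names(summary_cols(sb)))),
        stats::setNames(summary_cols(sc), paste0("change_", names(summary_cols(sc)))),
        tibble::tibble(
          proportional_change = round_half_away(sc$central / sa$central * 100),
          test = cmp$test, p = cmp$p
        )
      )
    }
    return(dplyr::bind_rows(out))
  }

  # table 1: baseline characteristics
  subj <- cohort$subjects
  ses <- cohort$sessions
  ur <- cohort$urine
  ps <- quantified$per_subject
  hd <- subj$arm == "hd"
  num_row <- function(char, a, b, flag = "normal") {
    sa <- summarize_values(a, flag)
    has_b <- !is.null(b) && sum(!is.na(b)) > 0
    cmp <- if (has_b) compare_groups(a, b, "continuous", dist_flag = flag) else NULL
    tibble::tibble(
      characteristic = char,
      hd_display = format(sa),
      ctrl_display = if (has_b) format(summarize_values(b, flag)) else "-",
      test = if (has_b) cmp$test else NA_character_,
      p = if (has_b) cmp$p else NA_real_
    )
  }
  nom_row <- function(char, a, b) {
    has_b <- !is.null(b)
    cmp <- if (has_b) compare_groups(a, b, "nominal") else NULL
    fmt <- function(x) sprintf("%d (%.0f%%)", sum(x), 100 * mean(x))
    tibble::tibble(
      characteristic = char, hd_display = fmt(a),
      ctrl_display = if (has_b) fmt(b) else "-",
      test = if (has_b) cmp$test else NA_character_,
      p = if (has_b) cmp$p else NA_real_
    )
  }
  hd_ur <- ur[match(subj$subject_id[hd], ur$subject_id), ]
  ctrl_ur <- ur[match(subj$subject_id[!hd], ur$subject_id), ]
  diuresis_hd <- !is.na(hd_ur$volume) & hd_ur$volume > 0.2
  dplyr::bind_rows(
    num_row("age_years", subj$age[hd], subj$age[!hd]),
    nom_row("male_sex", subj$sex[hd] == "male", subj$sex[!hd] == "male"),
    num_row("vintage_months", subj$vintage[hd], NULL, "skewed"),
    nom_row("three_sessions_per_week", ses$n_per_week == 3, NULL),
    num_row("dialysate_volume_l", ses$v_dialysate, NULL),
    num_row("ultrafiltration_volume_l", ses$uf_volume, NULL),
    num_row("ktv", ps$ktv[match(subj$subject_id[hd], ps$subject_id)], NULL),
    nom_row("residual_diuresis", diuresis_hd, rep(TRUE, sum(!hd))),
    num_row(
      "urinary_volume_l", hd_ur$volume[diuresis_hd],
      ctrl_ur$volume
    ),
    num_row("hemoglobin_mmol_l", subj$hemoglobin[hd], subj$hemoglobin[!hd]),
    num_row("weight_kg", subj$weight[hd], subj$weight[!hd]),
    num_row("height_m", subj$height[hd], subj$height[!hd]),
    num_row("bmi_kg_m2", subj$bmi[hd], subj$bmi[!hd]),
    num_row(
      "protein_intake_g", ps$protein_intake_g[ps$arm == "hd"],
      ps$protein_intake_g[ps$arm == "control"]
    ),
    num_row(
      "protein_intake_g_kg", ps$protein_intake_g_kg[ps$arm == "hd"],
      ps$protein_intake_g_kg[ps$arm == "control"]
    )
  )
}
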