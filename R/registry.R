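#' Amino acid registry
#'
#' The analyte panel covers 21 reported amino acids plus two species that were
#' measured but are not reported: cysteine (unstable in the analytical matrix)
#' and aspartic acid (below the detection limit). Grouping follows the
#' essential / non-essential convention used in dialysis nutrition work, with
#' the branched-chain amino acids (BCAAs: leucine, isoleucine, valine) as a
#' subset of the essential group. Taurine and citrulline — not proteinogenic
#' in the strict sense — are carried in the non-essential group.
#'
#' Molecular masses are average masses of the free (non-residue) molecule in
#' g/mol, used to convert micromolar losses to grams.
#'
#' @return A tibble with one row per species and columns `name`, `code3`
#'   (three-letter code), `mol_mass` (g/mol), `group`
#'   (`"essential"`/`"non-essential"`), `is_essential`, `is_bcaa`, `reported`.
#' @export
#' @examples
#' aa_registry()
aa_registry <- function() {
  .aa_registry
}

# Free-molecule average masses (g/mol). BCAA = {leucine, isoleucine, valine}.
.aa_registry <- local({
  ess <- c(
    histidine = 155.15, isoleucine = 131.17, leucine = 131.17,
    lysine = 146.19, methionine = 149.21, phenylalanine = 165.19,
    threonine = 119.12, tryptophan = 204.23, valine = 117.15
  )
  ness <- c(
    alanine = 89.09, arginine = 174.20, asparagine = 132.12,
    citrulline = 175.19, `glutamic acid` = 147.13, glutamine = 146.15,
    glycine = 75.07, ornithine = 132.16, proline = 115.13,
    serine = 105.09, taurine = 125.15, tyrosine = 181.19
  )
  excl <- c(cysteine = 121.16, `aspartic acid` = 133.10)
  code3 <- c(
    histidine = "His", isoleucine = "Ile", leucine = "Leu", lysine = "Lys",
    methionine = "Met", phenylalanine = "Phe", threonine = "Thr",
    tryptophan = "Trp", valine = "Val", alanine = "Ala", arginine = "Arg",
    asparagine = "Asn", citrulline = "Cit", `glutamic acid` = "Glu",
    glutamine = "Gln", glycine = "Gly", ornithine = "Orn", proline = "Pro",
    serine = "Ser", taurine = "Tau", tyrosine = "Tyr", cysteine = "Cys",
    `aspartic acid` = "Asp"
  )
  nm <- c(names(ess), names(ness), names(excl))
  tibble::tibble(
    name = nm,
    code3 = unname(code3[nm]),
    mol_mass = unname(c(ess, ness, excl)),
    group = c(
      rep("essential", length(ess)), rep("non-essential", length(ness)),
      rep(NA_character_, length(excl))
    ),
    is_essential = c(
      rep(TRUE, length(ess)), rep(FALSE, length(ness)),
      rep(NA, length(excl))
    ),
    is_bcaa = nm %in% c("leucine", "isoleucine", "valine"),
    reported = !nm %in% names(excl)
  )
})

#' Canonicalize an amino-acid name
#'
#' Accepts full names (any case) and three-letter codes. One-letter codes are
#' rejected: taurine, citrulline and ornithine have none, so a one-letter
#' interface would be ambiguous for this panel.
#'
#' @param name Character vector of names or three-letter codes.
#' @return Canonical lower-case full names.
#' @export
aa_canonicalize <- function(name) {
  stopifnot(is.character(name))
  reg <- aa_registry()
  low <- tolower(trimws(name))
  out <- character(length(low))
  by_name <- match(low, reg$name)
  by_code <- match(low, tolower(reg$code3))
  hit <- ifelse(is.na(by_name), by_code, by_name)
  bad <- is.na(hit)
  if (any(bad)) {
    one_letter <- nchar(low[bad]) == 1L
    if (any(one_letter)) {
      stop("one-letter amino-acid codes are not accepted: ",
        paste(unique(name[bad][one_letter]), collapse = ", "),
        call. = FALSE
      )
    }
    stop("unknown amino acid: ", paste(unique(name[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- reg$name[hit]
  out
}

#' Look up one amino-acid registry entry
#'
#' @param name A single amino-acid name or three-letter code.
#' @return A one-row tibble (see [aa_registry()]).
#' @export
#' @examples
#' aa_spec("leucine")
#' aa_spec("Tau")
aa_spec <- function(name) {
  stopifnot(length(name) == 1L)
  canon <- aa_canonicalize(name)
  reg <- aa_registry()
  row <- reg[reg$name == canon, ]
  if (!row$reported) {
    reason <- if (canon == "cysteine") {
      "cysteine is not reported due to instability"
    } else {
      "aspartic acid is not reported: concentrations below the detection limit"
    }
    stop("excluded analyte: ", reason, call. = FALSE)
  }
  row
}

#' Names of the reported amino acids
#'
#' @param group Optional subset: `"essential"`, `"non-essential"` or `"bcaa"`.
#' @return Character vector of canonical names.
#' @export
aa_names <- function(group = NULL) {
  reg <- aa_registry()
  reg <- reg[reg$reported, ]
  if (is.null(group)) {
    return(reg$name)
  }
  group <- match.arg(group, c("essential", "non-essential", "bcaa"))
  if (group == "bcaa") reg$name[reg$is_bcaa] else reg$name[reg$group == group]
}

#' Sum a per-species value map into amino-acid groups
#'
#' Totals are the sum of the essential and non-essential sums; BCAAs are a
#' subset of the essential group, so the partition identity
#' `essential + non-essential = total` holds to machine precision.
#'
#' @param per_species Named numeric vector keyed by reported amino-acid names
#'   (or three-letter codes). Species not present contribute nothing.
#' @return Named numeric vector with elements `bcaa`, `essential`,
#'   `non_essential`, `total`.
#' @export
#' @examples
#' aa_group_sums(c(leucine = 1, isoleucine = 2, valine = 3))
aa_group_sums <- function(per_species) {
  stopifnot(is.numeric(per_species), !is.null(names(per_species)))
  nm <- aa_canonicalize(names(per_species))
  if (anyDuplicated(nm)) {
    stop("duplicated species in value map", call. = FALSE)
  }
  reg <- aa_registry()
  if (any(!reg$reported[match(nm, reg$name)])) {
    stop("excluded analyte in value map: ",
      paste(nm[!reg$reported[match(nm, reg$name)]], collapse = ", "),
      call. = FALSE
    )
  }
  ess <- nm %in% aa_names("essential")
  bc <- nm %in% aa_names("bcaa")
  e <- sum(per_species[ess])
  n <- sum(per_species[!ess])
  c(bcaa = sum(per_species[bc]), essential = e, non_essential = n, total = e + n)
}

#' Write / read the registry as CSV
#'
#' Round-trippable plain-text serialization with columns `name`, `mol_mass`,
#' `group`, `bcaa`, `reported`.
#'
#' @param path File path.
#' @return `write_aa_registry()` returns `path` invisibly;
#'   `read_aa_registry()` returns the registry tibble.
#' @export
write_aa_registry <- function(path) {
  reg <- aa_registry()
  out <- data.frame(
    name = reg$name, mol_mass = reg$mol_mass,
    group = ifelse(is.na(reg$group), "", reg$group),
    bcaa = reg$is_bcaa, reported = reg$reported
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_aa_registry
#' @export
read_aa_registry <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    name = raw$name,
    mol_mass = raw$mol_mass,
    group = ifelse(raw$group == "", NA_character_, raw$group),
    is_essential = ifelse(raw$group == "", NA, raw$group == "essential"),
    is_bcaa = raw$bcaa,
    reported = raw$reported
  )
}
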