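# full-precision plain-text serialization: doubles are written with %.17g so
# a write -> read round trip is exact
write_csv_full <- function(df, path, sep = ",") {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path,
    sep = sep, row.names = FALSE, quote = TRUE,
    na = "NA"
  )
  invisible(path)
}

read_csv_plain <- function(path, sep = ",") {
  tibble::as_tibble(utils::read.table(path,
    sep = sep, header = TRUE,
    stringsAsFactors = FALSE, na.strings = "NA"
  ))
}

#' Write a cohort to schema-conformant CSV files
#'
#' Emits `subjects.csv`, `sessions.csv`, `urine.csv`, `panels.csv` (long
#' format: subject, compartment, analyte, value, unit) and a
#' `manifest.json` recording the seed, a configuration hash, and the file
#' list, sufficient to reproduce the dataset bit-identically.
#'
#' @param cohort An `aa_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    subjects = "subjects.csv", sessions = "sessions.csv",
    urine = "urine.csv", panels = "panels.csv"
  )
  for (nm in names(files)) {
    write_csv_full(cohort[[nm]], file.path(dir, files[[nm]]))
  }
  manifest <- list(
    package = "aabalance",
    version = as.character(utils::packageVersion("aabalance")),
    seed = cohort$config$seed,
    n_hd = cohort$config$n_hd,
    n_ctrl = cohort$config$n_ctrl,
    config_hash = rlang::hash(cohort$config),
    files = unname(files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]. The returned object carries the manifest
#' but no generator configuration (the data may come from any source with
#' the same schema).
#'
#' @param dir Directory holding the CSV files.
#' @return An `aa_cohort`.
#' @export
read_cohort <- function(dir) {
  need <- c("subjects.csv", "sessions.csv", "urine.csv", "panels.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss) > 0L) {
    stop("missing input files: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  manifest <- NULL
  if (file.exists(file.path(dir, "manifest.json"))) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  }
  seed <- if (!is.null(manifest)) manifest$seed else NA_integer_
  structure(list(
    subjects = read_csv_plain(file.path(dir, "subjects.csv")),
    sessions = read_csv_plain(file.path(dir, "sessions.csv")),
    urine = read_csv_plain(file.path(dir, "urine.csv")),
    panels = read_csv_plain(file.path(dir, "panels.csv")),
    manifest = manifest,
    config = list(seed = seed)
  ), class = "aa_cohort")
}

#' Run the full reporting pipeline
#'
#' Quantifies the cohort and writes the four descriptive tables plus the
#' two fatigue association tables as TSV, each with a header block
#' recording the test or model used per row, and a JSON run log.
#'
#' @param cohort An `aa_cohort`.
#' @param dir Output directory.
#' @return Invisibly, a named list of the six tables.
#' @export
run_report <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- quantify_cohort(cohort)
  tables <- list(
    table1_baseline = build_table(cohort, 1, q),
    table2_plasma = build_table(cohort, 2, q),
    table3_losses = build_table(cohort, 3, q),
    table4_changes = build_table(cohort, 4, q)
  )
  ds <- association_dataset(cohort, q)
  tables$table5_fatigue_plasma <- fatigue_table(ds, "plasma")
  tables$table6_fatigue_losses <- fatigue_table(ds, "loss")
  for (nm in names(tables)) {
    write_csv_full(tables[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t")
  }
  log <- list(
    seed = cohort$config$seed,
    n_subjects = nrow(cohort$subjects),
    tables = names(tables),
    timestamp_free = TRUE
  )
  jsonlite::write_json(log, file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(tables)
}
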