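# Patient/mutation registry: loading, validation and cohort statistics.

.registry_vocab <- list(
  phenotype = c("BMD", "DMD", "IMD", "DCM", "asymptomatic", "pending"),
  wb_amount = c("high", "medium", "low", "missing"),
  wb_size = c("increased", "normal", "reduced", "undetected", "missing"),
  if_staining = c("normal", "regular", "irregular", "mosaic",
                  "no_signal_revertant", "no_signal", "missing"),
  cardiomyopathy = c("yes", "no", "missing"),
  mental_retardation = c("yes", "no", "missing"),
  source = c("literature", "laboratory", "both")
)

.registry_columns <- c("patient_id", "mutation_id", "phenotype", "wb_amount",
                       "wb_size", "if_staining", "cardiomyopathy",
                       "mental_retardation", "source")

#' Load a patient registry CSV
#'
#' Reads and vocabulary-validates a registry of patients carrying in-frame
#' DMD mutations.  Columns: `patient_id`, `mutation_id`, `phenotype`
#' (BMD/DMD/IMD/DCM/asymptomatic/pending), `wb_amount` (western-blot
#' dystrophin amount), `wb_size`, `if_staining`, `cardiomyopathy`,
#' `mental_retardation`, `source`.  Missing clinical data is a first-class
#' `missing` category, never dropped.
#'
#' Phenotype definitions follow clinical convention: DMD = loss of
#' ambulation before age 13, BMD = after 16, IMD = between 13 and 16
#' (documented, not recomputed from ages).
#'
#' @param path CSV path.
#' @return data.frame of validated patient records.
#' @export
load_registry <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_registry(rec)
}

#' Validate registry records against the published schema
#'
#' @param records data.frame of patient records.
#' @return The records, invisibly valid; stops with offending row numbers on
#'   unknown categories or missing columns.
#' @export
validate_registry <- function(records) {
  missing_cols <- setdiff(.registry_columns, names(records))
  if (length(missing_cols) > 0)
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in names(.registry_vocab)) {
    bad <- which(!records[[col]] %in% .registry_vocab[[col]])
    if (length(bad) > 0)
      stop("unknown ", col, " category '", records[[col]][bad[1]],
           "' in rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  records
}

.int_pct <- function(count, total) {
  if (total == 0) return(rep(0, length(count)))
  round(100 * count / total)
}

#' Mutation-type breakdown of a cohort
#'
#' Counts distinct mutations per kind and the share of each kind among all
#' mutations, integer-rounded.
#'
#' @param records Patient records (used to restrict to observed mutations;
#'   may be `NULL` to summarise the mutation table alone).
#' @param mutations data.frame with columns `mutation_id`, `kind`.
#' @return data.frame with `kind`, `n`, `pct`.
#' @export
mutation_type_breakdown <- function(records, mutations) {
  if (!is.null(records)) {
    mutations <- mutations[mutations$mutation_id %in% records$mutation_id, ,
                           drop = FALSE]
  }
  kinds <- c("exon_deletion", "exon_duplication", "substitution", "small_deletion")
  n <- vapply(kinds, function(k) sum(mutations$kind == k), integer(1))
  data.frame(kind = kinds, n = as.integer(n),
             pct = .int_pct(n, sum(n)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Phenotype distribution over patients
#'
#' @param records Patient records.
#' @return data.frame with `phenotype`, `n`, `pct` (integer percentages of
#'   all patients).
#' @export
phenotype_distribution <- function(records) {
  ph <- .registry_vocab$phenotype
  n <- vapply(ph, function(p) sum(records$phenotype == p), integer(1))
  data.frame(phenotype = ph, n = as.integer(n),
             pct = .int_pct(n, nrow(records)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Reading-frame-rule exceptions
#'
#' Share of patients that contradict the reading-frame (Monaco) rule: the
#' registry universe is restricted to in-frame mutations, so every patient
#' with a severe DMD or intermediate IMD phenotype is an exception.
#'
#' @param records Patient records (all carrying in-frame mutations).
#' @return Integer-rounded percentage of patients with DMD or IMD phenotype.
#' @export
reading_frame_exceptions <- function(records) {
  if (nrow(records) == 0) return(0)
  .int_pct(sum(records$phenotype %in% c("DMD", "IMD")), nrow(records))
}

#' Clinical summary for one mutation
#'
#' Per-mutation "pie" data: phenotype split, western-blot amount and size
#' splits, cardiomyopathy and mental-retardation shares, each with an
#' explicit missing-data share, as integer percentages of the patients
#' carrying the mutation.
#'
#' @param records Patient records.
#' @param mutation_id Mutation identifier.
#' @return A `mutation_clinical_summary`: list of data.frames (`phenotype`,
#'   `wb_amount`, `wb_size`, `cardiomyopathy`, `mental_retardation`) plus
#'   `n_patients`.
#' @export
per_mutation_summary <- function(records, mutation_id) {
  sub <- records[records$mutation_id == mutation_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown mutation_id: ", mutation_id)
  pie <- function(col) {
    lv <- .registry_vocab[[col]]
    n <- vapply(lv, function(v) sum(sub[[col]] == v), integer(1))
    data.frame(category = lv, n = as.integer(n),
               pct = .int_pct(n, nrow(sub)), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  structure(list(
    mutation_id = mutation_id,
    n_patients = nrow(sub),
    phenotype = pie("phenotype"),
    wb_amount = pie("wb_amount"),
    wb_size = pie("wb_size"),
    cardiomyopathy = pie("cardiomyopathy"),
    mental_retardation = pie("mental_retardation")
  ), class = "mutation_clinical_summary")
}

#' @export
print.mutation_clinical_summary <- function(x, ...) {
  cat("Mutation ", x$mutation_id, ": ", x$n_patients, " patients\n", sep = "")
  for (nm in c("phenotype", "wb_amount", "wb_size", "cardiomyopathy",
               "mental_retardation")) {
    df <- x[[nm]]
    df <- df[df$n > 0, , drop = FALSE]
    cat("  ", nm, ": ",
        paste0(df$category, " ", df$pct, "%", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cohort-level summary of a registry
#'
#' Aggregates a registry into the cohort statistics a curator reports:
#' mutation-type breakdown, phenotype distribution, reading-frame-rule
#' exception share, and per-mutation cohort shares (one decimal).
#'
#' @param records Patient records.
#' @param mutations Mutation table (`mutation_id`, `kind`).
#' @return A `cohort_summary` object.
#' @export
cohort_summary <- function(records, mutations) {
  shares <- sort(table(records$mutation_id), decreasing = TRUE)
  structure(list(
    n_patients = nrow(records),
    n_mutations = length(unique(mutations$mutation_id)),
    mutation_types = mutation_type_breakdown(records, mutations),
    phenotypes = phenotype_distribution(records),
    reading_frame_exception_pct = reading_frame_exceptions(records),
    cohort_share_pct = round(100 * as.numeric(shares) / max(1L, nrow(records)), 1),
    cohort_share_mutation = names(shares)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort: ", x$n_patients, " patients, ", x$n_mutations, " mutations\n", sep = "")
  mt <- x$mutation_types
  cat("  mutation types: ",
      paste0(mt$kind, " ", mt$n, " (", mt$pct, "%)", collapse = ", "), "\n", sep = "")
  ph <- x$phenotypes[x$phenotypes$n > 0, ]
  cat("  phenotypes: ",
      paste0(ph$phenotype, " ", ph$n, " (", ph$pct, "%)", collapse = ", "), "\n", sep = "")
  cat("  reading-frame-rule exceptions: ", x$reading_frame_exception_pct, "%\n", sep = "")
  invisible(x)
}
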