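# Consolidated per-mutation report (the "summary page" view) and the thin
# command-line front-end.

#' Full report for one in-frame mutation
#'
#' Runs the whole projection pipeline for one mutation and assembles the
#' results: HGVS names, product length and (when a wild-type cDNA is
#' supplied) molecular mass, structural/binding/epitope impact tables,
#' isoform effects, the junction classification with its final comment,
#' and, when a registry is supplied, the per-mutation clinical summary.
#'
#' @param bundle A `reference_bundle`.
#' @param spec A `mutation_spec` (see [parse_hgvs_c()], [exons_to_mutation()]).
#' @param wildtype_cdna Optional wild-type coding sequence.
#' @param registry Optional registry list (`records`, `mutations`); the
#'   clinical summary is included when `spec` matches a `mutation_id` of
#'   the form `del<first>-<last>` / `dup<first>-<last>`.
#' @return A `mutation_report` object.
#' @export
#' @examples
#' b <- default_bundle()
#' mutation_report(b, exons_to_mutation(b, 45, 47, "deletion"))
mutation_report <- function(bundle, spec, wildtype_cdna = NULL, registry = NULL) {
  cons <- project_mutation(bundle, spec, wildtype_cdna = wildtype_cdna)
  cls <- classify_junction(bundle, cons)
  iso <- if (!is.na(spec$exon_first)) isoform_effects(bundle, spec) else NULL
  clinical <- NULL
  if (!is.null(registry) && !is.na(spec$exon_first)) {
    prefix <- if (spec$kind == "exon_duplication") "dup" else "del"
    mid <- paste0(prefix, spec$exon_first, "-", spec$exon_last)
    if (mid %in% registry$records$mutation_id)
      clinical <- per_mutation_summary(registry$records, mid)
  }
  structure(list(
    bundle_version = bundle$version,
    mutation = list(hgvs_c = spec$hgvs_c, hgvs_p = cons$hgvs_p,
                    kind = spec$kind,
                    exon_first = spec$exon_first, exon_last = spec$exon_last),
    product = list(cdna_length_nt = bundle$transcript$coding_length_nt -
                     (if (spec$kind == "exon_duplication") -1L else 1L) *
                     (spec$c_end - spec$c_start + 1L),
                   protein_length_aa = cons$product_length_aa,
                   mw_kda = cons$mw_kda),
    consequence = cons,
    structural = structural_impacts(bundle, cons),
    binding = binding_impacts(bundle, cons),
    epitopes = epitope_status(bundle, cons),
    isoforms = iso,
    junction = cls,
    clinical = clinical
  ), class = "mutation_report")
}

#' Serialise a mutation report to JSON
#'
#' @param report A `mutation_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  x <- report
  x$consequence <- unclass(x$consequence)
  x$junction$left <- unclass(x$junction$left)
  x$junction$right <- unclass(x$junction$right)
  x$junction <- unclass(x$junction)
  if (!is.null(x$clinical)) x$clinical <- unclass(x$clinical)
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.mutation_report <- function(x, ...) {
  cat("== Mutation report [bundle ", x$bundle_version, "] ==\n", sep = "")
  cat(x$mutation$hgvs_c, " ; ", x$mutation$hgvs_p, "\n", sep = "")
  cat("product: ", x$product$protein_length_aa, " aa",
      if (!is.na(x$product$mw_kda)) paste0(", ", round(x$product$mw_kda), " kDa"),
      "\n", sep = "")
  st <- x$structural[x$structural$status != "intact", , drop = FALSE]
  if (nrow(st) > 0)
    cat("structural domains affected: ",
        paste0(st$domain, " (", st$status, ")", collapse = ", "), "\n", sep = "")
  bd <- x$binding[x$binding$status != "intact", , drop = FALSE]
  if (nrow(bd) > 0)
    cat("binding domains affected: ",
        paste0(bd$domain, " (", bd$status, ")", collapse = ", "), "\n", sep = "")
  ep <- x$epitopes[x$epitopes$status != "detectable", , drop = FALSE]
  if (nrow(ep) > 0)
    cat("epitopes: ", paste0(ep$antibody, " ", ep$status, collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$isoforms)) {
    io <- x$isoforms[x$isoforms$effect != "unaffected", , drop = FALSE]
    if (nrow(io) > 0)
      cat("isoforms: ", paste0(io$isoform, " ", io$effect, collapse = ", "),
          "\n", sep = "")
  }
  cat("junction: ", x$junction$verdict, "\n", sep = "")
  cat("comment: ", x$junction$comment, "\n", sep = "")
  if (!is.null(x$clinical)) print(x$clinical)
  invisible(x)
}

# ---------------------------------------------------------------------------
# command line

.cli_usage <- function() {
  cat("usage: dystrophinr <command> [options]\n",
      "commands:\n",
      "  describe-mutation  --exons F L | --hgvs STR  [--kind del|dup]\n",
      "                     [--bundle PATH] [--format json|text] [--out PATH]\n",
      "  batch              --input mutations.csv [--bundle PATH] [--out-dir DIR]\n",
      "                     [--keep-going]\n",
      "  registry-stats     [--registry registry.csv --mutations mutations.csv]\n",
      "                     [--out PATH]\n",
      "  make-fixtures      --seed INT --out-dir DIR\n", sep = "")
}

.cli_args <- function(args) {
  out <- list(flags = character(0), opts = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--keep-going")) {
      out$flags <- c(out$flags, sub("^--", "", a)); i <- i + 1L
    } else if (a == "--exons") {
      out$opts$exons <- as.integer(args[c(i + 1L, i + 2L)]); i <- i + 3L
    } else if (startsWith(a, "--")) {
      out$opts[[sub("^--", "", a)]] <- args[i + 1L]; i <- i + 2L
    } else { out$flags <- c(out$flags, a); i <- i + 1L }
  }
  out
}

#' Command-line entry point
#'
#' Thin shell over the exported functions; every report field is produced
#' by the same module functions a script would call.  Exit status: 0 on
#' success, 2 on parse/validation errors, 3 for out-of-scope (frame-shift)
#' input.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { .cli_usage(); return(invisible(2L)) }
  cmd <- args[1]
  parsed <- .cli_args(args[-1])
  op <- parsed$opts
  bundle <- tryCatch({
    if (!is.null(op$bundle)) load_reference_bundle(op$bundle) else default_bundle()
  }, error = function(e) { message("error: ", conditionMessage(e)); NULL })
  if (is.null(bundle)) return(invisible(2L))

  status <- tryCatch(switch(
    cmd,
    "describe-mutation" = {
      spec <- if (!is.null(op$hgvs)) {
        parse_hgvs_c(op$hgvs, bundle)
      } else if (!is.null(op$exons)) {
        kind <- switch(op$kind %||% "del", del = "deletion", dup = "duplication",
                       stop("--kind must be del or dup"))
        exons_to_mutation(bundle, op$exons[1], op$exons[2], kind)
      } else stop("describe-mutation needs --hgvs or --exons")
      if (spec$kind != "substitution" && !is_in_frame(spec)) {
        message("error: out of scope: frame-shift mutation")
        return(invisible(3L))
      }
      rep <- mutation_report(bundle, spec)
      if ((op$format %||% "text") == "json") {
        if (!is.null(op$out)) report_json(rep, op$out) else cat(report_json(rep), "\n")
      } else {
        print(rep)
      }
      0L
    },
    "batch" = {
      if (is.null(op$input)) stop("batch needs --input")
      muts <- utils::read.csv(op$input, stringsAsFactors = FALSE)
      dir <- op[["out-dir"]] %||% "."
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      failures <- 0L
      for (i in seq_len(nrow(muts))) {
        res <- tryCatch({
          spec <- exons_to_mutation(bundle, muts$exon_first[i], muts$exon_last[i],
                                    if (muts$kind[i] == "exon_duplication")
                                      "duplication" else "deletion")
          rep <- mutation_report(bundle, spec)
          report_json(rep, file.path(dir, paste0(muts$mutation_id[i], ".json")))
          TRUE
        }, error = function(e) {
          message("row ", i, " (", muts$mutation_id[i], "): ", conditionMessage(e))
          FALSE
        })
        if (!res) {
          failures <- failures + 1L
          if (!"keep-going" %in% parsed$flags) return(invisible(2L))
        }
      }
      if (failures > 0L) 2L else 0L
    },
    "registry-stats" = {
      reg <- if (!is.null(op$registry)) {
        list(records = load_registry(op$registry),
             mutations = utils::read.csv(op$mutations, stringsAsFactors = FALSE))
      } else demo_registry()
      cs <- cohort_summary(reg$records, reg$mutations)
      if (!is.null(op$out)) {
        jsonlite::write_json(unclass(cs), op$out, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
      } else print(cs)
      0L
    },
    "make-fixtures" = {
      seed <- as.integer(op$seed %||% "1")
      dir <- op[["out-dir"]] %||% "fixtures"
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      cfg <- fixture_config(seed = seed)
      gm <- make_gene_model(cfg)
      writeLines(paste0(">synthetic_cdna_seed", seed, "\n", gm$cdna),
                 file.path(dir, "synthetic_cdna.fa"))
      write_registry(make_registry(cfg), dir)
      message("fixtures written to ", dir, " (seed ", seed, ")")
      0L
    },
    { .cli_usage(); 2L }
  ), error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
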