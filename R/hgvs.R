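#' @name mutation_spec
#' @title In-frame mutation specifications
#'
#' @description
#' A `mutation_spec` describes one mutation event on the coding sequence in
#' HGVS-style cDNA coordinates (1-based, inclusive, `c.1` = A of the
#' initiator ATG): an exon deletion or duplication, a small deletion, or a
#' single-nucleotide substitution.  Exon-aligned events carry their exon
#' indices and the `-?/+?` uncertain-intronic-breakpoint flag; downstream
#' arithmetic always uses the exon-boundary cDNA coordinates.
NULL

.mutation_kinds <- c("exon_deletion", "exon_duplication", "small_deletion",
                     "substitution")

new_mutation_spec <- function(kind, c_start, c_end, exon_first = NA_integer_,
                              exon_last = NA_integer_, boundary_uncertain = FALSE,
                              ref = NA_character_, alt = NA_character_,
                              degenerate = FALSE) {
  kind <- match.arg(kind, .mutation_kinds)
  c_start <- as.integer(c_start); c_end <- as.integer(c_end)
  if (is.na(c_start) || is.na(c_end) || c_start > c_end || c_start < 1L)
    stop("invalid cDNA span: ", c_start, "..", c_end)
  spec <- structure(list(
    kind = kind, c_start = c_start, c_end = c_end,
    exon_first = as.integer(exon_first), exon_last = as.integer(exon_last),
    boundary_uncertain = isTRUE(boundary_uncertain),
    ref = ref, alt = alt, degenerate = isTRUE(degenerate),
    hgvs_c = NA_character_
  ), class = "mutation_spec")
  spec$hgvs_c <- format_hgvs_c(spec)
  spec
}

#' Parse an HGVS cDNA mutation description
#'
#' Accepts deletions (`c.1483-?_6438+?del`, `c.1_3del`), duplications
#' (`c.6439-?_6912+?dup`) and substitutions (`c.76A>T`) on the coding
#' sequence.  Whitespace around `_` and the `-?`/`+ ?` breakpoint markers is
#' tolerated.  When the span coincides with a run of whole exons the exon
#' indices are filled in and the event is typed as an exon deletion or
#' duplication.
#'
#' @param s HGVS cDNA string.
#' @param bundle A `reference_bundle` used for coordinate checks and exon
#'   alignment.
#' @return A `mutation_spec`.
#' @export
#' @examples
#' parse_hgvs_c("c.1483-?_6438+?del", default_bundle())
parse_hgvs_c <- function(s, bundle) {
  raw <- s
  s <- gsub("[[:space:]]+", "", s)
  # dialect tolerance: a space instead of "_" after the "-?" marker
  s <- sub("-\\?(?=[0-9])", "-?_", s, perl = TRUE)
  if (!startsWith(s, "c.")) stop("not an HGVS cDNA description (offset 1): ", raw)
  body <- substring(s, 3L)
  L <- bundle$transcript$coding_length_nt

  m <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1]]
  if (length(m) == 4) {
    pos <- as.integer(m[2])
    if (pos > L) stop("coordinate c.", pos, " outside coding sequence (1..", L, ")")
    return(new_mutation_spec("substitution", pos, pos, ref = m[3], alt = m[4]))
  }

  m <- regmatches(body,
                  regexec("^([0-9]+)(-\\?)?(?:_([0-9]+)(\\+\\?)?)?(del|dup)$", body))[[1]]
  if (length(m) == 0)
    stop("malformed HGVS cDNA string (offset ", nchar(raw) , "): ", raw)
  c1 <- as.integer(m[2])
  c2 <- if (m[4] == "") c1 else as.integer(m[4])
  uncertain <- m[3] == "-?" || m[5] == "+?"
  op <- m[6]
  if (c1 > c2) stop("inverted cDNA span in ", raw)
  if (c2 > L) stop("coordinate c.", c2, " outside coding sequence (1..", L, ")")

  ex <- bundle$transcript$exons
  first <- match(c1, ex$c_start)
  last <- match(c2, ex$c_end)
  aligned <- !is.na(first) && !is.na(last)
  if (op == "del") {
    kind <- if (aligned) "exon_deletion" else "small_deletion"
  } else {
    kind <- "exon_duplication"
    if (!aligned) first <- last <- NA_integer_
  }
  new_mutation_spec(kind, c1, c2,
                    exon_first = if (aligned) ex$index[first] else NA_integer_,
                    exon_last = if (aligned) ex$index[last] else NA_integer_,
                    boundary_uncertain = uncertain,
                    degenerate = aligned && !is.na(first) && !is.na(last) &&
                      ex$index[first] == 1L && ex$index[last] == nrow(ex))
}

#' Format a mutation specification as an HGVS cDNA string
#'
#' The canonical form uses `-?`/`+?` markers for exon events with uncertain
#' intronic breakpoints, e.g. `c.6439-?_6912+?del`.
#'
#' @param spec A `mutation_spec`.
#' @return HGVS cDNA string.
#' @export
format_hgvs_c <- function(spec) {
  if (spec$kind == "substitution")
    return(paste0("c.", spec$c_start, spec$ref, ">", spec$alt))
  op <- if (spec$kind == "exon_duplication") "dup" else "del"
  lo <- if (spec$boundary_uncertain) paste0(spec$c_start, "-?") else spec$c_start
  hi <- if (spec$boundary_uncertain) paste0(spec$c_end, "+?") else spec$c_end
  if (spec$c_start == spec$c_end && !spec$boundary_uncertain)
    return(paste0("c.", lo, op))
  paste0("c.", lo, "_", hi, op)
}

#' Build a mutation specification from an exon range
#'
#' @param bundle A `reference_bundle`.
#' @param first,last Exon indices of the deleted or duplicated run.
#' @param kind `"deletion"` or `"duplication"`.
#' @return A `mutation_spec` with uncertain (`-?/+?`) breakpoint markers, as
#'   exon-level rearrangements are mapped from genomic events with unknown
#'   intronic breakpoints.
#' @export
#' @examples
#' exons_to_mutation(default_bundle(), 45, 47, "deletion")
exons_to_mutation <- function(bundle, first, last,
                              kind = c("deletion", "duplication")) {
  kind <- match.arg(kind)
  span <- cdna_span_for_exons(bundle, first, last)
  n <- nrow(bundle$transcript$exons)
  new_mutation_spec(
    if (kind == "deletion") "exon_deletion" else "exon_duplication",
    span[["c_start"]], span[["c_end"]],
    exon_first = first, exon_last = last, boundary_uncertain = TRUE,
    degenerate = first == 1L && last == n
  )
}

#' Is a deletion/duplication in frame?
#'
#' A deletion or duplication preserves the downstream reading frame exactly
#' when its nucleotide span is a multiple of three.
#'
#' @param spec A `mutation_spec` of kind deletion or duplication.
#' @return `TRUE` or `FALSE`.
#' @export
is_in_frame <- function(spec) {
  if (spec$kind == "substitution") stop("in-frame status applies to deletions and duplications")
  (spec$c_end - spec$c_start + 1L) %% 3L == 0L
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(x$hgvs_c, " (", x$kind, sep = "")
  if (!is.na(x$exon_first))
    cat(", exons ", x$exon_first, "-", x$exon_last, sep = "")
  if (x$kind != "substitution")
    cat(if (is_in_frame(x)) ", in-frame" else ", frame-shifting")
  cat(")\n")
  invisible(x)
}
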