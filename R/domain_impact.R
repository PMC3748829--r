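# Interval arithmetic between a mutated residue range and annotation tables.

.overlap_len <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1) + 1L)
}

.event_range <- function(consequence) {
  rng <- consequence$removed_aa_range %||% consequence$duplicated_aa_range
  if (is.null(rng)) stop("consequence carries no removed or duplicated residue range")
  rng
}

.impact_table <- function(df, name_col, consequence) {
  rng <- .event_range(consequence)
  deletion <- !is.null(consequence$removed_aa_range)
  ov <- mapply(.overlap_len, df$aa_start, df$aa_end,
               MoreArgs = list(b1 = rng[1], b2 = rng[2]))
  size <- df$aa_end - df$aa_start + 1L
  status <- rep("intact", nrow(df))
  if (deletion) {
    status[ov > 0L & ov < size] <- "partially_modified"
    status[ov == size] <- "fully_deleted"
  } else {
    # duplication vocabulary is conservative: wholly duplicated domains vs
    # domains spanning a duplication boundary
    status[ov == size] <- "fully_duplicated"
    status[ov > 0L & ov < size] <- "boundary_spanning"
  }
  data.frame(domain = df[[name_col]], status = status,
             overlap_aa = as.integer(ov),
             aa_start = df$aa_start, aa_end = df$aa_end,
             stringsAsFactors = FALSE)
}

#' Structural-domain impact of a mutation
#'
#' Intersects the removed (or duplicated) residue range with the
#' structural-domain table (CH1/CH2, hinges, spectrin-like repeats, WW, EF,
#' ZZ, C-terminal domain): one row per domain with status `intact`,
#' `partially_modified` or `fully_deleted` (for duplications,
#' `fully_duplicated` / `boundary_spanning`) and the number of affected
#' residues.
#'
#' @param bundle A `reference_bundle`.
#' @param consequence A `protein_consequence` from [project_mutation()].
#' @return data.frame of domain impacts.
#' @export
#' @examples
#' b <- default_bundle()
#' cons <- project_mutation(b, exons_to_mutation(b, 45, 47, "deletion"))
#' subset(structural_impacts(b, cons), status != "intact")
structural_impacts <- function(bundle, consequence) {
  .impact_table(bundle$structural, "name", consequence)
}

#' Binding-domain impact of a mutation
#'
#' As [structural_impacts()], over the binding-partner table (ABD1/2, lipid
#' binding domains, nNOS, PAR-1b, synemin, beta-dystroglycan, syntrophin,
#' dystrobrevin).
#'
#' @inheritParams structural_impacts
#' @return data.frame of binding-domain impacts.
#' @export
binding_impacts <- function(bundle, consequence) {
  .impact_table(bundle$binding, "partner", consequence)
}

#' Effect of an exon event on the internal-promoter isoforms
#'
#' The four short isoforms (Dp260, Dp140, Dp116, Dp71) are transcribed from
#' promoters inside DMD introns.  An exon-aligned deletion affects an
#' internal promoter when the deleted genomic interval brackets the host
#' intron (the intron lies between `exon_first - 1` and `exon_last`); it
#' deletes isoform coding sequence when it removes exons at or after the
#' isoform's first exon.  Promoter involvement takes precedence, since
#' without a promoter the isoform is not transcribed at all.
#'
#' @param bundle A `reference_bundle`.
#' @param spec An exon-aligned `mutation_spec`.
#' @return data.frame with columns `isoform`, `effect`
#'   (`unaffected`, `promoter_affected`, `coding_region_deleted`).
#' @export
#' @examples
#' b <- default_bundle()
#' isoform_effects(b, exons_to_mutation(b, 45, 47, "deletion"))
isoform_effects <- function(bundle, spec) {
  if (is.na(spec$exon_first))
    stop("isoform effects are defined for exon-aligned mutations")
  iso <- bundle$isoforms
  f <- spec$exon_first; l <- spec$exon_last
  deletion <- spec$kind != "exon_duplication"
  effect <- vapply(seq_len(nrow(iso)), function(i) {
    pi <- iso$promoter_intron[i]; fe <- iso$first_exon[i]
    if (deletion && pi >= f - 1L && pi <= l) return("promoter_affected")
    if (l >= fe) return(if (deletion) "coding_region_deleted" else "coding_region_duplicated")
    "unaffected"
  }, character(1))
  data.frame(isoform = iso$name, effect = effect, stringsAsFactors = FALSE)
}

#' Antibody epitope status of a mutant protein
#'
#' Intersects the removed residue range with the diagnostic antibody
#' epitopes (Dys-1: rod repeats 8-9; Dys-2: C-terminal residues 3669-3685;
#' Dys-3: N-terminal residues 321-494): each antibody is reported as
#' `detectable`, `epitope_partial` or `epitope_lost`.
#'
#' @inheritParams structural_impacts
#' @return data.frame with columns `antibody`, `status`, `overlap_aa`.
#' @export
epitope_status <- function(bundle, consequence) {
  rng <- consequence$removed_aa_range
  ep <- bundle$epitopes
  if (is.null(rng)) {
    # duplications leave every epitope present
    return(data.frame(antibody = ep$antibody, status = "detectable",
                      overlap_aa = 0L, stringsAsFactors = FALSE))
  }
  ov <- mapply(.overlap_len, ep$aa_start, ep$aa_end,
               MoreArgs = list(b1 = rng[1], b2 = rng[2]))
  size <- ep$aa_end - ep$aa_start + 1L
  status <- rep("detectable", nrow(ep))
  status[ov > 0L & ov < size] <- "epitope_partial"
  status[ov == size] <- "epitope_lost"
  data.frame(antibody = ep$antibody, status = status,
             overlap_aa = as.integer(ov), stringsAsFactors = FALSE)
}
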