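#' Residue index of a cDNA coordinate
#'
#' Maps a coding-sequence nucleotide to the protein residue whose codon
#' contains it: residue `ceiling(c/3)`.  Positions inside the stop codon
#' have no residue and raise an error when a bundle is supplied.
#'
#' @param c_pos cDNA coordinate (vectorised).
#' @param bundle Optional `reference_bundle` for range checks.
#' @return Integer residue index.
#' @export
#' @examples
#' codon_index(1483)  # 495
codon_index <- function(c_pos, bundle = NULL) {
  if (any(c_pos < 1L)) stop("cDNA coordinate must be >= 1")
  if (!is.null(bundle)) {
    lim <- bundle$transcript$coding_length_nt - 3L
    if (any(c_pos > lim))
      stop("coordinate inside the stop codon or beyond (c.", lim + 1L, "..)")
  }
  as.integer(ceiling(c_pos / 3))
}

# average residue masses (Da); protein mass = sum + one water
.aa_residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.01528

.aa_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", E = "Glu",
  Q = "Gln", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", X = "Xaa"
)

#' Average molecular mass of a protein sequence
#'
#' Sum of the standard average residue masses plus one water, reported in
#' kilodaltons at full precision (round for display; the wild-type dp427m
#' sequence gives 427 kDa at integer rounding).
#'
#' @param protein Character scalar over the 20 standard one-letter codes.
#' @return Mass in kDa.
#' @export
#' @examples
#' molecular_weight("G")  # 0.07507 kDa
molecular_weight <- function(protein) {
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) == 0)
    stop("protein must be a non-empty character scalar")
  aa <- strsplit(toupper(protein), "")[[1]]
  unknown <- which(!aa %in% names(.aa_residue_mass))
  if (length(unknown) > 0)
    stop("unknown amino-acid symbol '", aa[unknown[1]], "' at position ", unknown[1])
  (sum(.aa_residue_mass[aa]) + .water_mass) / 1000
}

#' Project an in-frame mutation onto the protein
#'
#' Computes the mutant protein implied by an in-frame deletion or
#' duplication: product length, the removed or duplicated residue range on
#' the wild type, the junction residues (last and first retained wild-type
#' residues flanking the event), whether a novel junctional residue is
#' created by codon splitting, and the HGVS protein-level name.  When the
#' wild-type cDNA is supplied the mutant sequence is built and its average
#' molecular mass reported.
#'
#' Frame-shifting events are refused: this projection is only defined for
#' mutations that preserve the downstream reading frame.
#'
#' @param bundle A `reference_bundle`.
#' @param spec An in-frame `mutation_spec` (deletion or duplication).
#' @param wildtype_cdna Optional wild-type coding sequence (character, length
#'   `coding_length_nt`).
#' @return A `protein_consequence` object.
#' @export
#' @examples
#' b <- default_bundle()
#' project_mutation(b, exons_to_mutation(b, 13, 44, "deletion"))
project_mutation <- function(bundle, spec, wildtype_cdna = NULL) {
  if (spec$kind == "substitution")
    stop("substitutions do not change protein coordinates; projection applies to deletions and duplications")
  if (!is_in_frame(spec))
    stop("out of scope: frame-shift (span of ", spec$c_end - spec$c_start + 1L,
         " nt is not a multiple of 3)")
  L <- bundle$transcript$protein_length_aa
  c1 <- spec$c_start; c2 <- spec$c_end
  span <- c2 - c1 + 1L
  aligned <- (c1 %% 3L == 1L) && (c2 %% 3L == 0L)
  p1 <- as.integer(ceiling(c1 / 3)); p2 <- as.integer(ceiling(c2 / 3))
  deletion <- spec$kind != "exon_duplication"

  if (deletion) {
    product_length <- L - span %/% 3L
    junction_left <- p1 - 1L
    junction_right <- p2 + 1L
  } else {
    # tandem duplication: the junction joins the end of the duplicated block
    # back to its own start
    product_length <- L + span %/% 3L
    junction_left <- p2
    junction_right <- p1
  }
  # a non-codon-aligned in-frame event splits codons at both ends and fuses
  # the two partial codons into one novel junction codon
  has_novel <- !aligned

  cons <- structure(list(
    kind = spec$kind,
    hgvs_c = spec$hgvs_c,
    exon_first = spec$exon_first, exon_last = spec$exon_last,
    wildtype_length_aa = L,
    product_length_aa = as.integer(product_length),
    removed_aa_range = if (deletion) c(p1, p2) else NULL,
    duplicated_aa_range = if (!deletion) c(p1, p2) else NULL,
    junction_left_aa = as.integer(junction_left),
    junction_right_aa = as.integer(junction_right),
    codon_aligned = aligned,
    junctional_novel_residue = NA_character_,
    mw_kda = NA_real_,
    unexpected_stop = FALSE,
    hgvs_p = NA_character_,
    bundle_version = bundle$version
  ), class = "protein_consequence")

  if (!is.null(wildtype_cdna)) {
    seqs <- build_mutant_sequences(bundle, spec, wildtype_cdna)
    cons$mw_kda <- molecular_weight(seqs$protein)
    cons$unexpected_stop <- seqs$unexpected_stop
    if (has_novel && deletion && nchar(seqs$protein) >= p1) {
      # identity of the fused junction codon created by the codon split
      cons$junctional_novel_residue <- substr(seqs$protein, p1, p1)
    }
    cons$hgvs_p <- format_hgvs_p(cons, sequence = translate_cdna(wildtype_cdna)$protein)
  } else {
    # coordinate-only projection: placeholder codes are expected, no warning
    cons$hgvs_p <- format_hgvs_p(cons, anchors = bundle$residue_anchors,
                                 warn = FALSE)
  }
  cons
}

# translate a coding sequence (with or without terminal stop codon) via
# Biostrings; returns the protein and whether an internal stop was hit
translate_cdna <- function(cdna) {
  cdna <- toupper(gsub("[[:space:]]", "", cdna))
  usable <- nchar(cdna) - nchar(cdna) %% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cdna, 1L, usable)),
    no.init.codon = TRUE))
  has_terminal_stop <- endsWith(aa, "*")
  if (has_terminal_stop) aa <- substr(aa, 1L, nchar(aa) - 1L)
  internal <- grepl("\\*", aa)
  if (internal) aa <- sub("\\*.*$", "", aa)
  list(protein = aa, unexpected_stop = internal,
       terminal_stop = has_terminal_stop)
}

#' Build the mutant cDNA and protein sequences
#'
#' Applies the event to the wild-type coding sequence (excision for
#' deletions, tandem duplication for duplications) and translates the
#' result.  An internal stop codon in an in-frame product is unexpected and
#' is flagged, never silently truncated.
#'
#' @param bundle A `reference_bundle`.
#' @param spec An in-frame `mutation_spec`.
#' @param wildtype_cdna Wild-type coding sequence, length `coding_length_nt`.
#' @return `list(cdna =, protein =, unexpected_stop =)`.
#' @export
build_mutant_sequences <- function(bundle, spec, wildtype_cdna) {
  wildtype_cdna <- toupper(gsub("[[:space:]]", "", wildtype_cdna))
  if (nchar(wildtype_cdna) != bundle$transcript$coding_length_nt)
    stop("wild-type cDNA length (", nchar(wildtype_cdna),
         ") != coding_length_nt (", bundle$transcript$coding_length_nt, ")")
  c1 <- spec$c_start; c2 <- spec$c_end
  mutant <- switch(
    spec$kind,
    substitution = {
      if (substr(wildtype_cdna, c1, c1) != spec$ref)
        stop("reference base mismatch at c.", c1)
      paste0(substr(wildtype_cdna, 1, c1 - 1), spec$alt,
             substr(wildtype_cdna, c1 + 1, nchar(wildtype_cdna)))
    },
    exon_duplication = paste0(substr(wildtype_cdna, 1, c2),
                              substr(wildtype_cdna, c1, nchar(wildtype_cdna))),
    # deletions (exon-sized or small)
    paste0(substr(wildtype_cdna, 1, c1 - 1),
           substr(wildtype_cdna, c2 + 1, nchar(wildtype_cdna)))
  )
  tr <- translate_cdna(mutant)
  if (tr$unexpected_stop)
    warning("unexpected internal stop codon in mutant coding sequence")
  list(cdna = mutant, protein = tr$protein, unexpected_stop = tr$unexpected_stop)
}

#' HGVS protein-level name of a consequence
#'
#' Formats `p.<aa><start>_<aa><end>del` / `dup` with three-letter residue
#' codes; single-residue events collapse to `p.<aa><pos>del`.  Residue
#' letters come from the supplied wild-type protein sequence, or failing
#' that from the bundle's curated residue anchors; unknown residues are
#' emitted as `Xaa` with a warning.
#'
#' @param consequence A `protein_consequence`.
#' @param sequence Optional wild-type protein sequence.
#' @param anchors Optional named character vector of known residue
#'   identities (names = residue indices, one-letter codes).
#' @param warn Warn when placeholders have to be used (default `TRUE`).
#' @return HGVS p. string.
#' @export
format_hgvs_p <- function(consequence, sequence = NULL, anchors = NULL,
                          warn = TRUE) {
  rng <- consequence$removed_aa_range %||% consequence$duplicated_aa_range
  if (is.null(rng)) stop("consequence has no removed or duplicated range")
  op <- if (!is.null(consequence$removed_aa_range)) "del" else "dup"
  letter_at <- function(pos) {
    if (!is.null(sequence) && nchar(sequence) >= pos)
      return(substr(sequence, pos, pos))
    if (!is.null(anchors) && as.character(pos) %in% names(anchors))
      return(anchors[[as.character(pos)]])
    NA_character_
  }
  a1 <- letter_at(rng[1]); a2 <- letter_at(rng[2])
  if (is.na(a1) || is.na(a2)) {
    if (warn)
      warning("wild-type residue identities unavailable; using Xaa placeholders")
    if (is.na(a1)) a1 <- "X"
    if (is.na(a2)) a2 <- "X"
  }
  if (rng[1] == rng[2])
    return(paste0("p.", .aa_three[[a1]], rng[1], op))
  paste0("p.", .aa_three[[a1]], rng[1], "_", .aa_three[[a2]], rng[2], op)
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(x$hgvs_c, " -> ", x$hgvs_p, "\n", sep = "")
  cat("  product: ", x$product_length_aa, " aa (wild type ",
      x$wildtype_length_aa, " aa)", sep = "")
  if (!is.na(x$mw_kda)) cat(", ", round(x$mw_kda), " kDa", sep = "")
  cat("\n")
  rng <- x$removed_aa_range %||% x$duplicated_aa_range
  what <- if (!is.null(x$removed_aa_range)) "removed" else "duplicated"
  cat("  ", what, " residues ", rng[1], "-", rng[2],
      "; junction ", x$junction_left_aa, " | ", x$junction_right_aa, "\n", sep = "")
  invisible(x)
}
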