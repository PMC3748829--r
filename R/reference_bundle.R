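#' Load a dystrophin reference bundle
#'
#' A reference bundle ties together every coordinate system the package
#' uses: the transcript model (79 coding exons of dp427m in 1-based HGVS
#' cDNA coordinates, `c.1` = A of the initiator ATG), the structural-domain
#' table (CH1, CH2, hinges H1-H4, spectrin-like repeats R1-R24, WW, EF, ZZ,
#' C-terminal domain), per-repeat helix A/B/C spans with heptad registers,
#' binding-domain and antibody-epitope tables, and the internal-promoter
#' isoform table (Dp260/Dp140/Dp116/Dp71).
#'
#' Bundles are plain JSON documents.  Two curated versions of the dp427m
#' bundle are packaged (see [default_bundle()]); any schema-valid bundle can
#' be loaded from a path, and every invariant is re-checked on load.
#'
#' @param path Path to a bundle JSON file.
#' @return An object of class `reference_bundle`.
#' @seealso [default_bundle()], [validate_bundle()]
#' @export
#' @examples
#' b <- default_bundle()
#' b$transcript$protein_length_aa  # 3685
load_reference_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bundle <- new_reference_bundle(raw)
  problems <- validate_bundle(bundle)
  if (length(problems) > 0) {
    stop("invalid reference bundle (", bundle$version, "):\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  bundle
}

#' The packaged dp427m reference bundle
#'
#' Returns the curated reference bundle for the full-length muscle isoform
#' dp427m (3685 residues, 11058 coding nucleotides including the stop
#' codon).  Repeat and helix boundaries are not defined by any single
#' primary source; two curated versions are shipped, differing in where
#' some repeats start, while the exon-anchored B-helix split points are
#' identical, so junction verdicts agree between versions.
#'
#' @param version `"winder-2012"` (default) or `"koenig-1990"`.
#' @return A `reference_bundle`.
#' @export
default_bundle <- function(version = c("winder-2012", "koenig-1990")) {
  version <- match.arg(version)
  key <- paste0("bundle_", version)
  if (!is.null(.dystrophinr_env[[key]])) return(.dystrophinr_env[[key]])
  file <- switch(version,
                 "winder-2012" = "dp427m_winder2012.json",
                 "koenig-1990" = "dp427m_koenig1990.json")
  path <- system.file("extdata", file, package = "dystrophinr")
  b <- load_reference_bundle(path)
  .dystrophinr_env[[key]] <- b
  b
}

# Build the in-memory representation from a parsed JSON list (or from the
# synthetic generator, which supplies the same shape).  Tables become data
# frames; exon phases are derived, never stored.
new_reference_bundle <- function(raw) {
  ex <- raw$transcript$exons
  exons <- data.frame(
    index = as.integer(unlist(ex$index)),
    c_start = as.integer(unlist(ex$c_start)),
    c_end = as.integer(unlist(ex$c_end))
  )
  exons <- exons[order(exons$index), , drop = FALSE]
  # phase_in: position within codon of the exon's first nucleotide
  # (0 = codon-initial); phase_out: phase_in of the next exon.
  exons$phase_in <- (exons$c_start - 1L) %% 3L
  exons$phase_out <- exons$c_end %% 3L

  to_df <- function(lst, fields, int_fields = fields) {
    if (length(lst) == 0) return(NULL)
    out <- lapply(fields, function(f) {
      v <- vapply(lst, function(x) {
        if (is.null(x[[f]])) NA_character_ else as.character(x[[f]])
      }, character(1))
      if (f %in% int_fields) as.integer(v) else v
    })
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  structural <- to_df(raw$structural, c("name", "aa_start", "aa_end"),
                      c("aa_start", "aa_end"))
  hinges <- to_df(raw$hinges, c("name", "aa_start", "aa_end"),
                  c("aa_start", "aa_end"))
  binding <- to_df(raw$binding, c("partner", "aa_start", "aa_end", "evidence"),
                   c("aa_start", "aa_end"))
  isoforms <- to_df(raw$isoforms, c("name", "promoter_intron", "first_exon"),
                    c("promoter_intron", "first_exon"))
  epitopes <- to_df(raw$epitopes, c("antibody", "aa_start", "aa_end"),
                    c("aa_start", "aa_end"))

  repeats <- NULL
  if (length(raw$repeats) > 0) {
    repeats <- do.call(rbind, lapply(raw$repeats, function(r) {
      pair <- r$b_helix_split_exon_pair
      if (length(pair) == 0) pair <- NULL
      ins <- r$insert
      if (length(ins) == 0) ins <- NULL
      data.frame(
        number = as.integer(r$number),
        aa_start = as.integer(r$aa_start), aa_end = as.integer(r$aa_end),
        helixA_start = as.integer(r$helixA[[1]]), helixA_end = as.integer(r$helixA[[2]]),
        helixB_start = as.integer(r$helixB[[1]]), helixB_end = as.integer(r$helixB[[2]]),
        helixC_start = as.integer(r$helixC[[1]]), helixC_end = as.integer(r$helixC[[2]]),
        heptad_offset_A = as.integer(r$heptad_offset_A %||% 0L),
        heptad_offset_B = as.integer(r$heptad_offset_B %||% 0L),
        heptad_offset_C = as.integer(r$heptad_offset_C %||% 0L),
        split_exon_lo = if (is.null(pair)) NA_integer_ else as.integer(pair[[1]]),
        split_exon_hi = if (is.null(pair)) NA_integer_ else as.integer(pair[[2]]),
        insert_start = if (is.null(ins)) NA_integer_ else as.integer(ins[[1]]),
        insert_end = if (is.null(ins)) NA_integer_ else as.integer(ins[[2]])
      )
    }))
    repeats <- repeats[order(repeats$number), , drop = FALSE]
    # B-helix split residue: the first residue encoded by the second exon of
    # the split pair (the third heptad of helix B for the phased repeats).
    repeats$split_residue <- ifelse(
      is.na(repeats$split_exon_lo), NA_integer_,
      exons$c_end[match(repeats$split_exon_lo, exons$index)] %/% 3L + 1L)
  }

  anchors <- character(0)
  if (length(raw$residue_anchors) > 0) {
    anchors <- vapply(raw$residue_anchors, function(x) as.character(x), character(1))
    names(anchors) <- names(raw$residue_anchors)
  }

  structure(list(
    version = as.character(raw$version),
    transcript = list(
      name = as.character(raw$transcript$name),
      protein_length_aa = as.integer(raw$transcript$protein_length_aa),
      coding_length_nt = as.integer(raw$transcript$coding_length_nt),
      exons = exons
    ),
    structural = structural,
    hinges = hinges,
    repeats = repeats,
    binding = binding,
    isoforms = isoforms,
    epitopes = epitopes,
    rod_exon_range = as.integer(unlist(raw$rod_exon_range)),
    rod_aa_span = as.integer(unlist(raw$rod_aa_span)),
    residue_anchors = anchors,
    cdna = if (is.null(raw$cdna)) NULL else as.character(raw$cdna)
  ), class = "reference_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a reference bundle
#'
#' Checks every structural invariant of the bundle: exon spans tile the
#' coding sequence contiguously from c.1; the coding length equals
#' `3 * (protein_length_aa + 1)` (stop codon included); repeats are sorted,
#' non-overlapping, with ordered A < B < C helices; each phased repeat's
#' B-helix split border is codon-aligned and falls inside helix B; domain,
#' binding and epitope coordinates stay within the protein; the rod span is
#' covered by exactly one repeat or hinge at every residue; and isoform
#' promoter introns precede their first exons.
#'
#' @param bundle A `reference_bundle`.
#' @return Character vector of violations, empty when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  p <- character(0)
  say <- function(...) p[[length(p) + 1L]] <<- paste0(...)
  tx <- bundle$transcript
  ex <- tx$exons

  if (nrow(ex) == 0) return("transcript has no exons")
  if (ex$c_start[1] != 1L) say("exon 1 must start at c.1")
  if (any(ex$c_end < ex$c_start)) say("exon with c_end < c_start")
  if (nrow(ex) > 1 && any(ex$c_start[-1] != ex$c_end[-nrow(ex)] + 1L))
    say("exons are not contiguous (gaps or overlaps in cDNA coordinates)")
  if (ex$phase_in[1] != 0L) say("phase_in of exon 1 must be 0")
  if (ex$c_end[nrow(ex)] != tx$coding_length_nt)
    say("last exon end (", ex$c_end[nrow(ex)], ") != coding_length_nt (",
        tx$coding_length_nt, ")")
  if (tx$coding_length_nt != 3L * (tx$protein_length_aa + 1L))
    say("coding_length_nt != 3 * (protein_length_aa + 1)")

  L <- tx$protein_length_aa
  check_range <- function(df, start, end, label) {
    if (is.null(df)) return(invisible())
    bad <- which(df[[start]] < 1L | df[[end]] > L | df[[start]] > df[[end]])
    if (length(bad) > 0) say(label, " rows outside 1..", L, ": ",
                             paste(bad, collapse = ", "))
  }
  check_range(bundle$structural, "aa_start", "aa_end", "structural domain")
  check_range(bundle$binding, "aa_start", "aa_end", "binding domain")
  check_range(bundle$epitopes, "aa_start", "aa_end", "epitope")

  if (!is.null(bundle$structural) && nrow(bundle$structural) > 1) {
    s <- bundle$structural[order(bundle$structural$aa_start), ]
    if (any(s$aa_start[-1] <= s$aa_end[-nrow(s)]))
      say("structural domains overlap")
  }

  rp <- bundle$repeats
  if (!is.null(rp)) {
    if (is.unsorted(rp$number, strictly = TRUE)) say("repeat numbers not strictly ascending")
    if (any(rp$aa_start[-1] <= rp$aa_end[-nrow(rp)]))
      say("repeats overlap or are out of order")
    for (i in seq_len(nrow(rp))) {
      r <- rp[i, ]
      ok <- r$aa_start <= r$helixA_start && r$helixA_start <= r$helixA_end &&
        r$helixA_end < r$helixB_start && r$helixB_start <= r$helixB_end &&
        r$helixB_end < r$helixC_start && r$helixC_start <= r$helixC_end &&
        r$helixC_end <= r$aa_end
      if (!ok) say("repeat ", r$number, ": helices not ordered A < B < C within the repeat")
      if (!is.na(r$split_exon_lo)) {
        if (r$split_exon_hi != r$split_exon_lo + 1L)
          say("repeat ", r$number, ": split exon pair not successive")
        ce <- ex$c_end[match(r$split_exon_lo, ex$index)]
        if (is.na(ce)) {
          say("repeat ", r$number, ": split exon not in transcript")
        } else {
          if (ce %% 3L != 0L)
            say("repeat ", r$number, ": B-helix exon border is not codon-aligned")
          split <- ce %/% 3L + 1L
          if (split <= r$helixB_start || split > r$helixB_end)
            say("repeat ", r$number, ": B-helix exon border (residue ", split,
                ") falls outside helix B")
        }
      }
      if (!is.na(r$insert_start) &&
          (r$insert_start > r$insert_end || r$insert_end > r$aa_end))
        say("repeat ", r$number, ": insert range invalid")
    }
  }

  # rod coverage: every residue of the rod span in exactly one repeat or hinge
  if (length(bundle$rod_aa_span) == 2 && !is.null(rp)) {
    rod <- seq.int(bundle$rod_aa_span[1], bundle$rod_aa_span[2])
    cover <- integer(length(rod))
    add <- function(s, e) {
      idx <- pmax(s, rod[1]):pmin(e, rod[length(rod)])
      idx <- idx[idx >= rod[1] & idx <= rod[length(rod)]]
      if (length(idx) > 0) cover[idx - rod[1] + 1L] <<- cover[idx - rod[1] + 1L] + 1L
    }
    for (i in seq_len(nrow(rp))) add(rp$aa_start[i], rp$aa_end[i])
    if (!is.null(bundle$hinges))
      for (i in seq_len(nrow(bundle$hinges)))
        add(bundle$hinges$aa_start[i], bundle$hinges$aa_end[i])
    if (any(cover != 1L))
      say("rod span ", bundle$rod_aa_span[1], "-", bundle$rod_aa_span[2],
          " not covered by exactly one repeat or hinge at ",
          sum(cover != 1L), " residues")
  }

  if (!is.null(bundle$isoforms)) {
    bad <- which(bundle$isoforms$promoter_intron + 1L > bundle$isoforms$first_exon)
    if (length(bad) > 0)
      say("isoform promoter intron does not precede first exon: rows ",
          paste(bad, collapse = ", "))
  }
  p
}

#' Map a cDNA coordinate to its exon
#'
#' @param bundle A `reference_bundle`.
#' @param c_pos 1-based cDNA coordinate (may be a vector).
#' @return Integer exon index (vectorised).
#' @export
#' @examples
#' exon_for_cdna_pos(default_bundle(), 1483)  # 13
exon_for_cdna_pos <- function(bundle, c_pos) {
  ex <- bundle$transcript$exons
  if (any(c_pos < 1L | c_pos > bundle$transcript$coding_length_nt))
    stop("cDNA coordinate out of range 1..", bundle$transcript$coding_length_nt)
  idx <- findInterval(c_pos, ex$c_start)
  ex$index[idx]
}

#' cDNA span covered by a run of exons
#'
#' @param bundle A `reference_bundle`.
#' @param first_exon,last_exon Exon indices, `first_exon <= last_exon`.
#' @return Named integer vector `c(c_start =, c_end =)`.
#' @export
#' @examples
#' cdna_span_for_exons(default_bundle(), 45, 47)  # c.6439..6912
cdna_span_for_exons <- function(bundle, first_exon, last_exon) {
  ex <- bundle$transcript$exons
  n <- nrow(ex)
  if (!(first_exon >= 1L && last_exon <= n && first_exon <= last_exon))
    stop("exon range must satisfy 1 <= first <= last <= ", n)
  c(c_start = ex$c_start[match(first_exon, ex$index)],
    c_end = ex$c_end[match(last_exon, ex$index)])
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("Reference bundle '", x$version, "' (", x$transcript$name, ")\n", sep = "")
  cat("  exons: ", nrow(x$transcript$exons),
      ", coding: ", x$transcript$coding_length_nt, " nt, protein: ",
      x$transcript$protein_length_aa, " aa\n", sep = "")
  if (!is.null(x$repeats))
    cat("  spectrin-like repeats: ", nrow(x$repeats),
        " (", sum(!is.na(x$repeats$split_exon_lo)),
        " with in-frame B-helix exon borders)\n", sep = "")
  if (!is.null(x$binding)) cat("  binding domains: ", nrow(x$binding), "\n", sep = "")
  invisible(x)
}
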