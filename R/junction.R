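# Rod-domain junction phasing: hybrid vs fractional spectrin-like repeats.
#
# Each spectrin-like repeat is a triple coiled-coil of helices A, B and C.
# Coiled-coil helices follow a seven-residue heptad register (letters a-g,
# apolar residues at a and d).  In the phased repeats the B helix is
# encoded by two successive exons whose codon-aligned border sits at the
# start of the third heptad of the helix; an in-frame deletion that joins
# the N-terminal part of one B helix to the C-terminal part of a later B
# helix at matching register re-creates a full-length, register-continuous
# "hybrid" B helix, and the junction is expected to fold like a native
# repeat.  Junctions that land anywhere else, or that break the register,
# give a "fractional" repeat with no native-like coiled-coil.

.heptad_letters <- letters[1:7]

#' Rod-domain context of a residue
#'
#' Locates a residue within the rod annotation: which repeat or hinge it
#' belongs to, which element of the repeat (helix A/B/C, loop AB/BC,
#' register-less insert, or linker residues inside the repeat span), and
#' its heptad letter when it lies in a registered helix.
#'
#' @param bundle A `reference_bundle`.
#' @param residue Residue index (1-based).
#' @return A `junction_context` list with fields `residue`, `repeat_number`,
#'   `hinge`, `helix`, `heptad_letter`.
#' @export
#' @examples
#' rod_context_at(default_bundle(), 494)  # helix B of repeat 2, letter g
rod_context_at <- function(bundle, residue) {
  if (residue < 1L || residue > bundle$transcript$protein_length_aa)
    stop("residue out of range 1..", bundle$transcript$protein_length_aa)
  ctx <- list(residue = as.integer(residue), repeat_number = NA_integer_,
              hinge = NA_character_, helix = "none",
              heptad_letter = NA_character_)
  h <- bundle$hinges
  if (!is.null(h)) {
    i <- which(h$aa_start <= residue & residue <= h$aa_end)
    if (length(i) == 1) {
      ctx$hinge <- h$name[i]
      class(ctx) <- "junction_context"
      return(ctx)
    }
  }
  rp <- bundle$repeats
  i <- which(rp$aa_start <= residue & residue <= rp$aa_end)
  if (length(i) != 1) {
    class(ctx) <- "junction_context"
    return(ctx)
  }
  r <- rp[i, ]
  ctx$repeat_number <- r$number
  helix_of <- function() {
    if (!is.na(r$insert_start) && residue >= r$insert_start && residue <= r$insert_end)
      return("insert")
    if (residue >= r$helixA_start && residue <= r$helixA_end) return("A")
    if (residue >= r$helixB_start && residue <= r$helixB_end) return("B")
    if (residue >= r$helixC_start && residue <= r$helixC_end) return("C")
    if (residue > r$helixA_end && residue < r$helixB_start) return("loopAB")
    if (residue > r$helixB_end && residue < r$helixC_start) return("loopBC")
    "linker"
  }
  ctx$helix <- helix_of()
  if (ctx$helix %in% c("A", "B", "C")) {
    start <- switch(ctx$helix, A = r$helixA_start, B = r$helixB_start, C = r$helixC_start)
    offset <- switch(ctx$helix, A = r$heptad_offset_A, B = r$heptad_offset_B,
                     C = r$heptad_offset_C)
    ctx$heptad_letter <- .heptad_letters[((offset + residue - start) %% 7L) + 1L]
  }
  class(ctx) <- "junction_context"
  ctx
}

#' @export
print.junction_context <- function(x, ...) {
  cat("residue ", x$residue, ": ", sep = "")
  if (!is.na(x$hinge)) {
    cat("hinge ", x$hinge, "\n", sep = "")
  } else if (!is.na(x$repeat_number)) {
    cat("repeat ", x$repeat_number, ", ", x$helix, sep = "")
    if (!is.na(x$heptad_letter)) cat(", heptad '", x$heptad_letter, "'", sep = "")
    cat("\n")
  } else cat("outside the rod domain\n")
  invisible(x)
}

.cyclic_successor <- function(letter) {
  .heptad_letters[(match(letter, .heptad_letters) %% 7L) + 1L]
}

# split residue of a repeat's B helix: the third-heptad border used to
# divide the helix into its N-terminal and C-terminal parts.  Phased
# repeats carry the exon-anchored split; for repeats without an in-frame
# exon pair the third-heptad position itself is used.
.b_split <- function(r) {
  if (!is.na(r$split_residue)) r$split_residue else r$helixB_start + 14L
}

#' Classify a rod-domain deletion junction
#'
#' Applies the exon-phasing/heptad rule to the junction of an in-frame
#' deletion (or, with reduced confidence, to the tandem junction of a
#' duplication):
#'
#' * `non_rod` - the deleted exon range lies outside the rod-encoding exons
#'   (or, for non exon-aligned events, the removed residues leave the rod);
#' * `native_boundary` - the removal excises an integer set of whole
#'   repeats and/or hinges, leaving two native boundaries abutting;
#' * `hybrid_repeat` - the left junction residue lies in the N-terminal
#'   part of one repeat's B helix (strictly before its third-heptad split),
#'   the right junction residue at/after the split of a later repeat's B
#'   helix, and the right residue's heptad letter is the cyclic successor
#'   of the left residue's letter: the fused B helix is register-continuous
#'   and a native-like triple coiled-coil can re-form;
#' * `fractional_repeat` - anything else: two truncated repeats are joined
#'   without register continuity.
#'
#' A hybrid junction whose removal also swallows a whole hinge is flagged
#' (`flag = "hybrid_with_hinge_loss"`): register continuity holds but the
#' consequences of hinge loss are left open.
#'
#' @param bundle A `reference_bundle`.
#' @param consequence A `protein_consequence` from an in-frame event.
#' @return A `junction_classification` with fields `verdict`, `left`,
#'   `right` (contexts), `donor_repeats`, `phase_preserved`, `hinges_lost`,
#'   `flag`, `confidence`, `comment`, `bundle_version`.
#' @export
#' @examples
#' b <- default_bundle()
#' classify_junction(b, project_mutation(b, exons_to_mutation(b, 13, 44, "deletion")))
classify_junction <- function(bundle, consequence) {
  deletion <- !is.null(consequence$removed_aa_range)
  rng <- .event_range(consequence)
  if (deletion) {
    left <- consequence$junction_left_aa
    right <- consequence$junction_right_aa
  } else {
    # tandem junction: end of the duplicated block joined to its own start
    left <- rng[2]; right <- rng[1]
  }
  confidence <- if (deletion) "normal" else "low"

  out <- structure(list(
    verdict = NA_character_,
    left = NULL, right = NULL,
    donor_repeats = c(NA_integer_, NA_integer_),
    phase_preserved = FALSE,
    hinges_lost = character(0),
    flag = NA_character_,
    confidence = confidence,
    comment = NA_character_,
    bundle_version = bundle$version
  ), class = "junction_classification")

  rod_ex <- bundle$rod_exon_range
  in_rod_exons <- if (!is.na(consequence$exon_first)) {
    consequence$exon_first >= rod_ex[1] && consequence$exon_last <= rod_ex[2]
  } else {
    rng[1] >= bundle$rod_aa_span[1] && rng[2] <= bundle$rod_aa_span[2]
  }
  if (!in_rod_exons) {
    out$verdict <- "non_rod"
    out$comment <- "Mutation lies (at least partly) outside the rod-encoding region; repeat phasing does not apply."
    return(out)
  }

  lc <- rod_context_at(bundle, left)
  rc <- rod_context_at(bundle, right)
  out$left <- lc; out$right <- rc

  # hinges entirely inside the removal
  h <- bundle$hinges
  if (deletion && !is.null(h)) {
    lost <- h$name[h$aa_start >= rng[1] & h$aa_end <= rng[2]]
    out$hinges_lost <- as.character(lost)
  }

  if (deletion) {
    units <- data.frame(name = paste0("R", bundle$repeats$number),
                        aa_start = bundle$repeats$aa_start,
                        aa_end = bundle$repeats$aa_end)
    if (!is.null(h))
      units <- rbind(units, data.frame(name = h$name, aa_start = h$aa_start,
                                       aa_end = h$aa_end))
    if (rng[1] %in% units$aa_start && rng[2] %in% units$aa_end) {
      out$verdict <- "native_boundary"
      out$phase_preserved <- TRUE
      out$comment <- paste0(
        "Whole repeats/hinges are excised; native repeat boundaries abut at the junction",
        if (length(out$hinges_lost) > 0)
          paste0(" (hinge ", paste(out$hinges_lost, collapse = ", "), " lost)"),
        ".")
      return(out)
    }
  }

  rp <- bundle$repeats
  hybrid <- FALSE
  if (!is.na(lc$repeat_number) && !is.na(rc$repeat_number) &&
      lc$helix == "B" && rc$helix == "B" &&
      (!deletion || rc$repeat_number > lc$repeat_number)) {
    rl <- rp[match(lc$repeat_number, rp$number), ]
    rr <- rp[match(rc$repeat_number, rp$number), ]
    n_part <- left < .b_split(rl)
    c_part <- right >= .b_split(rr)
    register_ok <- !is.na(lc$heptad_letter) && !is.na(rc$heptad_letter) &&
      rc$heptad_letter == .cyclic_successor(lc$heptad_letter)
    hybrid <- n_part && c_part && register_ok
    out$phase_preserved <- register_ok
  }

  if (hybrid) {
    out$verdict <- "hybrid_repeat"
    out$donor_repeats <- c(lc$repeat_number, rc$repeat_number)
    hinge_note <- length(out$hinges_lost) > 0
    if (hinge_note) out$flag <- "hybrid_with_hinge_loss"
    out$comment <- paste0(
      "A hybrid repeat is reconstituted at the junction from the N-terminal part of the B helix of repeat ",
      lc$repeat_number, " and the C-terminal part of the B helix of repeat ",
      rc$repeat_number, "; the heptad register is preserved ('",
      lc$heptad_letter, "' -> '", rc$heptad_letter,
      "') and a native-like triple coiled-coil can fold",
      if (hinge_note) paste0(" (note: hinge ",
                             paste(out$hinges_lost, collapse = ", "),
                             " is lost in the deletion)"),
      ".")
  } else {
    out$verdict <- "fractional_repeat"
    out$comment <- paste0(
      "The junction joins two truncated repeats without heptad-register continuity; ",
      "no hybrid repeat can be reconstituted and a fractional repeat is formed.")
  }
  out
}

#' @export
print.junction_classification <- function(x, ...) {
  cat("Junction verdict: ", x$verdict,
      " [bundle ", x$bundle_version, "]\n", sep = "")
  if (!is.na(x$donor_repeats[1]))
    cat("  donor repeats: R", x$donor_repeats[1], " + R", x$donor_repeats[2], "\n", sep = "")
  if (!is.null(x$left)) {
    cat("  left:  "); print(x$left)
    cat("  right: "); print(x$right)
  }
  cat("  ", x$comment, "\n", sep = "")
  invisible(x)
}

#' Verdicts for every in-frame exon deletion within the rod
#'
#' Enumerates all contiguous exon ranges inside the rod-encoding exon span
#' whose nucleotide length is a multiple of three, classifies each
#' junction, and returns the table - the lookup a therapist designing
#' exon-skipping would consult to prefer deletions that reconstitute a
#' hybrid repeat.
#'
#' @param bundle A `reference_bundle`.
#' @return data.frame keyed by `(first_exon, last_exon)` with `span_nt`,
#'   `verdict`, `donor_left`, `donor_right`, `phase_preserved`,
#'   `hinges_lost`.
#' @export
skipping_compatibility_matrix <- function(bundle) {
  rod <- bundle$rod_exon_range
  ex <- bundle$transcript$exons
  rows <- list()
  for (f in rod[1]:rod[2]) {
    for (l in f:rod[2]) {
      span <- ex$c_end[match(l, ex$index)] - ex$c_start[match(f, ex$index)] + 1L
      if (span %% 3L != 0L) next
      cons <- project_mutation(bundle, exons_to_mutation(bundle, f, l, "deletion"))
      cls <- classify_junction(bundle, cons)
      rows[[length(rows) + 1L]] <- data.frame(
        first_exon = f, last_exon = l, span_nt = span,
        verdict = cls$verdict,
        donor_left = cls$donor_repeats[1], donor_right = cls$donor_repeats[2],
        phase_preserved = cls$phase_preserved,
        hinges_lost = paste(cls$hinges_lost, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
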