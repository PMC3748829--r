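# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: translation goes through seqinr, heptad letters
# are assigned by an explicit walk, hybrid verdicts are re-derived from
# first principles.

# translate a coding sequence with seqinr, dropping the terminal stop
oracle_translate <- function(cdna) {
  aa <- seqinr::translate(seqinr::s2c(cdna))
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# walk the heptad register letter by letter from the helix start
oracle_walk_letter <- function(start, offset, residue) {
  letter <- offset + 1L
  r <- start
  while (r < residue) {
    r <- r + 1L
    letter <- if (letter == 7L) 1L else letter + 1L
  }
  letters[letter]
}

# first-principles hybrid check for a deletion junction (left, right =
# last/first retained wild-type residues).  Builds the fused register
# explicitly: anchors at the left residue's B helix, walks across the
# junction, and compares with the right residue's native letter.
oracle_hybrid <- function(bundle, left, right) {
  rp <- bundle$repeats
  row_of <- function(res) {
    i <- which(rp$aa_start <= res & res <= rp$aa_end)
    if (length(i) != 1) return(NULL)
    rp[i, ]
  }
  rl <- row_of(left); rr <- row_of(right)
  if (is.null(rl) || is.null(rr)) return(FALSE)
  in_b <- function(r, res) res >= r$helixB_start && res <= r$helixB_end
  if (!in_b(rl, left) || !in_b(rr, right)) return(FALSE)
  if (rr$number <= rl$number) return(FALSE)
  split_l <- if (!is.na(rl$split_residue)) rl$split_residue else rl$helixB_start + 14L
  split_r <- if (!is.na(rr$split_residue)) rr$split_residue else rr$helixB_start + 14L
  if (!(left < split_l && right >= split_r)) return(FALSE)
  letter_left <- oracle_walk_letter(rl$helixB_start, rl$heptad_offset_B, left)
  expected_next <- letters[(match(letter_left, letters[1:7]) %% 7) + 1]
  letter_right <- oracle_walk_letter(rr$helixB_start, rr$heptad_offset_B, right)
  identical(letter_right, expected_next)
}

# every in-frame contiguous exon range within the rod-encoding exons
rod_in_frame_ranges <- function(bundle, width = NULL) {
  ex <- bundle$transcript$exons
  rod <- bundle$rod_exon_range
  out <- list()
  for (f in rod[1]:rod[2]) {
    for (l in f:rod[2]) {
      if (!is.null(width) && l - f + 1L != width) next
      span <- ex$c_end[match(l, ex$index)] - ex$c_start[match(f, ex$index)] + 1L
      if (span %% 3L == 0L) out[[length(out) + 1L]] <- c(f, l)
    }
  }
  out
}

# random in-frame deletion/duplication specs on a bundle, exon-aligned;
# the stop-carrying last exon stays untouched
random_in_frame_specs <- function(bundle, n) {
  ex <- bundle$transcript$exons
  ne <- nrow(ex)
  out <- list()
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    f <- sample.int(ne - 1L, 1)
    l <- if (f == ne - 1L) f else sample(f:(ne - 1L), 1)
    span <- ex$c_end[l] - ex$c_start[f] + 1L
    if (span %% 3L != 0L) next
    kind <- if (stats::runif(1) < 0.8) "deletion" else "duplication"
    out[[length(out) + 1L]] <- exons_to_mutation(bundle, f, l, kind)
  }
  out
}
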