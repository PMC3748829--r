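test_that("cDNA-to-residue mapping follows the ceiling rule", {
  b <- default_bundle()
  expect_identical(codon_index(1L), 1L)
  expect_identical(codon_index(1483L), 495L)
  expect_identical(codon_index(6439L), 2147L)
  expect_identical(codon_index(c(3L, 4L)), c(1L, 2L))
  expect_error(codon_index(11056L, b), "stop")
  expect_error(codon_index(0L), ">= 1")
})

test_that("case-study deletions project to the published products", {
  b <- default_bundle()
  c1 <- project_mutation(b, exons_to_mutation(b, 13, 44, "deletion"))
  expect_identical(c1$product_length_aa, 2033L)
  expect_identical(c1$removed_aa_range, c(495L, 2146L))
  expect_identical(c1$hgvs_p, "p.Val495_Lys2146del")
  expect_identical(c1$junction_left_aa, 494L)
  expect_identical(c1$junction_right_aa, 2147L)

  c2 <- project_mutation(b, exons_to_mutation(b, 45, 47, "deletion"))
  expect_identical(c2$product_length_aa, 3527L)
  expect_identical(c2$removed_aa_range, c(2147L, 2304L))
  expect_identical(c2$hgvs_p, "p.Glu2147_Lys2304del")

  d <- project_mutation(b, exons_to_mutation(b, 45, 47, "duplication"))
  expect_identical(d$product_length_aa, 3685L + 158L)
  expect_identical(d$duplicated_aa_range, c(2147L, 2304L))

  expect_error(project_mutation(b, parse_hgvs_c("c.100del", b)),
               "out of scope: frame-shift")
})

test_that("residue conservation holds for every in-frame exon deletion", {
  b <- default_bundle()
  withr::with_seed(7, {
    specs <- random_in_frame_specs(b, 60)
    for (s in specs) {
      cons <- suppressWarnings(project_mutation(b, s))
      rng <- cons$removed_aa_range %||% cons$duplicated_aa_range
      size <- rng[2] - rng[1] + 1L
      span3 <- (s$c_end - s$c_start + 1L) %/% 3L
      if (s$kind == "exon_deletion") {
        expect_identical(cons$product_length_aa + span3, 3685L)
        # codon-aligned removals lose exactly the range; codon-splitting
        # ones lose one residue fewer (a novel junction codon is re-read)
        expect_identical(size, span3 + as.integer(!cons$codon_aligned))
      } else {
        expect_identical(cons$product_length_aa - span3, 3685L)
      }
    }
  })
})

test_that("mutant sequence building agrees with an independent translation", {
  skip_if_not_installed("seqinr")
  cfg <- fixture_config(seed = 11, n_repeats = 4,
                        fraction_codon_aligned_boundaries = 1)
  gm <- make_gene_model(cfg)
  wt <- oracle_translate(gm$cdna)
  expect_identical(nchar(wt), gm$transcript$protein_length_aa)

  # deleting codon-aligned exons leaves the concatenation of the remaining
  # exon translations
  ex <- gm$transcript$exons
  aligned <- which(ex$c_end %% 3L == 0L & ex$phase_in == 0L)
  aligned <- aligned[aligned > 1 & aligned < nrow(ex)]
  k <- aligned[1]
  s <- exons_to_mutation(gm, ex$index[k], ex$index[k], "deletion")
  seqs <- build_mutant_sequences(gm, s, gm$cdna)
  removed_pep <- substr(wt, ex$c_start[k] %/% 3L + 1L, ex$c_end[k] %/% 3L)
  expect_identical(seqs$protein,
                   paste0(substr(wt, 1, ex$c_start[k] %/% 3L),
                          substr(wt, ex$c_end[k] %/% 3L + 1L, nchar(wt))))
  expect_identical(oracle_translate(seqs$cdna), seqs$protein)

  # duplication of one exon repeats its peptide in tandem
  sd <- exons_to_mutation(gm, ex$index[k], ex$index[k], "duplication")
  seqs_d <- build_mutant_sequences(gm, sd, gm$cdna)
  expect_identical(seqs_d$protein,
                   paste0(substr(wt, 1, ex$c_end[k] %/% 3L), removed_pep,
                          substr(wt, ex$c_end[k] %/% 3L + 1L, nchar(wt))))

  expect_error(build_mutant_sequences(gm, s, "ATG"), "length")
})

test_that("codon-splitting in-frame deletions create one junctional residue", {
  cfg <- fixture_config(seed = 5, n_repeats = 3)
  gm <- make_gene_model(cfg)
  L <- gm$transcript$coding_length_nt
  # enumerate all phase pairs: start offset 0..2 against matching end phase
  for (off in 0:2) {
    c1 <- 301L + off
    c2 <- c1 + 3L * 20L - 1L                 # 60 nt, in frame
    s <- parse_hgvs_c(sprintf("c.%d_%ddel", c1, c2), gm)
    expect_true(is_in_frame(s))
    cons <- suppressWarnings(project_mutation(gm, s, wildtype_cdna = gm$cdna))
    expect_identical(cons$product_length_aa,
                     gm$transcript$protein_length_aa - 20L)
    seqs <- suppressWarnings(build_mutant_sequences(gm, s, gm$cdna))
    expect_identical(nchar(seqs$protein), cons$product_length_aa)
    if (off == 0) {
      expect_true(cons$codon_aligned)
      expect_true(is.na(cons$junctional_novel_residue))
    } else {
      expect_false(cons$codon_aligned)
      expect_identical(cons$junctional_novel_residue,
                       substr(seqs$protein, cons$removed_aa_range[1],
                              cons$removed_aa_range[1]))
    }
  }
})

test_that("average molecular mass follows the standard mass table", {
  expect_equal(molecular_weight("G"), 0.07507, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 0.13212, tolerance = 1e-4)
  expect_error(molecular_weight("GZ"), "position 2")
  expect_error(molecular_weight(""), "non-empty")

  # additivity: mw(AB) = mw(A) + mw(B) - water
  withr::with_seed(13, {
    aa <- names(dystrophinr:::.aa_residue_mass)
    for (i in 1:50) {
      s <- paste(sample(aa, sample(2:60, 1), replace = TRUE), collapse = "")
      cut <- sample(nchar(s) - 1L, 1)
      lhs <- molecular_weight(s)
      rhs <- molecular_weight(substr(s, 1, cut)) +
        molecular_weight(substr(s, cut + 1, nchar(s))) - 18.01528 / 1000
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  })

  # independent cross-check against seqinr's protein mass
  skip_if_not_installed("seqinr")
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(molecular_weight(s) * 1000,
               seqinr::pmw(seqinr::s2c(s)), tolerance = 0.5)
})

test_that("protein-level HGVS names use three-letter codes and anchors", {
  b <- default_bundle()
  cons <- project_mutation(b, exons_to_mutation(b, 13, 44, "deletion"))
  expect_identical(format_hgvs_p(cons, anchors = b$residue_anchors),
                   "p.Val495_Lys2146del")
  expect_warning(nm <- format_hgvs_p(cons), "Xaa")
  expect_identical(nm, "p.Xaa495_Xaa2146del")

  s1 <- parse_hgvs_c("c.1_3del", b)
  c1 <- project_mutation(b, s1)
  expect_identical(c1$hgvs_p, "p.Met1del")
})
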