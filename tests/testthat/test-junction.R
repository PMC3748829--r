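test_that("rod contexts locate residues in repeats, helices and hinges", {
  b <- default_bundle()
  ctx <- rod_context_at(b, 494)
  expect_identical(ctx$repeat_number, 2L)
  expect_identical(ctx$helix, "B")
  expect_identical(ctx$heptad_letter, "g")

  ctx2 <- rod_context_at(b, 2147)
  expect_identical(ctx2$repeat_number, 17L)
  expect_identical(ctx2$heptad_letter, "a")

  hx <- rod_context_at(b, 700)
  expect_identical(hx$hinge, "H2")
  expect_identical(hx$helix, "none")

  # first residue of a helix with offset 0 carries letter 'a'
  r5 <- b$repeats[b$repeats$number == 5L, ]
  expect_identical(rod_context_at(b, r5$helixB_start)$heptad_letter, "a")

  # register-less insert at the end of repeat 15
  r15 <- b$repeats[b$repeats$number == 15L, ]
  ins <- rod_context_at(b, r15$insert_start)
  expect_identical(ins$helix, "insert")
  expect_true(is.na(ins$heptad_letter))

  expect_true(is.na(rod_context_at(b, 100)$repeat_number))  # CH domain region
  expect_error(rod_context_at(b, 0), "out of range")
})

test_that("helix walks produce the cyclic heptad sequence", {
  b <- default_bundle()
  for (num in c(3L, 9L, 24L)) {
    r <- b$repeats[b$repeats$number == num, ]
    letters_walk <- vapply(r$helixB_start:r$helixB_end,
                           function(res) rod_context_at(b, res)$heptad_letter,
                           character(1))
    expected <- vapply(r$helixB_start:r$helixB_end,
                       function(res) oracle_walk_letter(r$helixB_start,
                                                        r$heptad_offset_B, res),
                       character(1))
    expect_identical(letters_walk, expected)
  }
})

test_that("case-study junctions classify as published", {
  b <- default_bundle()
  cls1 <- classify_junction(b, project_mutation(b, exons_to_mutation(b, 13, 44, "deletion")))
  expect_identical(cls1$verdict, "hybrid_repeat")
  expect_identical(cls1$donor_repeats, c(2L, 17L))
  expect_true(cls1$phase_preserved)
  expect_identical(cls1$hinges_lost, "H2")
  expect_match(cls1$comment, "hybrid repeat")

  cls2 <- classify_junction(b, project_mutation(b, exons_to_mutation(b, 45, 47, "deletion")))
  expect_identical(cls2$verdict, "fractional_repeat")
  expect_false(cls2$phase_preserved)

  # ex45-48: junction 2146 | 2367 joins the B helices of the two retained
  # flanking repeats (17 and 19; repeat 18 is removed in full)
  cls3 <- classify_junction(b, project_mutation(b, exons_to_mutation(b, 45, 48, "deletion")))
  expect_identical(cls3$verdict, "hybrid_repeat")
  expect_identical(cls3$donor_repeats, c(17L, 19L))
})

test_that("deletions outside the rod-encoding exons are non_rod", {
  b <- default_bundle()
  s <- exons_to_mutation(b, 2, 7, "deletion")
  expect_true(is_in_frame(s))
  cls <- classify_junction(b, suppressWarnings(project_mutation(b, s)))
  expect_identical(cls$verdict, "non_rod")
})

test_that("whole-repeat excisions restore a native boundary", {
  cfg <- fixture_config(seed = 3, n_repeats = 5)
  gm <- make_gene_model(cfg)
  r3 <- gm$repeats[3, ]
  s <- parse_hgvs_c(sprintf("c.%d_%ddel", 3L * (r3$aa_start - 1L) + 1L,
                            3L * r3$aa_end), gm)
  cls <- classify_junction(gm, suppressWarnings(project_mutation(gm, s)))
  expect_identical(cls$verdict, "native_boundary")
  expect_true(cls$phase_preserved)
})

test_that("split-to-split deletions between phased repeats always give hybrids", {
  b <- default_bundle()
  rp <- b$repeats
  phased <- rp[!is.na(rp$split_exon_lo), ]
  for (i in seq_len(nrow(phased) - 1L)) {
    f <- phased$split_exon_hi[i]
    l <- phased$split_exon_lo[i + 1L]
    s <- exons_to_mutation(b, f, l, "deletion")
    expect_true(is_in_frame(s))
    cls <- classify_junction(b, project_mutation(b, s))
    expect_identical(cls$verdict, "hybrid_repeat")
    expect_true(cls$phase_preserved)
    expect_identical(cls$donor_repeats,
                     c(phased$number[i], phased$number[i + 1L]))
  }
})

test_that("the classifier agrees with the register-walk oracle on all two-exon deletions", {
  b <- default_bundle()
  ranges <- rod_in_frame_ranges(b, width = 2L)
  expect_gt(length(ranges), 10)
  for (r in ranges) {
    cons <- project_mutation(b, exons_to_mutation(b, r[1], r[2], "deletion"))
    cls <- classify_junction(b, cons)
    want <- oracle_hybrid(b, cons$junction_left_aa, cons$junction_right_aa)
    expect_identical(cls$verdict == "hybrid_repeat", want,
                     info = paste("exons", r[1], "-", r[2]))
  }
})

test_that("hybrid verdicts are invariant under whole-heptad register re-anchoring", {
  cfg <- fixture_config(seed = 17, n_repeats = 4, loop_len = c(9L, 12L))
  gm <- make_gene_model(cfg)
  rp <- gm$repeats
  s <- exons_to_mutation(gm, rp$split_exon_hi[2], rp$split_exon_lo[3], "deletion")
  base <- classify_junction(gm, suppressWarnings(project_mutation(gm, s)))
  expect_identical(base$verdict, "hybrid_repeat")
  # re-anchor helix B of the left donor seven residues earlier: the same
  # register annotation in a different gauge
  gm2 <- gm
  gm2$repeats$helixB_start[2] <- gm2$repeats$helixB_start[2] - 7L
  expect_length(validate_bundle(gm2), 0)
  shifted <- classify_junction(gm2, suppressWarnings(project_mutation(gm2, s)))
  expect_identical(shifted$verdict, "hybrid_repeat")
  expect_identical(shifted$donor_repeats, base$donor_repeats)
})

test_that("the skipping-compatibility matrix is complete, in-frame and deterministic", {
  b <- default_bundle()
  m <- skipping_compatibility_matrix(b)
  expect_true(all(m$span_nt %% 3L == 0L))
  key <- paste(m$first_exon, m$last_exon)
  expect_identical(m$verdict[key == "13 44"], "hybrid_repeat")
  expect_identical(m$verdict[key == "45 47"], "fractional_repeat")
  expect_identical(m$verdict[key == "45 48"], "hybrid_repeat")
  # every in-frame range is present, no frame-breaking range is
  expect_identical(nrow(m), length(rod_in_frame_ranges(b)))
  m2 <- skipping_compatibility_matrix(b)
  expect_identical(m, m2)
  # verdicts agree across the two curated bundle versions
  mk <- skipping_compatibility_matrix(default_bundle("koenig-1990"))
  expect_identical(m$verdict, mk$verdict)
})

test_that("duplication junctions classify with reduced confidence", {
  b <- default_bundle()
  d <- project_mutation(b, exons_to_mutation(b, 45, 47, "duplication"))
  cls <- classify_junction(b, d)
  expect_identical(cls$confidence, "low")
  expect_true(cls$verdict %in% c("hybrid_repeat", "fractional_repeat"))
})
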