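del_cons <- function(b, f, l) project_mutation(b, exons_to_mutation(b, f, l, "deletion"))

test_that("structural impact maps match the case-study descriptions", {
  b <- default_bundle()
  si <- structural_impacts(b, del_cons(b, 13, 44))
  stat <- setNames(si$status, si$domain)
  expect_identical(stat[["R2"]], "partially_modified")
  expect_identical(stat[["R17"]], "partially_modified")
  expect_true(all(stat[c(paste0("R", 3:16), "H2")] == "fully_deleted"))
  expect_true(all(stat[c("CH1", "CH2", "H1", "R1", "R18", "WW", "Cterm")] == "intact"))

  si2 <- structural_impacts(b, del_cons(b, 45, 47))
  stat2 <- setNames(si2$status, si2$domain)
  expect_identical(stat2[["R17"]], "partially_modified")
  expect_identical(stat2[["R18"]], "partially_modified")
  expect_true(all(stat2[setdiff(names(stat2), c("R17", "R18"))] == "intact"))

  # an event confined to the C-terminal region leaves every rod domain intact
  si3 <- structural_impacts(b, suppressWarnings(del_cons(b, 71, 71)))
  expect_true(all(si3$status[grepl("^R[0-9]+$|^H[0-9]$", si3$domain)] == "intact"))
})

test_that("binding impact maps match the case-study descriptions", {
  b <- default_bundle()
  bi <- binding_impacts(b, del_cons(b, 13, 44))
  stat <- setNames(bi$status, bi$domain)
  expect_identical(stat[["PAR-1b"]], "fully_deleted")
  expect_identical(stat[["synemin"]], "fully_deleted")
  expect_true(all(stat[c("LBD1", "LBD2", "ABD2", "nNOS")] == "partially_modified"))
  expect_identical(stat[["ABD1"]], "intact")

  bi2 <- binding_impacts(b, del_cons(b, 45, 47))
  stat2 <- setNames(bi2$status, bi2$domain)
  expect_true(all(stat2[c("ABD2", "LBD2", "nNOS")] == "partially_modified"))
  expect_true(all(stat2[setdiff(names(stat2), c("ABD2", "LBD2", "nNOS"))] == "intact"))

  # event outside every binding domain (residues 2515-2624 sit between the
  # LBD2 end and the beta-dystroglycan site)
  bi3 <- binding_impacts(b, suppressWarnings(del_cons(b, 52, 53)))
  expect_true(all(bi3$status == "intact"))
})

test_that("isoform effects follow the promoter/coding rule", {
  b <- default_bundle()
  io <- isoform_effects(b, exons_to_mutation(b, 13, 44, "deletion"))
  eff <- setNames(io$effect, io$isoform)
  expect_identical(eff[["Dp260"]], "promoter_affected")
  expect_identical(eff[["Dp140"]], "promoter_affected")
  expect_identical(eff[["Dp116"]], "unaffected")
  expect_identical(eff[["Dp71"]], "unaffected")

  io2 <- isoform_effects(b, exons_to_mutation(b, 45, 47, "deletion"))
  eff2 <- setNames(io2$effect, io2$isoform)
  expect_identical(eff2[["Dp260"]], "coding_region_deleted")
  expect_identical(eff2[["Dp140"]], "promoter_affected")
  expect_identical(eff2[["Dp116"]], "unaffected")
  expect_identical(eff2[["Dp71"]], "unaffected")

  # a deletion entirely 3' of exon 63 touches all four short isoforms
  io3 <- isoform_effects(b, exons_to_mutation(b, 63, 65, "deletion"))
  expect_true(all(io3$effect != "unaffected"))
})

test_that("epitope status reflects interval overlap with the removal", {
  b <- default_bundle()
  ep <- epitope_status(b, del_cons(b, 13, 44))
  stat <- setNames(ep$status, ep$antibody)
  expect_identical(stat[["Dys-1"]], "epitope_lost")
  expect_identical(stat[["Dys-2"]], "detectable")
  expect_identical(stat[["Dys-3"]], "detectable")  # 321-494 vs removal from 495

  ep2 <- epitope_status(b, del_cons(b, 45, 47))
  expect_true(all(ep2$status == "detectable"))

  # removing the C-terminal residues abolishes the Dys-2 epitope
  expect_true(is_in_frame(parse_hgvs_c("c.11005_11055del", b)))
  cons <- suppressWarnings(project_mutation(b, parse_hgvs_c("c.11005_11055del", b)))
  expect_identical(cons$removed_aa_range, c(3669L, 3685L))
  ep3 <- epitope_status(b, cons)
  expect_identical(setNames(ep3$status, ep3$antibody)[["Dys-2"]], "epitope_lost")
})

test_that("structural overlaps partition the removed range and grow monotonically", {
  b <- default_bundle()
  withr::with_seed(31, {
    for (i in 1:25) {
      f <- sample(10:60, 1); l <- sample(f:61, 1)
      s <- exons_to_mutation(b, f, l, "deletion")
      if (!is_in_frame(s)) next
      cons <- suppressWarnings(project_mutation(b, s))
      si <- structural_impacts(b, cons)
      rng <- cons$removed_aa_range
      # the rod is tiled by repeats and hinges, so overlaps + linker = size;
      # within the rod-encoded removals the linker share is zero
      expect_lte(sum(si$overlap_aa), rng[2] - rng[1] + 1L)
      inside_rod <- rng[1] >= b$rod_aa_span[1] && rng[2] <= b$rod_aa_span[2]
      if (inside_rod)
        expect_identical(sum(si$overlap_aa), rng[2] - rng[1] + 1L)

      # monotonicity: enlarging the deletion never relaxes a domain's status
      if (l < 61) {
        s_big <- exons_to_mutation(b, f, l + 1L, "deletion")
        if (is_in_frame(s_big)) {
          si_big <- structural_impacts(b, suppressWarnings(project_mutation(b, s_big)))
          rank <- c(intact = 0, partially_modified = 1, fully_deleted = 2)
          expect_true(all(rank[si_big$status] >= rank[si$status]))
        }
      }
    }
  })
})
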