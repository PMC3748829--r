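# Seeded synthetic fixtures: gene models with controllable exon phasing and
# patient registries with configurable category frequencies.  All
# randomness flows from the single seed in the config.

#' Configuration for the synthetic-fixture generators
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_repeats Number of spectrin-like repeats in the synthetic rod.
#' @param helixA_len,helixC_len Ranges (length-2 integer) for helix A/C
#'   lengths.
#' @param helixB_len Range for helix B lengths; the B-helix split sits at
#'   the start of the third heptad (helix start + 14), so B helices are at
#'   least 21 residues.
#' @param loop_len Range for loop AB/BC lengths.
#' @param head_aa,tail_aa Residues before/after the rod.
#' @param extra_borders_between Number of additional exon borders placed
#'   between consecutive B-helix split borders (default 1, giving the
#'   two-exons-per-repeat layout).
#' @param fraction_codon_aligned_boundaries Probability that an *extra*
#'   border is codon-aligned (split borders always are).
#' @param registry_size Number of patients for [make_registry()].
#' @param n_mutations Number of distinct mutations for [make_registry()].
#' @param phenotype_freq,cardiomyopathy_freq,mental_retardation_freq,wb_amount_freq,wb_size_freq
#'   Named probability vectors over the registry vocabularies (each must
#'   sum to 1).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_repeats = 6L,
                           helixA_len = c(20L, 29L),
                           helixB_len = c(28L, 38L),
                           helixC_len = c(20L, 31L),
                           loop_len = c(3L, 6L),
                           head_aa = 40L,
                           tail_aa = 30L,
                           extra_borders_between = 1L,
                           fraction_codon_aligned_boundaries = 0.5,
                           registry_size = 200L,
                           n_mutations = 20L,
                           phenotype_freq = c(BMD = 0.78, DMD = 0.14, IMD = 0.02,
                                              pending = 0.04, asymptomatic = 0.015,
                                              DCM = 0.005),
                           cardiomyopathy_freq = c(yes = 0.2, no = 0.5, missing = 0.3),
                           mental_retardation_freq = c(yes = 0.02, no = 0.58, missing = 0.4),
                           wb_amount_freq = c(high = 0.01, medium = 0.05, low = 0.3,
                                              missing = 0.64),
                           wb_size_freq = c(increased = 0.02, normal = 0.05,
                                            reduced = 0.3, undetected = 0.03,
                                            missing = 0.6)) {
  cfg <- list(seed = as.integer(seed), n_repeats = as.integer(n_repeats),
              helixA_len = helixA_len, helixB_len = helixB_len,
              helixC_len = helixC_len, loop_len = loop_len,
              head_aa = as.integer(head_aa), tail_aa = as.integer(tail_aa),
              extra_borders_between = as.integer(extra_borders_between),
              fraction_codon_aligned_boundaries = fraction_codon_aligned_boundaries,
              registry_size = as.integer(registry_size),
              n_mutations = as.integer(n_mutations),
              phenotype_freq = phenotype_freq,
              cardiomyopathy_freq = cardiomyopathy_freq,
              mental_retardation_freq = mental_retardation_freq,
              wb_amount_freq = wb_amount_freq,
              wb_size_freq = wb_size_freq)
  if (cfg$helixB_len[1] < 21L)
    stop("helix B must be at least 21 residues (split at third heptad)")
  for (f in c("phenotype_freq", "cardiomyopathy_freq", "mental_retardation_freq",
              "wb_amount_freq", "wb_size_freq")) {
    if (abs(sum(cfg[[f]]) - 1) > 1e-8)
      stop(f, " must sum to 1 (got ", sum(cfg[[f]]), ")")
    vocab_col <- sub("_freq$", "", f)
    bad <- setdiff(names(cfg[[f]]), .registry_vocab[[vocab_col]])
    if (length(bad) > 0)
      stop(f, ": unknown categories ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "fixture_config")
}

# Body codons are drawn from the T-free alphabet {A,C,G}^3: none of the 27
# codons is a stop, and no fusion of codon fragments at a deletion or
# duplication junction can create one, so in-frame events on synthetic
# models never hit an internal stop.
.sense_codons <- function() {
  b <- c("A", "C", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Generate a synthetic gene model
#'
#' Builds a random multi-exon transcript with a rod of spectrin-like
#' repeats whose B helices are split at their third heptad by codon-aligned
#' exon borders, plus optional extra (possibly frame-breaking) borders, and
#' a matching stop-free random coding sequence.  The result passes
#' [validate_bundle()] and is byte-identical across runs with the same
#' config.
#'
#' @param config A [fixture_config()].
#' @return A `reference_bundle` with an extra `cdna` field (the synthetic
#'   coding sequence).
#' @export
make_gene_model <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, .make_gene_model_impl(config))
}

.make_gene_model_impl <- function(cfg) {
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  pos <- cfg$head_aa + 1L
  repeats <- list()
  for (i in seq_len(cfg$n_repeats)) {
    a_len <- rint(cfg$helixA_len); b_len <- rint(cfg$helixB_len)
    c_len <- rint(cfg$helixC_len)
    l1 <- rint(cfg$loop_len); l2 <- rint(cfg$loop_len)
    a_start <- pos
    b_start <- a_start + a_len + l1
    c_start <- b_start + b_len + l2
    r_end <- c_start + c_len - 1L
    repeats[[i]] <- list(number = i, aa_start = pos, aa_end = r_end,
                         helixA = c(a_start, a_start + a_len - 1L),
                         helixB = c(b_start, b_start + b_len - 1L),
                         helixC = c(c_start, r_end),
                         heptad_offset_A = 0L, heptad_offset_B = 0L,
                         heptad_offset_C = 0L,
                         b_helix_split_exon_pair = NULL, insert = NULL)
    pos <- r_end + 1L
  }
  rod_start <- repeats[[1]]$aa_start
  rod_end <- repeats[[cfg$n_repeats]]$aa_end
  protein_len <- rod_end + cfg$tail_aa
  coding_len <- 3L * (protein_len + 1L)

  # codon-aligned borders at every B-helix split; extras in between
  splits <- vapply(repeats, function(r) r$helixB[1] + 14L, integer(1))
  borders <- 3L * (splits - 1L)  # c_end of the exon preceding the split
  extra <- integer(0)
  anchors <- c(3L * (rod_start - 1L), borders, 3L * rod_end)
  for (j in seq_len(length(anchors) - 1L)) {
    lo <- anchors[j] + 30L; hi <- anchors[j + 1L] - 30L
    if (hi - lo < 2L || cfg$extra_borders_between < 1L) next
    gap <- lo:hi
    picks <- sort(sample(gap, min(cfg$extra_borders_between, length(gap))))
    for (p in picks) {
      if (stats::runif(1) < cfg$fraction_codon_aligned_boundaries)
        p <- p - (p %% 3L)  # force codon alignment
      extra <- c(extra, p)
    }
  }
  ends <- sort(unique(c(borders, extra,
                        3L * (rod_start - 1L), 3L * rod_end, coding_len)))
  ends <- ends[ends >= 1L & ends <= coding_len]
  if (ends[length(ends)] != coding_len) ends <- c(ends, coding_len)
  exons <- data.frame(index = seq_along(ends),
                      c_start = c(1L, utils::head(ends, -1) + 1L),
                      c_end = ends)

  # split exon pairs: the exons meeting at each split border
  for (i in seq_along(repeats)) {
    k <- match(borders[i], exons$c_end)
    repeats[[i]]$b_helix_split_exon_pair <- c(exons$index[k], exons$index[k] + 1L)
  }

  cdna <- paste0(c("ATG", sample(.sense_codons(), protein_len - 1L, replace = TRUE),
                   "TAA"), collapse = "")

  raw <- list(
    version = paste0("synthetic-seed", cfg$seed),
    transcript = list(name = "synthetic", protein_length_aa = protein_len,
                      coding_length_nt = coding_len, exons = exons),
    structural = c(
      list(list(name = "Nterm", aa_start = 1L, aa_end = rod_start - 1L)),
      lapply(repeats, function(r) list(name = paste0("R", r$number),
                                       aa_start = r$aa_start, aa_end = r$aa_end)),
      list(list(name = "Cterm", aa_start = rod_end + 1L, aa_end = protein_len))
    ),
    hinges = NULL,
    repeats = repeats,
    binding = list(list(partner = "partner1", aa_start = rod_start,
                        aa_end = rod_end, evidence = "synthetic")),
    isoforms = list(list(name = "Dp71", promoter_intron = nrow(exons) - 2L,
                         first_exon = nrow(exons) - 1L)),
    epitopes = list(list(antibody = "Dys-2", aa_start = protein_len - 10L,
                         aa_end = protein_len)),
    rod_exon_range = c(exon_of_cdna(exons, 3L * (rod_start - 1L) + 1L),
                       exon_of_cdna(exons, 3L * rod_end)),
    rod_aa_span = c(rod_start, rod_end),
    residue_anchors = list(),
    cdna = cdna
  )
  bundle <- new_reference_bundle(raw)
  problems <- validate_bundle(bundle)
  if (length(problems) > 0)
    stop("generated bundle failed validation: ", paste(problems, collapse = "; "))
  bundle
}

# plain lookup used before a bundle object exists
exon_of_cdna <- function(exons, c_pos) {
  exons$index[findInterval(c_pos, exons$c_start)]
}

#' Generate a random patient registry
#'
#' Samples `registry_size` patients over `n_mutations` synthetic in-frame
#' mutations with the configured category frequencies.  Deterministic under
#' the config seed.
#'
#' @param config A [fixture_config()].
#' @return `list(records =, mutations =)` of data.frames matching the
#'   registry schema.
#' @export
make_registry <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    n <- config$registry_size
    kinds <- sample(c("exon_deletion", "exon_duplication", "substitution",
                      "small_deletion"), config$n_mutations, replace = TRUE,
                    prob = c(0.61, 0.24, 0.11, 0.04))
    mutations <- data.frame(
      mutation_id = sprintf("mut%03d", seq_len(config$n_mutations)),
      kind = kinds, stringsAsFactors = FALSE)
    pick <- function(freq) sample(names(freq), n, replace = TRUE, prob = freq)
    records <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      mutation_id = sample(mutations$mutation_id, n, replace = TRUE),
      phenotype = pick(config$phenotype_freq),
      wb_amount = pick(config$wb_amount_freq),
      wb_size = pick(config$wb_size_freq),
      if_staining = "missing",
      cardiomyopathy = pick(config$cardiomyopathy_freq),
      mental_retardation = pick(config$mental_retardation_freq),
      source = sample(c("laboratory", "literature"), n, replace = TRUE,
                      prob = c(0.56, 0.44)),
      stringsAsFactors = FALSE)
    list(records = validate_registry(records), mutations = mutations)
  })
}

#' The demonstration cohort registry
#'
#' A deterministic reconstruction of the published cohort marginals: 209
#' distinct in-frame mutations (128 exon deletions, 50 duplications, 23
#' missense, 8 small in-frame deletions) carried by 945 patients (733 BMD,
#' 131 DMD, 20 IMD, the rest pending/asymptomatic/DCM), with the exon 45-47
#' deletion subcohort of 223 patients carrying the case-study clinical
#' distributions (214 BMD; 42 with cardiomyopathy; 4 with mental
#' retardation; western-blot amount low 67 / high-or-medium 2 / missing
#' 154; size reduced 67 / normal 7 / missing 149).  It reproduces the
#' cohort *marginals*, not real patients: the joint distribution over
#' mutations beyond the 45-47 subcohort is an arbitrary deterministic
#' spread.
#'
#' @return `list(records =, mutations =)` of data.frames.
#' @export
demo_registry <- function() {
  mutations <- demo_mutation_table()
  del4547 <- "del45-47"

  rep_cat <- function(...) {
    kv <- list(...)
    unlist(mapply(function(v, k) rep(v, k), names(kv), unlist(kv),
                  SIMPLIFY = FALSE), use.names = FALSE)
  }
  sub <- data.frame(
    patient_id = sprintf("P%05d", 1:223),
    mutation_id = del4547,
    phenotype = rep_cat(BMD = 214, DMD = 4, IMD = 1, pending = 4),
    wb_amount = rep_cat(low = 67, high = 1, medium = 1, missing = 154),
    wb_size = rep_cat(reduced = 67, normal = 7, missing = 149),
    if_staining = "missing",
    cardiomyopathy = rep_cat(yes = 42, no = 100, missing = 81),
    mental_retardation = rep_cat(yes = 4, no = 150, missing = 69),
    source = "laboratory",
    stringsAsFactors = FALSE)

  others <- setdiff(mutations$mutation_id, del4547)   # 208 mutations
  extra <- c(rep(4L, 103), rep(2L, 51), rep(0L, 54))  # 514 extra patients
  counts <- 1L + extra                                # each mutation >= 1
  mut_vec <- rep(others, counts)                      # 722 patients
  rest <- data.frame(
    patient_id = sprintf("P%05d", 224:945),
    mutation_id = mut_vec,
    phenotype = rep_cat(BMD = 519, DMD = 127, IMD = 19, pending = 40,
                        asymptomatic = 12, DCM = 5),
    wb_amount = rep_cat(low = 120, medium = 17, missing = 585),
    wb_size = rep_cat(reduced = 110, normal = 27, missing = 585),
    if_staining = "missing",
    cardiomyopathy = rep_cat(yes = 80, no = 300, missing = 342),
    mental_retardation = rep_cat(yes = 15, no = 365, missing = 342),
    source = rep_cat(laboratory = 308, literature = 414),
    stringsAsFactors = FALSE)

  list(records = validate_registry(rbind(sub, rest)), mutations = mutations)
}

#' Mutation table of the demonstration registry
#'
#' 209 in-frame mutations: 128 exon deletions (including the 13-44, 45-47,
#' 45-48 and 45-49 case studies), 50 exon duplications, 23 missense
#' substitutions and 8 small in-frame deletions.  Deletion/duplication exon
#' ranges are in frame on the packaged dp427m transcript.
#'
#' @return data.frame with `mutation_id`, `kind`, `exon_first`, `exon_last`.
#' @export
demo_mutation_table <- function() {
  b <- default_bundle()
  ex <- b$transcript$exons
  in_frame_ranges <- function(n, skip = list()) {
    out <- list()
    for (f in 2:79) {
      for (l in f:79) {
        span <- ex$c_end[l] - ex$c_start[f] + 1L
        if (span %% 3L != 0L) next
        key <- paste(f, l)
        if (key %in% skip) next
        out[[length(out) + 1L]] <- c(f, l)
        if (length(out) == n) return(out)
      }
      if (length(out) == n) break
    }
    out
  }
  forced <- list(c(13L, 44L), c(45L, 47L), c(45L, 48L), c(45L, 49L))
  dels <- c(forced, in_frame_ranges(124, skip = vapply(forced, paste, collapse = " ",
                                                       character(1))))
  dups <- rev(in_frame_ranges(50))
  del_df <- data.frame(
    mutation_id = vapply(dels, function(r) paste0("del", r[1], "-", r[2]), character(1)),
    kind = "exon_deletion",
    exon_first = vapply(dels, `[`, integer(1), 1),
    exon_last = vapply(dels, `[`, integer(1), 2),
    stringsAsFactors = FALSE)
  dup_df <- data.frame(
    mutation_id = vapply(dups, function(r) paste0("dup", r[1], "-", r[2]), character(1)),
    kind = "exon_duplication",
    exon_first = vapply(dups, `[`, integer(1), 1),
    exon_last = vapply(dups, `[`, integer(1), 2),
    stringsAsFactors = FALSE)
  mis_df <- data.frame(mutation_id = sprintf("mis%02d", 1:23),
                       kind = "substitution",
                       exon_first = NA_integer_, exon_last = NA_integer_,
                       stringsAsFactors = FALSE)
  sm_df <- data.frame(mutation_id = sprintf("smdel%d", 1:8),
                      kind = "small_deletion",
                      exon_first = NA_integer_, exon_last = NA_integer_,
                      stringsAsFactors = FALSE)
  rbind(del_df, dup_df, mis_df, sm_df)
}

#' Write a registry to CSV
#'
#' @param registry `list(records =, mutations =)` as returned by
#'   [demo_registry()] or [make_registry()].
#' @param dir Output directory.
#' @return Paths of the two files written, invisibly.
#' @export
write_registry <- function(registry, dir = ".") {
  rp <- file.path(dir, "registry.csv")
  mp <- file.path(dir, "mutations.csv")
  utils::write.csv(registry$records, rp, row.names = FALSE, quote = FALSE)
  utils::write.csv(registry$mutations, mp, row.names = FALSE, quote = FALSE)
  invisible(c(rp, mp))
}
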