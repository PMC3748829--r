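# One-off generator for the curated dp427m reference bundle fixtures.
# Run from the repository root: Rscript tools/make_bundle.R
# Writes inst/extdata/dp427m_winder2012.json and dp427m_koenig1990.json

exon_lengths <- c(
  31, 62, 93, 78, 93, 173, 119, 182, 129, 189,          # 1-10
  182, 151, 120, 102, 108, 180, 176, 124, 88, 242,      # 11-20
  181, 146, 213, 114, 156, 171, 183, 138, 147, 162,     # 21-30
  111, 174, 156, 171, 180, 129, 171, 125, 136, 153,     # 31-40
  183, 195, 173, 148, 176, 148, 150, 186, 102, 109,     # 41-50
  233, 118, 212, 155, 190, 173, 157, 121, 269, 148,     # 51-60
  78, 61, 62, 75, 202, 86, 158, 167, 112, 137,          # 61-70
  39, 67, 66, 159, 243, 125, 71, 32, 33                 # 71-79
)
stopifnot(length(exon_lengths) == 79, sum(exon_lengths) == 11058)
c_end <- cumsum(exon_lengths)
c_start <- c(1L, head(c_end, -1) + 1L)
stopifnot(c_end[12] == 1482, c_end[44] == 6438, c_start[45] == 6439,
          c_end[47] == 6912, c_end[48] == 7098, c_end[10] == 1149,
          c_end[28] == 3924, c_end[38] == 5450)

exons <- data.frame(index = 1:79, c_start = c_start, c_end = c_end)

# Spectrin-like repeats: aa span, helix spans, heptad offsets, and the exon
# pair whose shared (codon-aligned) border splits helix B at its third heptad.
# Repeat 14 has no in-frame split pair (border 38|39 is phase 2).
rp <- function(number, start, end, A, B, C, pair, insert = NULL) {
  list(number = number, aa_start = start, aa_end = end,
       helixA = A, helixB = B, helixC = C,
       heptad_offset_A = 0L, heptad_offset_B = 0L, heptad_offset_C = 0L,
       b_helix_split_exon_pair = pair, insert = insert)
}
repeats <- list(
  rp(1L,  338L,  447L, c(341L,  369L), c(370L,  403L), c(409L,  440L), c(10L, 11L)),
  rp(2L,  448L,  556L, c(451L,  479L), c(481L,  514L), c(520L,  551L), c(12L, 13L)),
  rp(3L,  557L,  666L, c(560L,  588L), c(591L,  624L), c(630L,  661L), c(15L, 16L)),
  rp(4L,  718L,  828L, c(721L,  749L), c(751L,  784L), c(790L,  821L), c(18L, 19L)),
  rp(5L,  829L,  934L, c(832L,  860L), c(861L,  894L), c(900L,  931L), c(20L, 21L)),
  rp(6L,  935L, 1044L, c(938L,  966L), c(970L, 1003L), c(1009L, 1040L), c(22L, 23L)),
  rp(7L, 1045L, 1154L, c(1048L, 1076L), c(1079L, 1112L), c(1118L, 1149L), c(24L, 25L)),
  rp(8L, 1155L, 1264L, c(1158L, 1186L), c(1188L, 1221L), c(1227L, 1258L), c(26L, 27L)),
  rp(9L, 1265L, 1370L, c(1268L, 1293L), c(1295L, 1328L), c(1334L, 1365L), c(28L, 29L)),
  rp(10L, 1371L, 1460L, c(1374L, 1396L), c(1398L, 1431L), c(1437L, 1458L), c(30L, 31L)),
  rp(11L, 1461L, 1570L, c(1464L, 1490L), c(1493L, 1526L), c(1532L, 1563L), c(32L, 33L)),
  rp(12L, 1571L, 1675L, c(1574L, 1600L), c(1602L, 1635L), c(1641L, 1672L), c(34L, 35L)),
  rp(13L, 1676L, 1780L, c(1679L, 1703L), c(1705L, 1738L), c(1744L, 1775L), c(36L, 37L)),
  rp(14L, 1781L, 1880L, c(1784L, 1801L), c(1803L, 1836L), c(1842L, 1873L), NULL),
  rp(15L, 1881L, 1992L, c(1884L, 1898L), c(1900L, 1933L), c(1939L, 1970L), c(40L, 41L),
     insert = c(1971L, 1992L)),
  rp(16L, 1993L, 2100L, c(1996L, 2024L), c(2026L, 2059L), c(2065L, 2096L), c(42L, 43L)),
  rp(17L, 2101L, 2208L, c(2104L, 2131L), c(2133L, 2166L), c(2172L, 2203L), c(44L, 45L)),
  rp(18L, 2209L, 2318L, c(2212L, 2239L), c(2241L, 2274L), c(2280L, 2311L), c(46L, 47L),
     insert = c(2312L, 2318L)),
  rp(19L, 2319L, 2424L, c(2322L, 2350L), c(2353L, 2386L), c(2392L, 2423L), c(48L, 49L)),
  rp(20L, 2471L, 2577L, c(2474L, 2499L), c(2501L, 2534L), c(2540L, 2571L), c(51L, 52L)),
  rp(21L, 2578L, 2686L, c(2581L, 2609L), c(2611L, 2644L), c(2650L, 2681L), c(53L, 54L)),
  rp(22L, 2687L, 2796L, c(2690L, 2718L), c(2726L, 2759L), c(2765L, 2790L), c(55L, 56L)),
  rp(23L, 2797L, 2908L, c(2800L, 2828L), c(2836L, 2869L), c(2875L, 2906L), c(57L, 58L)),
  rp(24L, 2909L, 3021L, c(2912L, 2940L), c(2966L, 2999L), c(3003L, 3020L), c(59L, 60L))
)

# sanity: split border of each pair is codon-aligned and equals helixB start + 14
for (r in repeats) {
  p <- r$b_helix_split_exon_pair
  if (is.null(p)) next
  stopifnot(c_end[p[1]] %% 3 == 0)
  stopifnot(c_end[p[1]] / 3 + 1 == r$helixB[1] + 14)
}
stopifnot(c_end[38] %% 3 != 0)  # repeat 14's B-helix border is out of frame

hinges <- list(
  list(name = "H1", aa_start = 247L, aa_end = 337L),
  list(name = "H2", aa_start = 667L, aa_end = 717L),
  list(name = "H3", aa_start = 2425L, aa_end = 2470L),
  list(name = "H4", aa_start = 3022L, aa_end = 3079L)
)

structural <- c(
  list(list(name = "CH1", aa_start = 14L, aa_end = 119L),
       list(name = "CH2", aa_start = 134L, aa_end = 240L)),
  hinges[1],
  lapply(repeats[1:3], function(r) list(name = paste0("R", r$number),
                                        aa_start = r$aa_start, aa_end = r$aa_end)),
  hinges[2],
  lapply(repeats[4:19], function(r) list(name = paste0("R", r$number),
                                         aa_start = r$aa_start, aa_end = r$aa_end)),
  hinges[3],
  lapply(repeats[20:24], function(r) list(name = paste0("R", r$number),
                                          aa_start = r$aa_start, aa_end = r$aa_end)),
  hinges[4],
  list(list(name = "WW", aa_start = 3080L, aa_end = 3112L),
       list(name = "EF", aa_start = 3130L, aa_end = 3290L),
       list(name = "ZZ", aa_start = 3300L, aa_end = 3360L),
       list(name = "Cterm", aa_start = 3361L, aa_end = 3685L))
)

binding <- list(
  list(partner = "ABD1",             aa_start = 1L,    aa_end = 246L,  evidence = "curated"),
  list(partner = "LBD1",             aa_start = 338L,  aa_end = 666L,  evidence = "curated"),
  list(partner = "LBD2",             aa_start = 718L,  aa_end = 2424L, evidence = "curated"),
  list(partner = "PAR-1b",           aa_start = 1155L, aa_end = 1370L, evidence = "curated"),
  list(partner = "ABD2",             aa_start = 1461L, aa_end = 2208L, evidence = "curated"),
  list(partner = "synemin",          aa_start = 1461L, aa_end = 1880L, evidence = "curated"),
  list(partner = "nNOS",             aa_start = 1993L, aa_end = 2208L, evidence = "curated"),
  list(partner = "beta-dystroglycan", aa_start = 3080L, aa_end = 3360L, evidence = "curated"),
  list(partner = "syntrophin",       aa_start = 3444L, aa_end = 3494L, evidence = "curated"),
  list(partner = "dystrobrevin",     aa_start = 3501L, aa_end = 3675L, evidence = "curated")
)

isoforms <- list(
  list(name = "Dp260", promoter_intron = 29L, first_exon = 30L),
  list(name = "Dp140", promoter_intron = 44L, first_exon = 45L),
  list(name = "Dp116", promoter_intron = 55L, first_exon = 56L),
  list(name = "Dp71",  promoter_intron = 62L, first_exon = 63L)
)

epitopes <- list(
  list(antibody = "Dys-1", aa_start = 1155L, aa_end = 1370L, note = "repeats 8-9"),
  list(antibody = "Dys-2", aa_start = 3669L, aa_end = 3685L, note = "C-terminus"),
  list(antibody = "Dys-3", aa_start = 321L,  aa_end = 494L,  note = "N-terminus")
)

residue_anchors <- list(`1` = "M", `495` = "V", `2146` = "K", `2147` = "E", `2304` = "K")

bundle <- list(
  version = "winder-2012",
  transcript = list(name = "dp427m", protein_length_aa = 3685L,
                    coding_length_nt = 11058L,
                    exons = exons),
  structural = structural,
  hinges = hinges,
  repeats = repeats,
  binding = binding,
  isoforms = isoforms,
  epitopes = epitopes,
  rod_exon_range = c(10L, 61L),
  rod_aa_span = c(247L, 3045L),
  residue_anchors = residue_anchors
)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(bundle, "inst/extdata/dp427m_winder2012.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "columns")

# Alternate curation: repeat starts differ by two residues for the repeats
# whose start the two alignments disagree on; exon-anchored B-helix splits
# are unchanged.
kb <- bundle
kb$version <- "koenig-1990"
shift <- c(2L, 5L, 7L, 9L, 11L, 13L, 15L, 17L, 19L, 21L, 23L)
for (i in shift) {
  kb$repeats[[i]]$aa_start <- kb$repeats[[i]]$aa_start - 2L
  kb$repeats[[i - 1L]]$aa_end <- kb$repeats[[i - 1L]]$aa_end - 2L
  ins <- kb$repeats[[i - 1L]]$insert
  if (!is.null(ins) && ins[2] > kb$repeats[[i - 1L]]$aa_end)
    kb$repeats[[i - 1L]]$insert[2] <- kb$repeats[[i - 1L]]$aa_end
}
# keep the structural table in step with the repeat spans
for (j in seq_along(kb$structural)) {
  nm <- kb$structural[[j]]$name
  if (grepl("^R[0-9]+$", nm)) {
    num <- as.integer(sub("^R", "", nm))
    kb$structural[[j]]$aa_start <- kb$repeats[[num]]$aa_start
    kb$structural[[j]]$aa_end <- kb$repeats[[num]]$aa_end
  }
}
jsonlite::write_json(kb, "inst/extdata/dp427m_koenig1990.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "columns")
cat("wrote bundles\n")
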