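Package: dystrophinr
Title: Protein-Level Consequences of In-Frame DMD Gene Mutations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects in-frame mutations of the DMD gene (exon deletions and
    duplications, small in-frame deletions, substitutions) onto the
    full-length muscle dystrophin isoform dp427m: HGVS cDNA parsing and
    coordinate mapping, mutant protein length, sequence and average
    molecular mass, impact maps over structural domains, binding domains,
    internal-promoter isoforms and diagnostic antibody epitopes, and
    classification of rod-domain deletion junctions as hybrid or fractional
    spectrin-like repeats from exon phasing and coiled-coil heptad register.
    Also aggregates genotype-phenotype registries into cohort statistics and
    ships seeded synthetic gene-model and registry generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
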