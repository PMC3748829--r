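---
title: "Projecting in-frame DMD mutations onto dystrophin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting in-frame DMD mutations onto dystrophin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dystrophinr)
```

## The problem

Most mutations of the DMD gene shift the reading frame, abolish dystrophin
and cause severe Duchenne muscular dystrophy.  In-frame deletions and
duplications instead produce an internally truncated or lengthened protein
with partial function, typically the milder Becker phenotype — with many
exceptions.  Anticipating what the mutant protein looks like matters both
for genotype–phenotype interpretation and for exon-skipping therapy, where
one *chooses* which in-frame deletion to create.

`dystrophinr` computes that projection for the 3685-residue muscle isoform
dp427m (427 kDa; 79 coding exons, 11,058 nt of coding sequence including
the stop codon): coordinates, sequence and mass of the mutant product,
impact on structural and binding domains, internal-promoter isoforms and
diagnostic antibody epitopes, and — the discriminating step — whether the
rod-domain junction created by a deletion can fold back into a native-like
spectrin repeat.

## The coordinate model

All cDNA coordinates are HGVS-style: 1-based, inclusive, `c.1` is the A of
the initiator ATG; protein residues are 1-based from Met1.  The stop codon
is excluded from protein-length arithmetic (3685 aa + stop = 11,058 nt).
A nucleotide `c` belongs to residue `ceiling(c/3)`.

An exon deletion of exons *f*–*l* removes the cDNA span from the first
nucleotide of exon *f* to the last of exon *l*; the HGVS `-?/+?` markers
record that the true genomic breakpoints lie in the flanking introns, but
all protein arithmetic uses the exon-boundary cDNA coordinates, exactly as
the published case-study `c.` spans do.  Duplications are modelled as
direct tandem repeats; mRNA level and stability are out of scope, as are
frame-shifting events, which the projection refuses explicitly.

When an in-frame deletion splits codons at both ends, the two partial
codons fuse into one junction codon.  The removed residue range then
counts both partially encoded residues and one novel residue appears in
the product, so the product length is always `3685 - span/3`.  The HGVS
protein name uses the simple `del` form whenever the junction codon
re-creates a wild-type residue.

## The reference bundle and its provenance

Every table the package consults lives in one versioned JSON document, the
*reference bundle*: exon coordinates, structural domains (CH1/CH2, hinges
H1–H4, repeats R1–R24, WW/EF/ZZ/C-terminal), per-repeat helix spans and
heptad registers, binding domains, isoform promoters and antibody
epitopes.  Every invariant — contiguous exon tiling, ordered helices,
exactly-one coverage of the rod span (residues 247–3045) by repeats and
hinges, codon-aligned B-helix split borders — is re-checked on load.

The exon table is a curated reconstruction of the dp427m (NM_004006.2)
coding exons.  All coordinates that anchor published case studies are
exact (exon 13 starts at c.1483, exon 44 ends at c.6438, exon 45 spans
c.6439.., exon 47 ends at c.6912; total 11,058 nt); the widely used
exon-skipping hotspot exon lengths are used verbatim; a small number of
mid-rod exon ends were curated so that the table satisfies the phasing
regularity described below, which is the property the classifier depends
on.

Repeat and helix boundaries are not printed in any single primary source
and differ between the two classical alignments of the 24 repeats.  The
package therefore ships two curated versions, `winder-2012` (default) and
`koenig-1990`, that differ in where some repeats start but share the
exon-anchored B-helix split points — so junction verdicts, which are
driven by the splits and helix membership, agree between versions, and the
test suite checks this.  Every verdict carries the bundle version it was
computed under.  The register-less extra sequences at the ends of repeats
15 and 18 are stored as insert ranges without heptad letters.

A small table of curated residue identities (Met1, Val495, Lys2146,
Glu2147, Lys2304 — the residues named in published HGVS protein names)
lets the formatter emit `p.Val495_Lys2146del` without the full protein
sequence; for all other positions, placeholder `Xaa` codes are used unless
a wild-type sequence is supplied.  The 11-kb reference sequence itself is
not shipped; sequence-level operations are exercised on synthetic gene
models.

## Exon phasing and the hybrid-repeat rule

Each spectrin-like repeat is a triple coiled-coil of helices A, B and C.
Coiled-coil helices follow the seven-residue heptad register (letters
a–g).  Comparing the repeat alignment with the exon structure reveals a
striking regularity: in 23 of the 24 repeats the B helix is encoded by two
successive exons whose shared border is codon-aligned (phase 0) and falls
at the start of the third heptad of the helix.  Repeat 14 is the single
exception: the exon border crossing its B helix (exons 38|39) splits a
codon.

This regularity is what makes *hybrid repeats* possible.  An in-frame
deletion whose junction joins the N-terminal part of one repeat's B helix
(strictly before its third-heptad split) to the C-terminal part of a later
repeat's B helix (at or after its split), with the right residue's heptad
letter the cyclic successor of the left residue's letter, reconstitutes a
full-length, register-continuous B helix: the junction can fold like a
native repeat.  Junctions that land in loops, hinges, helices A or C, or
the register-less inserts, or that break the register, give *fractional*
repeats with no native-like coiled-coil.  A removal that excises an
integer set of whole repeats and hinges leaves two native boundaries
abutting (`native_boundary`), the situation engineered in mini-dystrophin
constructs.

Operationalising "N-terminal / C-terminal part of the B helix" as
strictly-before / at-or-after the third-heptad split is the only anchoring
consistent with the published junction verdicts, and it makes the rule
self-reinforcing: because all split borders sit at the same register
position (letter *a* of the third heptad), any deletion running from one
split border to another is automatically register-continuous, which is why
deletions of "two such exons, or multiples of two" recreate hybrids.

Three published junctions calibrate the classifier:

* exons 13–44 (`p.Val495_Lys2146del`, 2033 aa): junction 494|2147 joins
  the B helices of repeats 2 and 17 at matching register → hybrid repeat
  (hinge 2 is lost and this is flagged);
* exons 45–47 (`p.Glu2147_Lys2304del`, 3527 aa): junction 2146|2305 lands
  in repeat 18's C helix → fractional repeat;
* exons 45–48: junction 2146|2367 is register-continuous into a later B
  helix → hybrid repeat.

On the donor numbering of the third case: the removal (residues
2147–2366) contains repeat 18 in its entirety, and the repeat whose
B helix carries residue 2367, followed by hinge 3, is repeat 19 — the
same numbering that places repeats 17 and 19 (plus H3) as the retained
flanks of the neighbouring exon 45–49 deletion.  The package therefore
reports the ex45–48 hybrid's donors as repeats 17 and 19.  Descriptions
that call the right-hand donor "repeat 18" count the first retained
repeat *after* the junction rather than the alignment index; the verdict
itself — a hybrid forms — is unaffected.

Junctions whose removal also swallows a whole hinge keep their register
verdict but are flagged `hybrid_with_hinge_loss`: register continuity is a
sequence-level statement, while the consequences of hinge loss (e.g. for
cardiomyopathy) are a separate, unresolved question the package does not
decide.  Duplication junctions are classified by the same rule applied to
the tandem junction and marked low-confidence, since no published
duplication case calibrates them.

`skipping_compatibility_matrix()` enumerates all in-frame contiguous exon
deletions within the rod-encoding exons (10–61) and tabulates their
verdicts — the lookup relevant to choosing an exon-skipping target.

## Domain, isoform and epitope impact

Impact calls are interval arithmetic between the removed (or duplicated)
residue range and the annotation tables: `intact` (no overlap),
`partially_modified`, `fully_deleted`; duplications use the conservative
`fully_duplicated` / `boundary_spanning` vocabulary since no published
duplication case study fixes a stronger one.  Internal-promoter logic: a
short isoform is `promoter_affected` when the deleted exon range brackets
its host intron (intron between `first-1` and `last`), which dominates;
`coding_region_deleted` when the isoform's own exons are removed.  This
rule reproduces both published case-study verdicts (ex13–44: Dp260 and
Dp140 promoters affected, Dp116/Dp71 untouched; ex45–47: Dp260 coding
deleted, Dp140 promoter affected).  Epitope status is the same arithmetic
over the Dys-1 (repeats 8–9), Dys-2 (3669–3685) and Dys-3 (321–494)
epitopes.

Average (not monoisotopic) residue masses are used for protein mass, with
one water added, reported in kDa at full precision and rounded to integers
for display, matching the convention in which dp427m is "427 kDa".  The
mass table is cross-checked in the tests against an independent
implementation (seqinr).

## The registry model

The registry schema records one row per patient: phenotype (BMD / DMD /
IMD / DCM / asymptomatic / pending, with DMD = loss of ambulation before
13 years, BMD after 16, IMD between — documented definitions, not
recomputed), western-blot amount and size categories, immunostaining
pattern, cardiomyopathy, mental retardation, and source.  Missing clinical
data is a first-class category and is never dropped; percentages are
integer-rounded over the full subcohort, with the single exception of the
per-mutation cohort share, reported to one decimal.

`demo_registry()` is a deterministic reconstruction from published cohort
marginals — 209 mutations (128 large deletions, 50 duplications, 23
missense, 8 small in-frame deletions) in 945 patients (733 BMD, 131 DMD,
20 IMD), with a 223-patient exon 45–47 subcohort carrying the published
clinical distributions.  It reproduces the marginals, not real patients:
the joint distribution of the remaining 722 patients over the other 208
mutations is an arbitrary deterministic spread, so only marginal
statistics are meaningful.  One arithmetic wrinkle is encoded faithfully:
the published western-blot figures (amount low 30%, normal-or-high 1%;
size small 30%, normal 3%, missing 67%) are only jointly consistent if the
67% missing share refers to the size row (100−30−3 rounds to 67, while
100−30−1 gives 69); the demo registry realises exactly that.

## Synthetic gene models

`make_gene_model()` generates random multi-exon transcripts with a rod of
repeats whose B helices are split at their third heptad by codon-aligned
exon borders, optional extra (possibly frame-breaking) borders between
them, and a random coding sequence over the T-free codon alphabet
{A,C,G}³.  The T-free alphabet guarantees that no deletion or duplication
junction can fuse codon fragments into a stop codon, so in-frame events on
synthetic models always translate cleanly — which is what lets a
translation oracle check the coordinate projection exhaustively.  What
these models do *not* emulate: real codon usage, splice-site biology,
hinge regions, repeat-length irregularities and the register-less inserts;
passing tests on them validates coordinate arithmetic and register logic,
not biological realism.  All randomness flows from the single seed in
`fixture_config()`, and generation restores the caller's RNG state.

## Numerical and design choices

* Heptad registers are stored per helix as the register letter offset of
  the helix's first residue; all packaged B helices use offset 0, placing
  letter *a* at each helix start and at each third-heptad split.  Only
  *relative* register along a helix and the shared split-position
  convention matter for verdicts, not the absolute letter assignment.
* Repeat 14 can never donate at its B-helix split via an exon-aligned
  deletion: every candidate junction there involves its out-of-frame
  border, so the arithmetic excludes it without a special case.
* Percentages: `round()` to integers over the stated denominator; rounding
  audits in the tests allow the usual ±rounding drift in totals.
* Degenerate inputs: zero-length spans are unrepresentable; whole-gene
  deletions are flagged `degenerate`; substitutions are accepted by the
  parser but refused by the projection (they do not change coordinates).
* Problem sizes: the test suite checks the projection–translation oracle
  on 1000 seeded synthetic mutations over ten gene models, HGVS
  round-trips on 200 generated specifications, and the register-walk
  oracle on every in-frame two-exon deletion in the rod; the acceptance
  script re-runs the 1000-case agreement rate under its command-line seed.

## Known limitations

* The curated exon table and repeat/helix boundaries are reconstructions;
  coordinates not anchored by published case studies may differ from any
  particular alignment's values, and verdicts for junctions far from the
  anchors inherit that uncertainty.  Both curated versions are loadable
  and verdict-equivalent; a user with a better boundary table can load it
  as a bundle and every verdict will carry its version string.
* Hybrid vs fractional is a sequence-register prediction, not a stability
  or function prediction: mRNA stability, protein turnover and binding
  changes are explicitly out of scope.
* The registry statistics describe the demo reconstruction or whatever
  registry the user loads; no statistical association testing is
  performed.
* 3D structure modelling and model-quality scoring are out of scope; the
  register-continuity properties and their oracle tests stand in for
  structure-level validation at desk scale.
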