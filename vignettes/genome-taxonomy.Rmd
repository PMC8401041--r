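---
title: "Genome-based species delimitation and group partitioning in Pseudomonas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based species delimitation and group partitioning in Pseudomonas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The genus *Pseudomonas* is one of the largest among Gram-negative bacteria,
and public databases are full of strains that are unassigned or incorrectly
assigned at the species level. Modern practice resolves this with
genome-scale relatedness: average nucleotide identity (ANI) and digital
DNA–DNA hybridization (dDDH) have replaced wet-lab DNA hybridization as the
operational species definition, while single-copy housekeeping markers such
as *rpoD* remain the cheap first-pass identification tool for large strain
collections. `pseudotax` implements this workflow as composable, tested
pieces:

1. **Marker screen** — extract an *rpoD*-like locus, compute pairwise
   identities on a 650-bp window, and triage strains (confirmed /
   needs-ANI-validation / potential new species).
2. **ANIb engine** — fragment-based ANI between genome pairs with an
   internal seed-and-extend aligner, plus a clearly labelled dDDH surrogate.
3. **Species decision tree** — assign, resolve via dDDH, or call a new
   species; single-linkage clustering collapses synonymous type strains and
   numbers putative new species.
4. **Group delineation** — neighbor-joining trees from marker distances,
   bootstrap supports, and a greedy supported-clade cut into groups and
   subgroups named after the earliest-described member.
5. **CLP screen** — rule-based detection of cyclic-lipopeptide NRPS gene
   clusters and family assignment by synteny.
6. **Synthetic data** — genome, marker, and gene-cluster generators with
   recorded ground truth, so every stage is testable without downloads.

## The ANIb model

ANIb fragments the query genome into consecutive non-overlapping windows of
1020 bp (a terminal fragment is kept only if it is at least 100 bp), aligns
each fragment to the reference, and averages the identities of usable hits:

* a hit is usable when identity >= 30% and at least 70% of the fragment
  aligns (the method's published filter constants; exposed in
  `thresholds()` and overridable);
* identity is matches / alignment columns x 100;
* when no fragment passes, the ANI is *undefined* rather than 0 — the pair
  is simply unrelated at alignable distance.

The aligner is a seed-and-extend local aligner: exact 15-mer seeds are
grouped into diagonal bands, and candidate bands are extended by affine-gap
Smith–Waterman (match +1, mismatch −1, gap open 4, gap extend 1; the
dynamic programming is delegated to `Biostrings::pairwiseAlignment`). On
indel-free synthetic pairs the engine tracks a direct position-wise identity
oracle to well within 0.5 percentage points (the test suite enforces this at
substitution rates 0.5–4%), and self-ANI is exactly 100.

ANIb is directional. The published tables print one value per pair, without
stating a direction or summary; classification here consumes the arithmetic
mean of the two directions, recorded as `mean_of_directions` in every
manifest. This is a package decision, made for symmetric decisions and
consistency with common practice.

### dDDH

Where a measured dDDH (or a printed "dDDH < 70%" flag) is available it is
passed through with `source = "supplied"`. Otherwise an optional surrogate
maps symmetric ANI to a dDDH-scale value through the calibration points
(95, 60), (96.5, 70), (100, 100), piecewise linearly; below ANI 95 the lower
segment's slope is extended and clamped at zero. The two species boundaries
(ANI 96.5, dDDH 70) coincide by construction. The surrogate is a stand-in
for genome-to-genome distance computation, is monotone by construction, is
disabled by default in the pipeline, and is always labelled
`source = "surrogate"` in outputs. It should never be quoted as a measured
dDDH.

## The species decision tree

For a strain with symmetric ANI `a` to its closest type strain:

* `a >= 96.5` — **assigned** to that species;
* `95 <= a < 96.5` — the ambiguity zone: dDDH >= 70 assigns
  (**assigned-via-ddh**), dDDH < 70 calls a **new species**, and absent dDDH
  evidence yields **ambiguous-unresolved** (a first-class outcome; the
  surrogate is never invoked silently);
* `a < 95` — **new species**.

Both interval boundaries are inclusive on the left; the printed
reassignment table treats 96.51 as assigned and resolves 96.15/95.00 through
the dDDH flag, which fixes the convention. Every decision carries a full
rule trace (rule, value, threshold, outcome) so the decision log alone
reconstructs the classification.

Strains called new species are grouped by single-linkage clustering at the
species cutoff and numbered #1, #2, … in input (table row) order, which
makes numbering reproducible. Single linkage matches the synonymy
semantics: any above-threshold link merges clusters. The packaged
reassignment fixture reproduces the published outcome: 25 strains assigned,
19 strains representing 13 new species.

When the reassignment table itself is the input, ambiguous-zone rows
without the below-70 asterisk are treated as carrying a supplied dDDH at or
above 70: the table's footnote flags only sub-70 pairs, and the rows in
question are printed as assigned. This reading is what
`classify_reassignments()` implements.

### Synonymy and the tolerance knob

Type strains whose pairwise ANI reaches the species cutoff are synonyms;
the earliest-described name is retained (ties break lexicographically; a
cluster with no known year falls back to a lexicographic representative
with a warning). The published synonymy table contains two pairs printed at
96.25 and 96.49 — below its own >= 96.5 caption. Whether those were
accepted via dDDH or rounding is not stated, so the package keeps the strict
rule by default and exposes a `tolerance` knob: tolerance 0 drops the two
pairs and reports them as warnings; tolerance 0.25 reproduces the printed
clusters exactly (including a 3-member and a 4-member cluster). Both
behaviours are first-class and documented in the reports.

Description years live in `inst/extdata/species_years.tsv`, curated from
culture-collection records; they are data, editable without code changes.

## Group delineation

Full phylogenomic inference is out of scope; the package builds
neighbor-joining trees from marker identity distances (100 − identity),
with taxa sorted lexicographically so tie-breaking is deterministic, and
accepts externally produced newick trees with support labels. NJ reproduces
additive matrices exactly (the suite checks 4-taxon additive matrices
against a least-squares brute force over all three quartet topologies, at
1e−9). Bootstrap supports come from column resampling of the marker
alignment with per-replicate NJ.

The published delineation criterion — branch length, grouping, and
bootstrap values — is qualitative. The package operationalizes it as a
greedy top-down cut: a clade becomes a group iff its support >= 70 and its
stem branch length >= `min_stem` (default 1 identity-percent unit); within
each group the same rule with `min_stem_subgroup` (default 0.25) yields
subgroups; leaves absorbed by no qualifying clade are orphan groups. The
numeric defaults are explicit package choices calibrated on synthetic data
— they must not be quoted as published values. Rooting uses a supplied
outgroup when available, otherwise midpoint rooting with a logged note.
Groups and subgroups are named `<earliest-described member> G/SG`.

## CLP NRPS screening

*Pseudomonas* cyclic-lipopeptide assembly lines have two diagnostic
features: the final module ends in two consecutive thioesterase (TE)
domains, and no epimerization (E) domain occurs anywhere (D-amino acids are
installed by dual-function C/E condensation domains). Detection is a pure
function of (tandem TE, E domain, completeness):

| tandem TE | E domain | complete | status |
|-----------|----------|----------|----------|
| yes | no | yes | positive |
| yes | no | no | putative |
| yes | yes | any | negative |
| no | any | any | negative |

"Tandem" is read as *at least two* consecutive TEs; the source material
never defines it beyond two. An E domain forces negative even on fragments,
since the absence of epimerization domains is part of the diagnostic. The
putative status captures contig-edge fragments carrying tandem TEs without
a complete module chain — exactly the evidence class reported for
poor-quality genomes.

A module is counted when it carries an adenylation–thiolation (A–T) core,
with an optional leading condensation domain; initiation modules lacking C
count, because published family totals include them. Family assignment is
synteny-only: the total module count and the per-gene module distribution
must match a packaged reference table
(`inst/extdata/clp_family_reference.tsv`), curated from the CLP literature
(Viscosin/WLIP 9 = 2+4+3, Putisolvin 12 = 2+7+3, Entolysin 14 = 2+5+7,
Xantholysin 14 = 2+8+4). The 13-module lipotridecapeptide (LP-13) total is
published; its per-gene distribution here is provisional, as is the
17-module "N8" stub. A total-only match is reported with a
distribution-mismatch note; several total-only candidates yield
`unassigned` with the candidates listed; no match at all is `novel`;
several exact matches raise an error. Amino-acid-level relationships are
assessed separately by global identity of concatenated NRPS sequences with
single-linkage clustering.

Two input dialects are parsed: a simplified domain-string TSV
(`cluster<TAB>gene:+:C-A-T,C-A-T-TE-TE`) and an antiSMASH-v6-style JSON
(`records[].features[]` of type `aSDomain`); thiolation/PCP tokens
normalize to T, unknown tokens warn and become `other`.

## The synthetic-data generator

The generator emulates the study design, not bacterial genomes in full:

* **Ancestors** are i.i.d. sequences at a chosen GC (default 0.60, typical
  for the genus), length >= 10,200 bp so fragmentation is meaningful.
* **Evolution** is uniform site-wise substitution (Jukes–Cantor-like; only
  ANI-scale divergence matters here, so no rate heterogeneity or
  transition/transversion structure) with optional short (1–10 bp)
  Poisson-placed indels. The realized substitution count is recorded as
  ground truth; indels influence ANI only through coverage.
* **Planted species sets** use a star design: species ancestors evolve from
  a root at `between_rate / 2`, strains from their species ancestor at
  `within_rate / 2`, so pairwise divergences land near `within_rate`
  (within) and `between_rate` (between) — the rates name the pairwise
  quantities the 96.5% boundary acts on. Defaults (within 0.01, between
  0.08) straddle the boundary at roughly 99% vs 92% ANI. Planting is
  substitution-only, so the truth divergence matrix is the exact pairwise
  Hamming distance.
* **Markers** are embedded verbatim between fixed 30-bp anchors (on either
  strand), keeping extraction deterministic without a gene caller.
* **Gene clusters** follow the packaged family reference distributions.

What the generator does *not* emulate: real genome length (megabases),
repeats and horizontal transfer, rearrangements, contig fragmentation from
assembly, GC skew and coding structure, and marker paralogy. Passing tests
therefore demonstrate the correctness of the decision logic and the
alignment engine under controlled divergence — not performance on real
assemblies, where repeats and mobile elements make fragment hits noisier.

## Numerical choices and problem sizes

* Seed determinism everywhere: generators restore the RNG state; the
  pipeline funnels all randomness through one seed recorded in the
  manifest.
* The engine-vs-oracle validation runs at 51-kb genomes over substitution
  rates \{0.005, 0.01, 0.02, 0.04\} on a fixed 10-seed panel; the
  planted-partition recovery uses 3 species x 3 strains at 12,240-bp
  genomes (12 ANIb fragments) on the same panel. These sizes keep a full
  run of the validation suite in minutes while leaving every fragment-level
  effect (tail rule, coverage filter, band selection) exercised.
* Local alignment can clip a few terminal mismatches of a fragment; at 4%
  divergence the induced identity bias is far below the 0.5-point oracle
  band, and the coverage filter bounds it structurally.
* `hclust(method = "single")` with `cutree` at height `100 − cutoff`
  implements single linkage with an inclusive boundary (ANI exactly 96.5
  links).
* Degenerate inputs are first-class errors: empty genomes, undefined ANI in
  the decision tree, missing matrix pairs in new-species clustering,
  two-taxon NJ, unrooted trees without an outgroup.

## Known limitations

* The dDDH surrogate is a calibration convenience, not a distance
  computation; conclusions in the ambiguity zone should rest on supplied
  values.
* The aligner is tuned for ANI-scale divergence (>= ~75% identity); it is
  not a general homology search and the empirical-null test only shows that
  unrelated sequences produce no usable hits.
* Group/subgroup thresholds are synthetic-data calibrations; applying them
  to a real marker tree requires the user to revisit `min_stem` on that
  tree's branch-length scale.
* CLP family assignment is architecture-only by design; it cannot separate
  families that share module counts and distributions, and says nothing
  about the produced chemistry.
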