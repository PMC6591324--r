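---
title: "gstfam: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gstfam: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstfam)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator emulates, the numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The survey problem

A gene-family survey starts from a genome release and asks: how many
family members are there, where do they sit, how did the family expand,
under what selective regime, and how are the members regulated? The
package models the workflow of the published pepper GST survey — an
85-member family in ten classes compared against its tomato counterpart —
as a pipeline of small, contract-tested operations, with a packaged
transcription of the published catalog as the reference input.

Two transcription notes on that fixture. The printed "Gene (bp)" column
equals the coordinate span `end − start + 1` for 83 of 85 rows; the two
exceptions (CaGSTU28: printed 630 vs span 1775; CaGSTU31: printed 1223 vs
span 1283) are carried verbatim, not patched. Likewise the source text
says nine genes on chromosome 2 where its own table has eight, reports a
protein-length range of 101–361 aa although the table contains a 654-aa
member, and a pI range of 5–9 against table extremes of 4.37 and 9.74;
the package always trusts the table.

## Catalog annotation

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da). The theoretical pI solves `net_charge(seq, pH) = 0` by
bisection on [0, 14] to |charge| < 10⁻⁴, where the net charge is the
Henderson–Hasselbalch sum over the termini and the D, E, C, Y, H, K, R
side chains. The pKa table (N-term 7.5, C-term 3.55, D 4.05, E 4.45,
H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0) ships as data. Published pI/MW
columns came from a different tool with its own pKa set, so tests check
the fixture by parsing, and check the computation against an independent
10⁻⁵-step pH grid search — not against the printed columns.

Class assignment replaces a conserved-domain database lookup with a
deterministic nearest-reference rule: highest global-alignment score,
ties broken by identity then lexicographic reference id. This is a
testable surrogate, not a reimplementation of the database search.

## Alignment screen and duplicate pairs

Screening approximates a blastp search with Smith–Waterman local
alignment (BLOSUM62, gap open −11 / extend −1, BLAST-style gap cost) and
a Karlin–Altschul expectation `E = K·m·n·exp(−λS)` with the published
gapped-BLOSUM62 constants λ = 0.267, K = 0.041 and no edge-effect
correction. The E ≤ 10⁻¹⁰ threshold and the ≥80% identity rule for
duplicate pairs follow the survey's configuration. Because the source
never defines "80% similar" precisely, identity over gap-free aligned
columns is the default and the denominator is configurable
(`shorter_seq` as the alternative). A gene may belong to several pairs.

Tandem vs segmental: a pair is tandem iff both genes share a chromosome
and the gap between their CDS spans is ≤100 kb, boundary inclusive;
cross-chromosome pairs are segmental by definition. Genomic clusters use
the same window with single-linkage chaining; since the source does not
state its cluster rule, the cluster count is reported alongside the
published 16 rather than gated on it.

## dN/dS and dating

The counting method behind the published dN/dS values is unstated (only
an alignment front-end is named), so the package implements the simplest
published estimator and names it in reports: Nei–Gojobori (1986).
Per-codon site counts give each of the nine single-nucleotide changes
1/3 site weight, excluding changes that create stops. Differences
between codons are averaged with equal weight over all minimal
mutational pathways; pathways through stop codons are excluded, with a
documented fallback to all pathways when every ordering is blocked.
Proportions are Jukes–Cantor corrected, `d = −(3/4)·ln(1 − 4p/3)`, with
a saturation error at p ≥ 3/4 rather than a silent NaN; dS = 0 yields an
undefined ω marker rather than infinity. Divergence time is the
molecular clock `T = dS/(2λ)` at λ = 1.5×10⁻⁸ substitutions/site/year
(the dicot rate), reported in Mya.

Codon alignments are built PAL2NAL-style: proteins are globally aligned
and gaps are threaded back onto the codon sequences; codon columns with
a gap in either sequence are dropped pairwise.

## Gene trees and gain/loss accounting

Maximum-likelihood tree inference is out of scope; trees are built by
neighbor joining on Poisson-corrected pairwise alignment distances
(`d = −ln(1 − p)` over gap-free columns). This is deterministic and
desk-scale, and the reconciliation layer — the part the accounting
depends on — is agnostic to how the tree was made. Negative NJ branch
lengths are clamped to zero with a warning. Rooting is midpoint by
default because the published trees are unrooted and MRCA counts depend
on the root; the rooting method is therefore part of any reported
result. Polytomies are resolved deterministically (left-branching) with
a warning, since species-overlap labeling needs binary nodes.

Species overlap labels an internal node a duplication iff its two child
clades share a species; duplications are `ancestral` (subtree spans both
species) or `lineage` (single-species subtree). The MRCA decomposition
descends from the root: ancestral duplications split into their
children's units; a speciation node spanning both species is one unit; a
maximal single-species clade under an ancestral duplication is one unit
whose absence from the other species is a loss. Units partition the
leaves (asserted), and for each species
`extant = units − losses + gains` is enforced by assertion, never
patched. This decomposition is the minimal algorithm consistent with the
verbal description of the published figure; it is an interpretation, and
the published "at least N MRCA" hedge is preserved in wording. Bootstrap
support resamples alignment columns with replacement, seeded, and scores
each reference bipartition by its replicate frequency.

## Expression

Stress series are expressed as fold change against the 0-h control,
`(x + c)/(x₀ + c)`; the pseudocount default c = 1 guards zero controls,
which the source does not address. Heatmap scaling is per gene to
0–100% of its own range; a constant row maps to all zeros with a
warning. Tiers (low/medium/high) split genes at tertiles of mean log
abundance — the published three groups are described, not defined, so
tertiles are the package's choice and the thresholds are configurable.
"Manhattan correlation" (the heatmap tool's term) is interpreted as the
Manhattan/city-block metric, and the tool's unnamed default linkage as
average linkage; both are configurable. The timepoint sets printed in
the source differ between methods (ending 24 h) and a figure legend
(ending 48 h); the module accepts any timepoint set and records which
was used.

## Promoters

Upstream windows are anchored at the CDS start (the source conflates
"transcription start site" with ATG; the package resolves this as CDS
start and says so), strand-aware, 1000 bp by default, clipped with a
warning at contig edges. Element scanning is exact IUPAC consensus
matching on both strands with overlapping matches counted individually,
checked in tests against a character-by-character sliding-window oracle.
The element catalog ships as an editable TSV with one consensus per
element; the web tool used by the source keeps unpublished per-entry
patterns, so its printed per-element totals (85 MBS, 83 TC-rich, 64 HSE,
63 TCA) are irreproducible exactly and are treated as a documentation
comparison, not an acceptance gate. The enhancer entry
(pyrimidine-rich, TTTCTTCTCT) has no published consensus; the shipped
pattern is the package's choice.

## Enzyme assay

CDNB conjugation at 344 nm converts as rate(mM/min) = ΔA/(ε·ℓ) with
ε = 9.6 mM⁻¹cm⁻¹ and path ℓ in cm; 1 mM/min = 1000 nmol·mL⁻¹·min⁻¹, so
specific activity = rate · V(mL) · 1000 / protein(mg). The source states
no reaction volume, so volume is a required argument with no default.

## The synthetic world

The generator's defaults are a stated world, fixed before testing:

- **Family process**: 10 ancestral genes, per-copy gain and loss rates
  0.02/My in each lineage, split age 36 My (the approximate
  pepper–tomato divergence). Events are post-split only, so MRCA counts
  are exactly checkable; units extinct in both lineages are recorded in
  the truth but absent from the tree. Unit subtrees are joined with a
  two-species unit anchoring the chain and single-species units
  interleaved — otherwise adjacent same-species-only units would merge
  into one apparent unit and exact closure would be impossible by
  construction, not by defect. One identifiability limit remains and is
  recorded in the truth (`identifiable`): when *no* ancestral unit
  survives in both species, a pepper-only and a tomato-only clade joined
  at the root are indistinguishable from a single speciation unit with
  no losses — the more parsimonious history — and any species-overlap
  method must merge them. Closure tests therefore assert exact recovery
  on identifiable trees and treat the unidentifiable remainder as what
  it is: information genuinely absent from the data.
- **Sequences**: founders are random 300-codon CDS; duplicate partners
  evolve at ω = 0.3 (purifying, matching the published ω < 0.7 regime)
  and planted dS ∈ {0.08, 0.15, 0.25}. The codon simulator draws
  Poisson(dS·S) synonymous and Poisson(ω·dS·N) nonsynonymous events and
  applies them in random order, never creating stops — a
  mutation-acceptance scheme, not a full GY94 matrix, which suffices to
  generate controlled ω at this scale.
- **Architecture**: 3 tandem pairs (20-kb gap, same chromosome), 3
  segmental pairs (different chromosomes), 4 singletons, 150-kb spacing
  elsewhere so no unplanned tandem call or cluster can arise; one pair
  carries a planted intron gain.
- **Promoters**: 1-kb backgrounds are scrubbed of all catalog-element
  matches, then known element counts (0–2 each of MBS, ABRE, HSE,
  TGACG-motif, LTR) are planted at separated offsets and re-verified, so
  scan counts equal planted counts exactly.
- **Expression**: tier means 2/40/800 (≥10× separation; tier group
  sizes match the tertile rule so recovery can be exact), ±25% noise;
  stress responders follow a 1→8 fold ramp over 0–24 h against an exact
  0-h control.

What the generator does **not** emulate: UTRs and alternative isoforms,
indels in coding sequence, rate heterogeneity among sites, genome-scale
repeat structure, pre-split duplications (available behind a flag in the
family simulator's design but off by default), and read-level expression
noise. A green end-to-end test therefore establishes that the pipeline
recovers planted structure under its own assumptions — not that it would
reproduce every number from a real genome release.

## Numerical and engineering choices

Pairwise alignment, NJ agglomeration, GFF3/FASTA/Newick parsing and
hierarchical clustering are delegated to Biostrings, ape, rtracklayer
and stats respectively, behind the package's validated contracts; the
analysis substance (site/pathway counting, reconciliation, unit
decomposition, scanning semantics, the simulator) is implemented here
and cross-checked against independent brute-force oracles in the test
suite. Alignment traceback ties follow the engine's deterministic rule
rather than a bespoke diagonal-first rule; scores, matches and column
counts — the quantities downstream code consumes — are unaffected.
Reported E-values use fixed Karlin–Altschul constants, an approximation
adequate for thresholding at 10⁻¹⁰. RNG is R's default generator under
explicit integer seeds; emitted datasets are byte-identical across runs
at a fixed seed.

## Known limitations

- Segmental duplication is "not tandem", per the survey's operational
  rule; no synteny-block evidence is consulted.
- The species-overlap accounting is parsimony-style: it cannot see a
  duplication-then-double-loss that mimics a speciation, and adjacent
  single-species units in a poorly resolved tree can merge.
- The per-element counts of the promoter scan depend entirely on the
  consensus catalog supplied; the shipped catalog is a reasonable
  default, not a reproduction of any web server's pattern set.
- ML inference (trees and ω) is deliberately out of scope; estimates
  here are method-of-moments style and documented as such.
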