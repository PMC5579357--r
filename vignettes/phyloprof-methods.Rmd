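---
title: "Models and conventions behind phyloprof"
author: "phyloprof authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind phyloprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprof)
```

## The scientific problem

Multiprotein machines such as the kinetochore are conserved as functions but
surprisingly variable as parts lists: across a clade, individual subunits are
lost, duplicated or replaced while the machine keeps working. Two signals
make this variation interpretable. First, subunits that work as a unit tend
to be lost together, so their *phylogenetic profiles* — presence/absence
vectors over a fixed set of genomes — are correlated; profile similarity
therefore predicts functional association, and profile dissimilarity between
known interactors flags recent interactions or moonlighting partners.
Second, placing each gene's losses on the species tree with Dollo parsimony
summarizes how dispensable it has been since the clade's last common
ancestor. `phyloprof` implements both layers, adds a motif-level variant of
the co-occurrence analysis, and pairs everything with a generative simulator
so that the whole pipeline can be checked against known truth.

## Profiles

A profile is defined over an ordered `species_catalog()` of 4-letter codes
(first letter of the genus + first three letters of the species). Sequence
identifiers are the code plus six digits, and the species of each orthogroup
member is read off its identifier. Copy number is the number of members per
species; presence is its support, so a species counts as "has the gene"
whether single- or multi-copy. Codes are matched case-sensitively and
catalog collisions are rejected outright — two species collapsing to one
code would silently merge their profiles. Unknown codes abort by default; a
lenient mode skips them with a warning for exploratory use. The catalog
order should follow the species tree's tip order (see
`catalog_from_tree()`): profile transitions (adjacent state changes) are
only meaningful when neighbouring columns are related species.

## Co-evolution scoring

Profile similarity is the Pearson correlation *r* of the binary vectors,
which for two binary variables is exactly the phi coefficient of their 2×2
co-occurrence table. Pearson is undefined for a constant profile; we return
0 with a `constant` flag rather than `NA` so that the correlation matrix
stays complete for clustering while flagged rows are excluded from threshold
sweeps. The tests verify the phi identity against an independent
contingency-table computation and against `stats::cor()`.

The interaction threshold is calibrated by a sweep: candidate thresholds are
the distinct observed *r* values, selection is inclusive (`r >= t`), and
`enrichment(t)` is the precision of the selection on a reference list of
established interacting pairs divided by the reference's base rate among all
scored pairs. The reported threshold is the *smallest* candidate achieving
the requested fold (default 6), which keeps the selected set as large as the
enrichment rule allows; if no candidate achieves it, a sentinel (−1) is
returned rather than a fabricated cut-off. The whole sweep is part of the
result for audit. Sweeping observed values only (rather than a continuous
grid) loses nothing: enrichment is a step function with steps at observed
values.

Clustering follows the standard recipe for profiles: distances *d* = 1 − *r*
and average linkage via `stats::hclust`. Proteins are sorted
lexicographically before clustering so tie-breaking is deterministic across
platforms. Reference-family screening (`family_profiles()`,
`family_top_matches()`, `recurrent_families()`) ranks family profiles by *r*
against each query, with ties broken by family identifier; subfamily
assignments (ids of the form `FAM:SFn`) propagate to their parent family.

## Dollo parsimony

Under Dollo's assumption — one invention, no regain — the most parsimonious
history of a profile on a rooted tree is forced: the gain sits at the last
common ancestor of all presence leaves, and there is one loss per *maximal*
subtree below the gain containing no presence leaf. Losses are counted per
pruned branch, so a loss on a terminal branch and a loss removing a whole
clade each count once. Polytomies are handled as-is; no arbitrary
resolution is introduced. A gene is called ancestral ("in LECA" when the
tree spans the eukaryotes) exactly when its origin is the root of the
supplied tree; sensitivity to the root placement is deliberately left with
the user, since the tree is an explicit input to every tree-dependent
operation. Mean loss counts are averaged over ancestral proteins only —
loss counts of later inventions are not comparable.

Correctness is established two ways: a replay identity (gain at origin plus
losses reproduces the input bit-for-bit, asserted for every reconstruction
in the tests) and an independent brute-force oracle that enumerates every
gain placement on small trees and computes minimal loss sets recursively.
The two agree on all 15 presence patterns of a 4-leaf tree and on hundreds
of random instances.

## Motif analysis

The canonical Mad2-interacting motif is `[RK][ILV](2)X(3,7)P`; the relaxed
definition, `[ILV](2)X(3,7)P | [RK][ILV](2)`, additionally admits the
land-plant-style variant. Both residue-class spellings in circulation
(`[KR][IVL]` vs `[RK][ILV]`) denote the same sets and are treated as
identical. Patterns compile from this bracket notation; the bounded gap is
matched lazily (the shortest match per start position is reported) because
greediness is not part of the motif definition, and overlapping matches are
allowed. A wildcard position accepts any residue letter including the
ambiguity code `X`, but never a stop (`*`) or gap character; residue classes
accept their listed letters only, so an ambiguous `X` in the input never
satisfies `[RK]`.

Motif profiles are scored at a *conserved position*: the alignment columns
occupied by an anchor sequence's motif, widened by a slack of 5 columns per
side (a tolerance knob, since "similar position" has no canonical width),
are extracted per sequence, de-gapped and scanned. A species is scored
present if any of its orthologs has a hit in the window — profile semantics
are species-level — and a motif elsewhere in the protein does not count.
Truncated or gap-only sequences in the window simply score absent.

Motif/partner co-occurrence restricts the universe to species carrying the
motif's host protein (a species without the host cannot carry the motif, and
including it would inflate the association), cross-tabulates partner against
motif presence, and reports the one-sided hypergeometric tail
`P(X >= k)` — one-sided because the tested claim is over-representation —
next to the phi correlation of the restricted profiles. The tail is
computed with `stats::phyper` and verified in the tests against exhaustive
enumeration of all draws for every universe up to N = 12.

## Set statistics

Occurrence frequency is the presence mean; profile entropy is the binary
entropy of that mean in bits (maximal, 1 bit, at 50% occurrence; 0 at fixed
profiles). Set completeness is conditioned on anchor proteins: species
carrying all anchors (for a kinetochore-like machine, its chromatin- and
microtubule-binding ends) are assumed to have the machine, and completeness
is the fraction of set members present in such species. Because the
anchored and unconditional conventions give different headline numbers, both
are reported (`mean` and `mean_all_species`).

Loss-frequency comparison between two sets uses the two-sided Mann–Whitney
rank test, consistent with the nonparametric choice (Spearman) used for the
loss-versus-rate correlation. Loss counts are small integers, so ties are
the norm and the textbook exact distribution does not apply; for total
sample sizes up to 20 the p-value is computed by exact enumeration of all
rank assignments with midranks (two-sided p = twice the smaller tail, capped
at 1), and larger samples use the normal approximation. Evolutionary-rate
tables (dN/dS, percent identity for a stated species pair) are consumed as
input; deriving them is out of scope.

## The simulator

The generator is the generative counterpart of Dollo's assumptions: a gene
is invented once (by default at the root) and each lineage below loses it on
a branch with probability `loss_prob`, with no regain and no events below a
loss. Losses are drawn per branch, not per unit branch length, because the
species tree is used as a topology. The defaults — 90 species, 70 genes,
`loss_prob = 0.15`, `coupling = 0.9`, noise-free motifs, 200-residue
sequences — describe the study conditions the analyses target: about 90
diverse genomes, a 70-protein machine, and loss frequencies in the mid-teens
per gene, which the default per-branch rate reproduces on a 90-leaf topology.

Co-evolving pairs share their origin; each loss of gene A is copied to gene
B with probability `coupling`, and B draws residual independent losses at
rate `loss_prob × (1 − coupling)`, so B's marginal loss rate stays near A's
while coupling dials the co-occurrence of loss events. At coupling 1 the
profiles are identical; at coupling 0 they are independent — and under
independence the expected phi is exactly zero (conditional on the margins,
the expected determinant of the 2×2 table vanishes), so uncoupled pairs
scatter around *r* = 0 rather than sitting slightly above it.
Multifunctional triplets set an enzyme's presence to the union of its two
partners (the retention rule of a protein kept while at least one partner
needs it), optionally flipped per species by a noise rate.

Genes that go extinct in all leaves are resampled with an incremented seed —
observed orthogroups are conditioned on survival — with the resample count
recorded; a flag retains extinct genes for testing the all-absent error
paths, and certain extinction (`loss_prob = 1`) errors out after a bounded
number of retries.

Emitted fixture datasets are analysis-ready text: one FASTA per orthogroup,
the newick tree, a ground-truth table and a YAML configuration echo,
bit-reproducible from the seed. Emitted sequences are random draws from the
20 amino acids *minus K, R and P*: with the positive residue and the
terminal proline unavailable to the background, a planted `KILSTDP` instance
at a fixed offset is provably the only way any MIM branch can match, so
motif scans of fixtures reproduce the planted truth exactly, and the fixed
offset means the unaligned sequences can be scanned as an alignment.

## What the simulations do and do not show

The simulator emulates the *generative structure* the analyses assume:
single origins, branch-wise inherited loss, coupled losses, union-retention,
and motif presence tracking a partner. Passing its end-to-end checks shows
the pipeline's bookkeeping and statistics are correct under that model. It
does not emulate homology-detection failure (false absences concentrated in
fast-evolving lineages), annotation noise, gene duplication dynamics (copy
numbers in fixtures are 0/1), horizontal transfer, substitution-level
sequence evolution, or branch-length-dependent loss rates — so agreement on
fixtures does not certify conclusions drawn from real proteome scans, where
false negatives both inflate inferred losses and correlate them with
sequence divergence.

A structural limitation worth knowing: when an entire clade incident to the
true origin loses a gene, the origin is unidentifiable from the surviving
presences — Dollo necessarily infers the (more recent) ancestor of the
survivors. Under root origins and a per-branch loss rate of 0.1 on 10-leaf
trees this affects roughly a fifth of simulated genes (the probability that
exactly one of the two root clades drops out), which is the ceiling on
"origin recovery" any reconstruction method can reach under that model; the
inferred loss count, by contrast, is always a lower bound on the simulated
events, and that bound is asserted without exception in the tests.

## Numerical conventions and test scale

Degenerate inputs fail loudly: all-absent profiles (no origin definable),
empty universes, empty references, unrooted trees, catalog mismatches,
ragged alignments and malformed identifiers are errors with the offending
item named. Determinism is enforced throughout: every simulator function is
a pure function of (tree, config, seed) and restores the caller's RNG
state; clustering and ranking tie-breaks are lexicographic. Floating-point
identities (phi vs contingency table, hypergeometric vs enumeration) are
asserted to 1e−12.

The test suite sizes were chosen to exercise the asymptotics while keeping a
full run in seconds: exhaustive checks on 4-leaf trees and universes up to
N = 12, 200 random Dollo instances on 5–10-leaf trees, 1,000 random profile
pairs for the phi identity, 500 simulated genes for parameter recovery, and
200 replicate pairs per coupling level at 90 species for the discrimination
check.
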