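---
title: "Evaluating organellar super-barcodes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating organellar super-barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgbarcode)
```

`orgbarcode` evaluates whole organellar genomes as species-identification
markers. This vignette is the package's account of the underlying models,
the parameters that matter, the synthetic data used for validation, and
the places where the design was genuinely open.

## The homology scan

Plastid-to-mitochondrion transfers (MTPTs) and internal repeats are found
by a classic seed-and-extend local alignment. Every exact shared k-mer
(default `seed_len = 11`) seeds a diagonal; seed runs are extended
ungapped under an X-drop rule (`xdrop = 40`, i.e. extension stops once the
running score falls 40 below its maximum — about thirteen consecutive
mismatches under the default scheme); ungapped HSPs whose diagonals lie
within `chain_band = 64` of each other and whose query ranges fall within
`chain_gap = 200` bp are chained, because insertions and deletions shift
the alignment diagonal and would otherwise split one homologous segment
into several hits; each chain is refined by an affine-gap local DP
(Gotoh recursion, vectorized row-wise) on a window padded by `pad = 100`
bp. The scoring scheme is the blastn-like default: match +2, mismatch −3,
a gap of length *g* costs 5 + 2*g*. On fixtures up to 2 kb the best hit's
raw score equals the full Smith–Waterman optimum computed independently
by `Biostrings::pairwiseAlignment` — the test suite asserts this on
fixtures that contain indels, which exercises the chaining and the gapped
DP. One consequence of score-optimal semantics worth knowing: a hit may
extend a few bases past a verbatim transfer when the surrounding sequence
happens to align with net positive score, so recovered identity for a
verbatim insert is occasionally slightly under 100%.

Significance uses the Karlin–Altschul expectation
`E = K·m·n·exp(−λS)`. λ is solved numerically from the score-generating
equation at uniform base composition (the solved value, 0.634 for +2/−3,
matches the published ungapped tables); K is shipped as a small table of
ungapped values for common reward/penalty pairs (0.408 for +2/−3) and
must be supplied for other schemes — the ungapped pair is used as an
approximation for gapped scores, which only shifts the (configurable)
e-value cutoff. Scoring schemes with non-negative expected score per
aligned pair have no λ and are rejected as configuration errors.

Hits are kept at raw score ≥ 100 and e-value ≤ 10⁻⁵ by default. A raw
score of 100 needs ≥ 50 matched bases, and at the default genome sizes
the corresponding e-values are astronomically small for random sequence,
so the thresholds act as a minimum-transfer-length filter, which is how
they are used in practice. Hits under 80% identity are flagged
(`low_identity`) rather than dropped: cross-matches between analogous
ribosomal genes look like transfers at ~74% identity and are best judged
editorially, not algorithmically. Circular molecules are linearized by
doubling, and hits crossing the origin are reported split into two rows
sharing a hit id.

Duplicate transfers — the same plastid region inserted at several
mitogenome loci — are collapsed by `dedupe_hits()`: hits whose query *or*
subject intervals reciprocally overlap by ≥ `overlap_frac = 0.5` are
clustered transitively. The 0.5 default is a declared choice (no
published value exists for this step); it is insensitive in practice
because duplicate insertions share their source interval almost exactly.
A gene is a `complete` transfer iff its full annotated interval lies
inside one merged subject interval, otherwise a `fragment` — fragments
cannot be functional in the mitogenome, so the distinction matters for
interpreting transfer content.

## Fragment selection

Barcode candidates are the complement of the MTPT and repeat masks,
dropped below `min_len = 1000` bp, then filtered on *commonness*: a
fragment must be present in ≥ `min_presence_frac = 0.9` of the species.
Presence is a per-species criterion — a species counts as having a
fragment when at least one of its samples covers ≥ 50% of the columns
with non-gap characters — and deliberately soft: a marker set missing
from a couple of taxa is still usable, and the panel analysis simply
proceeds without those samples. Both thresholds are configurable.

## MDC calling and discrimination

An alignment column is a molecular diagnostic character (MDC) for a
query taxon iff every query sample carries the same unambiguous base and
no reference sample carries a state compatible with it;
query-polymorphic columns are excluded. The ambiguity policy is explicit
and pluggable because reference ambiguity codes admit two defensible
readings:

* `conservative` (default): any reference gap, `N`, or ambiguity code
  whose base set contains the query base disqualifies the column. This
  policy can only under-count.
* `strict_acgt`: non-ACGT reference characters are ignored; at least one
  unambiguous reference base is required.

Discrimination compares each species against the other species of its
genus (`scope = "genus"`), or against the whole panel. A species is
*identified* when it has ≥ 1 MDC summed over the fragments. Species that
are their genus's sole member have no congeneric reference set; they are
flagged not-evaluable and removed from the efficiency denominator, which
the report states explicitly (efficiency = 100 × identified / evaluable).
Subspecies merge into their species by default; `taxon_level =
"subspecies"` splits them, and `compare_taxa()` gives the asymmetric
pair counts used for subspecies-vs-subspecies questions.

## Diversity statistics

Gap handling is pairwise deletion throughout: every pair of sequences is
compared over the columns where both carry unambiguous bases. This keeps
per-window values defined in gappy alignments, where complete deletion
would discard whole windows. π is the mean over unordered pairs of
differences per compared site; on gap-free data this equals the mean
per-column pairwise heterozygosity (a test asserts the identity). The
standard tracks are π in 600 bp windows sliding by 100 bp, MDC counts in
non-overlapping 1000 bp windows (the trailing partial window is counted
and flagged so window counts conserve the total), and GC in 100 bp
tiles. Window positions are alignment-column native; mapping to genome
coordinates is the caller's concern because only the caller knows the
reference row. The divergent-block scan (for hypervariable segments
private to one sample) merges sliding windows of width `min_run` whose
divergence from the column majority exceeds `min_frac`; majority ties
break alphabetically, which makes the scan deterministic.

## Codon usage

RSCU uses the standard genetic code (plant organelles translate with
it); the codon→family map is configurable. The six-fold Leu/Ser/Arg
families are single r = 6 families by default — the common RSCU
convention — with `split_sixfold` available. ATG and TGG (r = 1) carry
no within-family contrast and are excluded from the rank tests.
Within-amino-acid differences use Kruskal–Wallis across the family's
codons with species as replicates (mid-ranks, tie correction; the
degenerate all-equal case returns p = 1), followed by Dunn's post hoc z
from pooled mid-ranks, Bonferroni-corrected over the family's
`choose(r, 2)` comparisons. The organelle contrast tests each codon
MT-vs-PT and corrects over all tested codons — a two-level correction
structure: within-family tests correct within the family, the
genome-wide contrast corrects genome-wide.

MILC for a gene is `Σ_a M_a / L − C` with
`M_a = 2 Σ_c o_c ln(f_c/g_c)` over each synonymous family and
`C = Σ_a (r_a − 1)/L − 0.5`, so a gene matching the expected usage
exactly has zero information term and the statistic approaches its ~0.5
floor as genes grow — the suite checks both the closed-form boundary
case and the monotone length trend by simulation. Genes under 80 sense
codons are excluded by default (short genes make the G-statistic
unstable), matching the hard filter used with this statistic in
practice. The default expected model is the pooled usage of the input
set; any expected frequency of zero with positive observed count is a
model misspecification and raises an error rather than returning ±Inf.

## Tree comparison

Trees are compared unrooted. RF distance counts symmetric differences of
nontrivial bipartitions, normalized by 2(n−3); the implementation
enumerates bipartitions via `ape::prop.part` and is cross-checked in the
suite against `phangorn::RF.dist`. NJ delegates to `ape::nj`; negative
branch lengths are clamped to zero with the deficit moved to the sister
edge so path lengths are preserved, and additive matrices are recovered
exactly (tested to n = 12). The tanglegram minimizes line crossings by
greedy child-order reversal at internal nodes of both trees, sweeping
until no flip helps; it is deterministic given input order, monotone
(never worse than the initial layout), and solves mirrored caterpillars
to zero crossings, but it only reverses child orders, so a
multifurcating node whose optimal child order is a non-reversal
permutation can retain crossings — a known limitation. Polytomy counts
use the unrooted convention (a trifurcating stored root is not a
polytomy); an `outgroup` argument reroots before summarizing.

## The synthetic generators

The generators define the validation conditions; their defaults are
fixed once and the acceptance tests run under them.

**Panel.** 33 species in six genera (18 + 5 × 3), two samples per
species, 29 fragments of 1000–3000 bp — a desk-scale rendering of a
multi-genus grass panel. Haplotypes evolve along a simulated ultrametric
tree under Jukes–Cantor; the clean default is `subst_rate = 0` so that
ground truth stays exact. Diagnostic sites are then *planted* at columns
invariant across the panel (fixed within the species, absent everywhere
else by construction) rather than left to mutation — this removes
homoplasy from recovery tests entirely. Twenty-five species receive ≥ 1
planted site; one hybrid's samples are overwritten with its parental
donor's haplotype (so hybrid and donor are mutually indistinguishable
and both unidentifiable, as real hybrid/parent pairs are), and one
fragment is absent from two species. Planting avoids fragments carrying
fewer than three members of the species' genus: with exactly two, a site
fixed in one would be reciprocally diagnostic for the lone congener and
truth would no longer equal the planted table. The default panel
therefore yields exactly 25/33 = 75.76% discrimination, and per-species
MDC counts equal the planted counts exactly. What passing these tests
shows is that the calling machinery is exact under clean conditions; it
does *not* show robustness to homoplasy, alignment error, or
intra-species polymorphism — those enter only when `subst_rate` /
`polymorphism_rate` are raised, where exact equality is no longer the
right assertion.

**Organelles.** An 80 kb mitogenome and 40 kb plastome at GC 0.44
(desk-scale; real grass organelles are ~5× larger, and the scan scales
linearly in seed hits), with 30 planted transfers of 200–1500 bp of
which 10 duplicate an already-used source region, 1% insert divergence,
two exact 1.2 kb repeats, five genes fully inside transfers and four
straddling transfer boundaries. The scan recovers 30 hits, duplicate
collapse yields 20 unique region pairs, and gene classification reports
exactly 5 complete transfers — all checked against the emitted truth
tables across seeds. Planted intervals are drawn with rejection and a
30 bp spacing; impossible configurations error rather than silently
overlap.

**Trees and CDS.** The tree generator is a forward birth–death
simulation conditioned on reaching n extant tips (extinct lineages
pruned); for a pure-birth tree the expected crown height is
`(1/b)(Σ_{k=2}^{n−1} 1/k + 1/n)`, which the suite checks against 300
replicates. CDS sets draw codons i.i.d. from a bias profile between a
start and a stop codon, so pooled counts recover the profile by the law
of large numbers.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
inclusive) and BED convert at the boundary, and features spanning a
circular origin are stored split into two intervals sharing a name.
Ambiguity codes are kept as-is in memory; each consumer's policy decides
their meaning. Pairs with zero compared columns are excluded from
identity means with a warning, error in p-distance matrices (a tree
cannot be built), and yield `NA` windows in π tracks. Majority ties,
co-optimal DP cells and equal-score hits all break deterministically
(alphabetical / first-index / genome order), so every output is
reproducible byte-for-byte under a fixed seed.

## Problem sizes used in validation

The suite runs 200 random panels against a brute-force MDC oracle,
eight 3 kb random pairs against a full Smith–Waterman oracle for the
no-hit case, the full 33-species panel and the 80 kb organelle pair end
to end, 2000 null replicates for the Kruskal–Wallis type-I rate
(nominal 0.05; observed ~0.044 — the rank test is mildly conservative
at 10 replicates per codon), and 300 tree-height replicates. The whole
suite completes in under two minutes on one core; `scripts/acceptance.R`
in about twenty seconds.

## Known limitations

The scan's Karlin–Altschul K for gapped scores is an ungapped
approximation; e-values are therefore indicative near the cutoff. The
tanglegram heuristic is a local optimizer. The generators do not
simulate recombination, structural rearrangement, sequencing error or
alignment uncertainty — inputs are assumed correctly assembled and
aligned, and alignment construction itself is out of scope (alignments
are consumed as given). Maximum-likelihood tree inference is likewise
out of scope; the tree module consumes externally inferred Newick trees.
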