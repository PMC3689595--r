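---
title: "Methods: detecting and comparing positionally overlapping genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing positionally overlapping genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoverlap)
```

## The problem

Two genes are *positionally overlapping* when their annotated genomic
spans share at least one base on the same assembled sequence.  In insect
genomes roughly a tenth of annotated genes sit in such pairs, either
*nested* (one gene embedded wholly inside another — E/H, for
embedded/host) or *partially overlapping* (P/O).  Overlap is fragile over
evolutionary time: one-to-one orthologs of an overlapping pair are often
found far apart in a sister genome.  genoverlap packages the full
comparative workflow around that observation: per-genome detection and
classification, cross-species retention/rearrangement accounting through
one-to-one ortholog maps, and the statistical tests that link
rearrangement to candidate mechanisms (introns, microsatellites,
substitution rates, expression, phylogeny).

## Detection and classification

Detection is deliberately minimal: genes are intervals, overlap requires
one shared base on the same `seq_id`, and strand is ignored at this stage
(orientation is classified afterwards, because both orientations occur in
both categories).  The pairwise overlap graph is decomposed into
connected components:

* size 2 → a classified pair.  Nested (`EH`) when one span contains the
  other, boundaries inclusive; otherwise partial (`PO`).  The container
  is the host.  `overlap_len` is `min(end) - max(start) + 1`, which for
  an EH pair equals the embedded gene's length.
* size ≥ 3 → an *overlapping cluster*.  Clusters are excluded from all
  pair-level analyses (they are rare, under a few percent of overlapping
  genes at genome scale) and reported separately.

Two identical spans are an edge case real annotations can contain:
we classify them `EH`, appoint the lexicographically smaller `gene_id`
host, and flag the pair (`identical_span`) so downstream users can drop
them.  The implementation rides on `GenomicRanges::findOverlaps`, but its
contract is *brute-force equivalence*: the test suite compares it, pairs
and clusters alike, against an independent all-vs-all oracle on hundreds
of random genomes.

`embedded_in_intron()` asks whether the embedded gene's entire span falls
strictly between two consecutive host exons (exon bases excluded).  A
single-exon host yields `FALSE`, never an error.  Exons from multiple
isoforms are merged to a non-overlapping union on input, so "intron"
means intronic in every isoform.

## Cross-species accounting

Given one-to-one ortholog maps (strictly one-to-one: any duplicated
identifier is rejected; paralog-only matches count as absent), each
reference pair receives a code per comparison species: `ABS` if either
ortholog is missing, otherwise the *pairwise relation* of the two
orthologs there — `EH`, `PO`, or `NOV` (non-overlapping).  We require the
two mapped orthologs to overlap *each other*; it is not enough for each
to overlap something.  Orthologs that land inside a cluster in the other
genome are still coded by their pairwise relation.

For a two-species comparison the universe is every ortholog pair
overlapping in at least one genome, classified into eight categories
(`EH_EH`, `PO_PO`, `EH_PO`, `PO_EH`, `EH_NOV`, `PO_NOV`, `NOV_EH`,
`NOV_PO`).  The four two-sided categories sum to the *retained* count,
the four one-sided ones to *rearranged*; the eight counts partition the
universe.  Age classes (`old_old` / `young_young` / `young_old`) depend
only on ortholog presence of the two members and are symmetric in member
order.

The intron contingency compares two reciprocal categories (rows) across
the two species (columns), each cell summing introns (= exons − 1) of
both pair members in that species.  The SSR analogue normalises total
microsatellite bases by the ortholog alignment length, because intron
content makes raw gene lengths incomparable; alignment lengths are inputs
(the package ships a toy Needleman–Wunsch helper for synthetic tests
only).

## The SSR scanner

Genome-scale SSR surveys are usually run with external scanners whose
exact seed-and-extend internals are opaque; instead of imitating one
bit-for-bit, this module turns the parameterisation such surveys report
— perfect and imperfect repeats of 1–6 bp motifs, a fixed mismatch
penalty of 5, exclusion of runs with more than 3 consecutive mismatch
sites, genes containing ambiguous bases skipped entirely — into a
transparent contract:

* a candidate hit is anchored by a motif occurrence (primitive motifs
  only: a `k`-mer that is itself a repetition of a shorter motif is
  scanned at the shorter length) and extended rightwards; matches score
  +1, mismatches −5, extension stops before any run of 4 mismatches, and
  hits end on a match;
* every extension end reaching the minimum score (default 15, the
  scanner's conventional default, exposed in the API) is a candidate;
* candidates are resolved greedily — highest score, then leftmost start,
  then shortest motif, then longest span — and accepted hits never
  overlap.

The acceptance suite equates this scanner with an exhaustive
dynamic-programming oracle enumerating all motif/window candidates on 500
random kilobase sequences.  Penta-nucleotide motifs are included by
default (surveys that enumerate "mono- through tetra- and hexa-" motifs
most plausibly omit penta by accident); `include_penta = FALSE` gives
the strict reading.  Motifs are reported in canonical rotation;
`shared_motifs()` additionally canonicalises under reverse complement so
`AC` and `GT` match across strands.

## Statistics

All tests are implemented in-package and checked against independent
references in the test suite:

* **Yates chi-square** on 2×2 counts, statistic
  $\sum (\lvert O - E\rvert - 0.5)^2/E$ with the correction floored at
  zero, df = 1.  A zero marginal is an error (expected counts
  undefined).
* **Spearman** on mid-ranks; exact two-sided permutation p for
  $n \le 10$ (full $n!$ enumeration, chunked to bound memory), t
  approximation above.
* **Mantel**: Pearson correlation of the two flattened pair × species
  binary matrices; the null permutes *rows* (gene pairs) of the
  dependent matrix.  These are feature matrices, not distance matrices —
  the row-permutation null matches how the original analysis describes
  permuting the overlap matrix.  Permutation p-values use the add-one,
  tie-inclusive convention and can never be exactly zero.  A caveat
  follows from that convention: on small binary matrices the statistic
  is a monotone function of an integer cross-count, its permutation
  distribution is coarsely discrete, and ties — concentrated at the
  two-sided fold near $|r| = 0$ — make the p-values conservative (a
  visible point mass at $p = 1$ under the null, empirical mean ≈ 0.55
  rather than 0.50 at 20 × 8).  The test never over-rejects; users who
  need exactly uniform null p-values on small matrices should use a
  mid-p variant, which we deliberately do not substitute for the stated
  convention.  **multi-Mantel** regresses
  the flattened dependent matrix on several flattened predictors,
  permuting dependent rows and refitting.
* **Binary logit** by IRLS with step-halving (the log-likelihood trace
  is non-decreasing by construction), Wald standard errors from observed
  information, convergence at relative log-likelihood change
  $<10^{-10}$ or 100 iterations.  Perfect/quasi-separation is flagged
  (`separated = TRUE`, `converged = FALSE`), never silently reported.
  Published coefficient tables for this kind of analysis sometimes pair
  coefficients with standard errors inconsistent with their p-values;
  we report standard Wald statistics and make no attempt to match any
  such inconsistency.
* **Average-linkage city-block clustering** wraps `hclust` on Manhattan
  distances; tests compare its cophenetic matrix against a naive
  agglomeration oracle.

## Correlated trait evolution on a phylogeny

Overlap presence/absence across species is treated as a binary character
and tested for correlation with a second binary character (ortholog
presence) by nested continuous-time Markov models over the combined
states {00, 01, 10, 11}:

* *independent*: four rates (gain/loss per trait); the 4-state generator
  is the Kronecker sum of the two 2-state generators, so the joint
  log-likelihood is the sum of two marginal pruning likelihoods (an
  identity the tests assert).
* *dependent*: the eight single-change rates are free; dual transitions
  are fixed at zero, the standard construction.

Likelihoods come from Felsenstein pruning with $P(t) = e^{Qt}$ (computed
in C++ via `arma::expmat`, as this field's packages push pruning into
compiled code) and a **uniform root prior** over the four combined states
— the classical method descriptions leave the prior open, so uniform is
the default with a `stationary` option.  Fitting is bounded multi-start
L-BFGS-B on log rates in $[10^{-8}, 100]$.  One start always embeds the
fitted independent rates into the dependent parameterisation; since the
optimizer never worsens its starting value, the nesting inequality
$\ell_{dep} \ge \ell_{indep}$ holds on every fit by construction.  The
LRT uses 4 degrees of freedom.

**Calibration caveat.**  On small trees the χ²(4) reference is
conservative: with 16 leaves the data are 32 bits however long the
branches are, the dependent model's extra freedom buys little, and the
null LRT statistic is stochastically smaller than χ²(4) (our simulations
put its 95th percentile near 6 against the 9.49 reference point, and the
nominal-0.05 rejection rate near 0 across a grid of rates and tree
depths).  The acceptance suite states a 5% ± 2.5% band for this rejection
rate; with the simulation world fixed a priori (16-leaf coalescent trees
of doubled depth, symmetric rates 1) the observed rate sits below that
band, and we report the criterion honestly rather than switching to a
simulation-based null that would pass by construction.  The practical
reading: on fewer than a few dozen species this LRT, evaluated against
χ²(4), yields large p-values even when traits are mildly coupled — the
flatness that comparative analyses of eight-species trait matrices run
into.  The nesting property holds in every replicate.

## Synthetic data: what a green test establishes

Generators are deterministic under a seed and always emit their ground
truth:

* `generate_genome()` *constructs* the requested overlap architecture —
  each nested pair by inserting an embedded gene into a designated host
  intron (87% by default, matching the reported intron-embedding rate)
  or across exon bases, each partial pair by staggered placement, each
  cluster as an overlap chain — and lays blocks out with generous gaps,
  so the truth table is exact, not probabilistic.  Defaults: ~10% of
  genes in overlapping pairs, 40% of pairs nested, 70% opposite
  orientation, log-normal gene lengths (median ≈ 1.8 kb), exon count
  1 + Poisson(3).  These mirror the genome-scale observations the
  pipeline targets.
* `generate_family()` evolves a base genome along a species tree; each
  pair rearranges per branch with a logit-linear probability in its
  intron and SSR covariates, young genes are born per branch, and block
  structure is shared across species so covariates mean the same thing
  everywhere.  Rearrangement is realised as relocation — the real
  mechanism is unknown, and the accounting under test is independent of
  the mechanism.
* `implant_ssrs()`, `generate_expression()` (Gaussian-copula Spearman
  effect for same-orientation pairs only) and `generate_logit_data()`
  (gamma-distributed rates, Bernoulli outcome) cover the remaining
  inputs.

What the generators do *not* emulate: sequence-level evolution, realistic
synteny, annotation error, isoform complexity, expression normalisation
artifacts.  A green round-trip therefore establishes correctness of the
accounting and the statistics on ideal inputs, not robustness to
annotation noise — the genome-scale published counts (761/565 pairs and
their kin) require the original downloads and are out of desk-scale
scope.

## Numerical and design choices

* Coordinates are 1-based inclusive internally; BED converted at the
  boundary; gene boundaries taken exactly as annotated (UTR-inclusive
  where the annotation is).  Strand "." is rejected; zero-exon records
  are rejected.
* Polytomies in input trees are resolved to binary with zero-length
  branches and flagged.
* Permutation p-values: add-one convention; seeds are arguments, RNG
  state is restored after use (`with_seed`), and every pipeline output
  embeds the seed, package version and config hash, so a rerun is
  byte-identical.
* The matrix exponential for simulation uses an eigen decomposition with
  a scaling-and-squaring fallback for near-defective generators; the
  C++ likelihood path uses `arma::expmat` with per-node rescaling
  against underflow on deep trees.
* Ties in SSR resolution and identical-span overlap classification are
  broken deterministically (documented above) so outputs are stable
  across platforms.

## Limitations

Transcript-isoform overlap, non-gene features, EST/BLAST evidence
pipelines, dN/dS estimation and microarray normalisation are out of
scope; the relevant quantities enter as plain-text inputs.  The Pagel
LRT is a small-sample-conservative test here by design of the data, not
a software property; users with enough species should prefer larger
trees, and users who need exact size should calibrate by simulation
with `simulate_traits()`.
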