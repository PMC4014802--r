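---
title: "The splicing-code model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The splicing-code model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science the package implements, the modelling
assumptions behind it, the parameters that matter and the choices made
where the design was genuinely open.  It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

A cassette exon sits between two constitutively spliced neighbours and is
either included in the mature transcript or skipped.  Whether it is
included — and whether inclusion shifts between tissues — is encoded
largely in *cis*: splice-site strength, exonic and intronic binding motifs
for SR, hnRNP and tissue-restricted factors (Fox-1/2, Nova, Ptb, Quaking,
Mbnl, Cugbp), the pyrimidine tract and AG-exclusion zone, and chromatin
features such as nucleosome positioning.  A *splicing code* is a predictive
map from these sequence-derived features to splicing outcomes across
cellular contexts.  The package predicts, for an exon triplet, the
probability that the middle exon is alternative and, conditionally, the
probability of increased inclusion, increased exclusion or no change in
each of four tissue groups (CNS, muscle, digestive, embryo).

## Regions and features

Features live in seven regions: the flanking exons `C1`/`C2`, the
alternative exon `A`, and two windows per intron (`I1a` donor-proximal,
`I1b` acceptor-proximal upstream; `I2a`/`I2b` downstream).

* **Intronic window width.** The upstream literature of this model family
  does not restate the widths; 300 nt per window is the convention of the
  splicing-code lineage and is exposed as `intronWindow=`.  Short introns
  split at the midpoint — donor side takes the floor — so the two windows
  never overlap.
* **Motif counts.** IUPAC patterns are scanned with all (possibly
  overlapping) start positions counted; `N` in the genome matches nothing.
  Overlap counting keeps the statistic deterministic and checkable against
  a brute-force oracle.  Each motif is counted only in its annotated
  regions.
* **Splice-site strength.** Log-odds in bits against a uniform background,
  `sum log2(p/0.25)`, with columns smoothed as `(p + 1e-3)/(1 + 4e-3)` so
  a zero-probability base costs about 8 bits rather than minus infinity.
  Donor PWMs are 9 nt (−3..+6 across the exon/intron boundary), acceptor
  PWMs 23 nt (−20..+3).  Because no external PWMs are assumed, defaults are
  estimated from the constitutive junctions of the triplet database itself
  (+1 pseudocount).
* **First upstream AG.** Distance from the 3'-splice-site AG to the next
  upstream AG, a proxy for the AG-exclusion zone; censored at window
  length − 1 when absent.
* **Lengths.** `log10` of exon and intron lengths — raw lengths are
  heavy-tailed and destabilise network training.
* **Nucleosome/accessibility summaries.** Mean and max of a user-supplied
  per-base track over the exon-proximal first 100 nt of each intron, the
  first/last 50 nt of `A`, and the full intronic window pairs (12 values).
  "First 100 nt of the intron" is read as *exon-proximal*; the
  transcription-start reading is the other defensible choice and is noted
  here because the sources are ambiguous.  Secondary-structure
  accessibility is accepted only as a precomputed track with the same
  summarisation, since no method for computing it is fixed by the model.

The default model schema (used by `prepareFeatures()`) is motif counts +
splice sites + lengths + AG distance (~28 features with the shipped motif
library).  Composition (mono/di/tri frequencies per region, 420 features)
and track summaries are available via `families=`; they multiply the input
dimension twentyfold and mostly add noise at the simulation sizes used
here, so they are opt-in rather than default.

## The two-stage Bayesian ensemble

Both stages are small feed-forward networks — tanh hidden layer, sigmoid
output for stage 1, a 3-way softmax per tissue group for stage 2 — with a
spike-and-slab prior on each feature-to-hidden connection.  "Sparsity prior
0.9" is interpreted as the *exclusion* (spike) probability; the
complementary reading would contradict sparsity.  Slab and all other
weights are standard normal.  Stage 2 trains against *soft labels*
`(q_inc, q_exc, q_nc)` by per-group categorical cross-entropy, so
uncertain training estimates propagate instead of being thresholded.

Sampling is adaptive random-walk Metropolis-within-Gibbs: per-hidden-unit
proposals on active weights, a joint output-layer proposal, and
birth/death flips of connection indicators using the slab prior as the
proposal (so the acceptance ratio reduces to likelihood times prior odds).
Step sizes adapt towards ~30% acceptance during burn-in only, keeping the
post-burn-in chain a valid fixed-kernel sampler.  The exact kernel of the
original Bayesian neural-network work is not published in reusable form;
any correct sampler targeting the same posterior is admissible, and this
one is chosen for simplicity and bit-reproducibility under a seed.

Inputs are standardised to zero mean/unit variance with statistics stored
in the model — necessary for sane proposal scales, and the reason
"removing" a feature is defined on the raw scale (below).  Desk-scale
defaults are 500 retained samples (burn-in 2000, thin 5); the full-size
published ensembles used 5,000 samples, reachable via `nSamples`.  The
tissue stage is one network with 4×3 outputs rather than four separate
networks; sharing the hidden layer lets tissue groups borrow strength and
halves the parameter count, and the alternative is a config away
(`tissueGroups=` with a single group, trained per group).

Prediction is the posterior mean of per-sample outputs; stage-2 rows are
renormalised to machine precision.  The chain rule
`pChange_t = pAS * (1 - q_nc_t)` combines the stages; the single-stage
baseline `max_t (1 - q_nc_t)` is implemented for comparison.

## In-silico feature removal

`FE_f` recomputes the stage-2 conditional probabilities with feature `f`
set to **raw zero** (a zero motif count is the biologically meaningful
"removed" state; standardised zero would mean "average occurrence").  The
effect is measured on the conditional `(q_inc, q_exc)` rather than the
combined `pChange`, matching the formula's intent of capturing shifts in
the inc/exc balance as well as in overall change confidence; stage-1
effects can be reported separately.  NFE normalises FE over the robust set
`J` (features with posterior inclusion frequency ≥ 0.5).  NFE is reported
per tissue group (pooling is an option), and it deliberately carries no
significance measure — it ranks, it does not test.  When every FE is zero
the report is flagged degenerate instead of dividing by zero.

Enrichment percentiles use the mid-rank rule
`100·(#below + 0.5·#ties)/n` — symmetric and standard where the sources do
not fix tie handling — with two-sided 5/95 display cutoffs.

## Query matching

Queries are matched to the triplet database before any genome search:
coordinate queries by interval lookup (≥90% reciprocal overlap counts as
the same exon — partial-overlap behaviour is otherwise unspecified),
sequence queries by seed-and-extend with 8-mer seeds, at least two seeds
per exon, and global-alignment identity ≥ 0.88 — the thresholds of the
external aligner configuration this pipeline historically used, with the
external binary replaced by an internal matcher.  Ties break by identity
then lexicographic id, for reproducibility.  A genome fallback runs only
when coordinates for all three exons are supplied.

## Evaluation machinery

* **AUC** is the Mann-Whitney statistic (ties 0.5), verified against
  exhaustive pair enumeration.
* **Non-redundant folds**: triplets sharing a gene or with middle-exon
  identity ≥ 0.88 (the matcher threshold — one knob, reused) are forced
  into the same fold; clusters are assigned greedily to the smallest fold
  in seeded random order.
* **Negative-set cascade**: drop triplets with missing expression; flanks
  within 1.5-fold in every experiment; both flanks with |value| ≥ 0.1 in
  ≥ 15 experiments; both flanks above the per-experiment bottom 20th
  percentile in ≥ 3 experiments of the target group; change P-value
  ≥ 0.7.  Expression values are treated as log2-scale, so "1.5-fold" is
  `|Δ| ≤ log2(1.5)`; the bottom percentile is computed per experiment
  across all exon rows in the table, the only self-contained reading.
  The change P-value supplier is a rank-based stand-in (Wilcoxon rank-sum
  of middle-vs-flank relative inclusion, target group vs the rest) and is
  swappable.  Survivors are sampled gene-first, then by position.
* **Bias correction**: expression-filtered negative sets are biased toward
  constitutive-looking exons, so candidates are importance-resampled
  without replacement with weights ∝ reference/candidate histogram density
  on a shared binning, and the report carries Kolmogorov–Smirnov distances
  to the reference CDF before and after.  Any mechanism that reduces the
  KS distance would do; histogram importance resampling is the simplest.
* **Repeated CV**: the number of repeats is not fixed by the sources;
  the default is 3, configurable.

## The synthetic study

The generator defines the conditions under which the package's claims are
tested: 500 cassette and 500 constitutive triplets (~1,000 triplets, ~2.4
Mb of genome on both strands), 60 tissue-dependent exons per group split
evenly between increased inclusion and exclusion, log-normal exon
(~130 nt) and intron (~800 nt) lengths with canonical GT…AG intron ends, a
45% GC background, and an 11-tissue × 3-replicate expression panel with a
1 log2-unit tissue shift, 0.25 replicate noise and 2% missing cells —
values a mouse exon-array compendium would find unremarkable.  Cassette
exons receive enhancer/silencer-like hexamers; each tissue group plants
one group-specific motif (e.g. TGCATG/Fox-1/2 for CNS) with probability
`2·(plogis(effect) − 0.5)` per copy slot, so a zero effect is a true null.
Planted copies never overlap, making every recorded occurrence
re-discoverable by the scanner — a cross-module oracle.

Planted effects act on sequence only, so the sequence model must beat an
expression-only classifier by construction: the comparison has a known
winner, which is what makes it a test rather than an observation.  What
the simulation does *not* emulate — array probe noise structure, paralogy,
conservation, realistic splice-site evolution, correlated motif
co-occurrence — bounds what passing tests show about real data: they
verify the machinery (feature extraction, inference, attribution,
evaluation logic), not mouse-genome accuracy, whose published headline
figures require the original exon databases and array tracks.

## Problem sizes and numerics

The test suite and acceptance script run the full benchmark at 1,000
triplets with 200-sample ensembles (burn-in 1,000, thin 5) and the
two-stage/single-stage comparison over ten 240-triplet studies with
40-sample ensembles — sizes chosen so the whole suite completes on a
single CPU in well under half an hour while leaving the recovery margins
wide.  Numerical guards: probabilities clamped to `[1e-12, 1 - 1e-12]`
inside likelihoods; softmax computed with max-subtraction; constant
features get unit scale instead of zero; acceptance rates outside
`[0.05, 0.95]` set a metadata warning rather than failing; empty robust
sets and all-zero FE are explicit degenerate cases.

## Known limitations

Absolute inclusion levels (Ψ) are out of scope — the model scores
*relative, tissue-dependent* change only.  Non-cassette event types and
minor-spliceosome introns are unsupported.  Conservation features are
absent (they would require genome-alignment downloads).  The motif library
shipped is a compact stand-in for the full several-hundred-motif
compendium; the schema is extensible through the same TSV format.
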