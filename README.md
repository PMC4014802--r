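# splicecode

Sequence-based prediction and regulatory analysis of alternative splicing
for cassette exons.

Most mammalian multi-exon genes produce alternative transcripts, and the
commonest event is the cassette exon: an internal exon either included or
skipped between two constitutive neighbours, often in a tissue-dependent
way.  `splicecode` implements a *splicing code* engine: given an exon
triplet (the exon of interest plus its immediate upstream and downstream
exons) and the surrounding genomic sequence, it predicts

1. whether the middle exon is an alternative cassette exon, and
2. whether its inclusion increases or decreases in four tissue groups
   (CNS, muscle, digestive, embryo),

and then asks *why*, by measuring the effect of removing each regulatory
element in silico.

## The model

A feature vector `r_e` is extracted from seven regions around the exon
(the flanking exons C1/C2, the alternative exon A, and exon-proximal
windows I1a/I1b and I2a/I2b of the two introns): IUPAC motif occurrence
counts for RNA-binding-protein motifs, donor/acceptor splice-site strengths
(PWM log-odds), log10 lengths, the first-upstream-AG distance, nucleotide
composition, and windowed nucleosome-occupancy summaries.

Two classifiers are ensembles of sparse feed-forward Bayesian neural
networks sampled by MCMC (spike-and-slab priors on the feature-to-hidden
connections; 10 hidden units / sparsity 0.9 for stage 1, 20 units / 0.95
for the tissue stage).  Predictions combine by the chain rule

    P(O_t = change | r_e)  =  P(AS | r_e) * P(O_t = change | r_e, AS)

with the second factor given per tissue group as probabilities of increased
inclusion, increased exclusion, or no change `(q_inc, q_exc, q_nc)`.

For regulatory analysis, each feature `f` in the robust set `J` (features
retained across the posterior ensemble) is zeroed and the predictions
recomputed; the feature effect and its normalization are

    FE_f  = |q_inc - q_inc^(Δf)| + |q_exc - q_exc^(Δf)|
    NFE_f = FE_f / Σ_{j∈J} FE_j .

The package also ships the evaluation machinery around the model: query
matching against a triplet database by seed-and-extend alignment (8-mer
seeds, ≥2 seeds per exon, identity ≥ 0.88), gene-aware non-redundant
cross-validation folds, an expression-filter cascade that builds
non-tissue-dependent negative sets, distribution-matched subsampling that
removes the constitutive-exon bias of that selection, and a synthetic
generator that plants known motifs and tissue effects so that every claim
is testable end to end without external data.

## Worked example

```r
library(splicecode)

cfg <- simConfig(nCassette = 150, nConst = 150,
                 nTissueDep = c(CNS = 20, muscle = 20, digestive = 20, embryo = 20),
                 seed = 7)
sim  <- generateTripletDB(cfg)            # toy genome + labelled triplets
lib  <- defaultMotifLibrary()
prep <- prepareFeatures(sim$db, sim$genome, lib)

tt <- sim$truth$triplets
y  <- setNames(as.integer(tt$label == "cassette"), tt$triplet_id)
m1 <- sampleEnsemble(prep$X, y[rownames(prep$X)],
                     netConfig("as_vs_const", nSamples = 100, burnIn = 600,
                               thin = 2, seed = 1),
                     schema = prep$schema)
m2 <- sampleEnsemble(prep$X[names(y)[y == 1], ],
                     truthSoftLabels(sim$truth)[names(y)[y == 1], ],
                     netConfig("tissue", nSamples = 100, burnIn = 600,
                               thin = 2, seed = 2),
                     schema = prep$schema)

pred <- predictSplicing(m1, m2, prep$X["t0012", ])
pred
#> SplicingPrediction: p(AS) = 0.999
#>             inc   exc    nc pChange
#> CNS       0.357 0.385 0.258   0.741
#> muscle    0.030 0.059 0.910   0.090
#> digestive 0.037 0.075 0.888   0.112
#> embryo    0.064 0.032 0.905   0.095
```

Here `t0012` is a simulated CNS-dependent cassette exon: the model is
confident it is alternative (`p(AS) = 0.999`) and that its inclusion
changes in CNS (`pChange = 0.74`) but not in the other groups (~0.1),
while remaining inconclusive about the *direction* of the CNS change
(`q_inc = 0.36` vs `q_exc = 0.39`) — confident change with uncertain
direction is a common and biologically plausible outcome.

In-silico removal then attributes the prediction to regulatory elements:

```r
nfe <- normalizedFeatureEffects(m2, prep$X["t0012", ], "CNS", motifLib = lib)
head(nfe, 3)
#>          feature region     rbp tissue     FE    NFE
#> 1  motif_fox_I2a    I2a Fox-1/2    CNS 0.6254 0.8819
#> 2 motif_mbnl_I2b    I2b Mbnl1/2    CNS 0.0291 0.0410
#> 3  ss_acceptor_A      A    <NA>    CNS 0.0247 0.0349
writeBed(motifHitsToBed(sim$db[["t0012"]], lib, sim$genome, nfe = nfe),
         "t0012_motifs.bed")
```

The planted Fox-1/2 (TGCATG) site downstream of the exon dominates the
normalized feature effect, and the BED track places every motif occurrence
back on genomic coordinates for a genome browser.

A thin command-line wrapper over the same functions is installed at
`inst/cli/splicecode.R` (subcommands `simulate`, `extract`, `train`,
`predict`, `match`, `analyze`, `eval`).

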