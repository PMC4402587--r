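---
title: "Binning metagenomic reads with topic models and feature-weighted clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning metagenomic reads with topic models and feature-weighted clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicbin)
```

## The problem

A shotgun metagenome mixes reads from every organism in a sample, and for
most environmental samples the source genomes are unknown. *Binning* groups
reads so that each group collects sequences from one species or taxon,
without reference genomes or training data. The signal this package exploits
is purely compositional: genomes differ in their tetranucleotide usage, and
even a 1 kbp fragment carries a measurable imprint of its genome's 4-mer
profile.

`topicbin` implements a three-step unsupervised pipeline:

1. **k-mer representation.** Each read becomes a vector of 4-mer counts.
   A window slides over the read; every valid window increments the observed
   4-mer *and* its reverse complement, so a read and its reverse complement
   get identical vectors while the feature space keeps all `4^4 = 256`
   dimensions.
2. **Topic transformation.** A Latent Dirichlet Allocation (LDA) model
   treats reads as documents and 4-mer occurrences as words, and is
   estimated by collapsed Gibbs sampling. Each read is then represented by
   its topic proportions `theta_d` — a drop from 256 to `T` (default 20)
   dimensions that absorbs correlated 4-mer usage into shared latent
   factors.
3. **Feature-weighted clustering.** The topic vectors are clustered by
   SKWIC, a K-means variant that learns one weight per cluster and
   dimension while clustering, under per-dimension Manhattan distance. The
   user supplies the cluster count `K` (the expected species count); the
   method does not infer it.

With truth labels the binning is scored by precision (cluster purity),
sensitivity (species recovery, with unclassified reads inflating only the
denominator) and their harmonic mean F1.

## The model and its estimation

For token `i` of read `d` carrying 4-mer `w`, the collapsed sampler draws a
topic from

$$P(z_i = j \mid \cdot) \propto
  \frac{\beta + n^{w}_{-i,j}}{W\beta + n^{*}_{-i,j}} \cdot
  \frac{\alpha + n^{d}_{-i,j}}{T\alpha + n^{d}_{-i,*}},$$

with symmetric priors `alpha = 0.1` and `beta = 0.01` — deliberately sparse
priors that push reads toward few topics and topics toward few k-mers,
keeping topic profiles diverse. After the final sweep, point estimates are
read off the count tables:
`theta[d, j] = (n_dj + alpha) / (N_d + T alpha)` and
`phi[j, w] = (n_jw + beta) / (n_j + W beta)`.

Design choices worth knowing:

* **Single-state estimates, not sample averages.** Averaging `theta` across
  post-burn-in sweeps mixes topic labels between sweeps (label switching),
  so the estimate comes from the final state only. `burn_in` is a
  convergence allowance, and `track_logjoint = TRUE` records the collapsed
  log-joint per sweep as the convergence diagnostic.
* **Sampler length.** Defaults are 1000 sweeps with 500 burn-in; both are
  exposed. On well-separated communities the chain stabilizes within a few
  hundred sweeps.
* **Token multiplicity.** Every counted occurrence is its own token, the
  standard bag-of-words reading: a read of length `L` contributes
  `2(L - 3)` tokens under the default both-strand policy.
* **Determinism.** Sampling uses inverse-CDF draws from R's seeded RNG, in
  a fixed token order (window position, observed before complement), so one
  seed reproduces a chain bit for bit. The resampling kernel runs in
  compiled code; interpreted R cannot revisit millions of tokens a thousand
  times.
* **Reverse-complement handling.** Adding each window's complement keeps
  the full 256-dimensional space while making vectors strand-symmetric; a
  `forward` policy is available for ablation. Windows containing `N` are
  skipped outright rather than imputed, and reads with no valid window are
  excluded from the corpus, reported, and counted as unclassified during
  evaluation.

## SKWIC

SKWIC minimizes

$$J = \sum_{i=1}^{K} \sum_{x_j \in \chi_i} \sum_{k=1}^{n} v_{ik}
  \lvert x_{jk} - c_{ik}\rvert + \sum_{i=1}^{K} \delta_i \sum_k v_{ik}^2,
  \qquad v_{ik} \ge 0,\; \textstyle\sum_k v_{ik} = 1,$$

alternating a closed-form weight update, nearest-centroid assignment under
the weighted Manhattan distance, a centroid update, and a rescaling of the
regularizers `delta_i`. Implementation decisions, in the order they bit:

* **First iteration.** The published loop updates weights before any
  assignment exists. The implementation therefore assigns points once with
  uniform weights, computes `delta` from that configuration, and then
  enters the loop in the published order (weights -> assignment ->
  centroids -> delta).
* **Centroid rule.** Under Manhattan distance the per-dimension median
  minimizes within-cluster cost, so the median is the default (`mean` is
  available).
* **Negative weights.** The closed-form update can leave the simplex; such
  rows are clipped at zero and renormalized (logged when it happens). This
  is the standard remedy and keeps the constraint exactly satisfied after
  every iteration.
* **`K_delta = 1`.** The `delta` update's scale constant is not pinned by
  theory; 1 makes `delta_i` track the cluster's weighted dispersion, which
  balances the two objective terms. It is exposed in the API.
* **Degeneracies.** A perfectly tight cluster gets `delta = 1e-9` so the
  weight update stays defined; an emptied cluster is reseeded with the
  point farthest from its own centroid; assignment ties go to the lowest
  cluster index.
* **Convergence.** Iterations stop when the largest absolute centroid move
  drops below `tol = 1e-6` (or `max_iter = 100`). A final assignment pass
  against the converged centroids and weights ensures no point could lower
  its weighted distance by switching clusters.
* **Initialization.** Centroids start from `K` distinct data points drawn
  by the seeded RNG; `n_restart` keeps the lowest-objective fit across
  restarts (default 1).

With weights frozen at `1/n` (`weighting = FALSE`) the algorithm is exactly
Manhattan K-medians — the test suite exploits this reduction against an
independent implementation.

## What the simulator emulates — and what it does not

`simulate_community()` exists so the pipeline can be exercised and
validated without downloading reference genomes. Each species' genome is
generated from its own order-1 Markov chain over `{A,C,G,T}`; the
`divergence` parameter mixes each species' transition matrix with the
uniform chain, which directly controls how far apart the species' 4-mer
profiles are — the only genome property the method uses. Reads are sampled
with species probabilities proportional to the abundance ratios, uniform
start positions, Gaussian length about `read_length_mean`, a uniform
strand choice, and i.i.d. substitution errors.

The defaults — 3 species at 1:1:1, genomes of 50 kbp, 1,500 reads of
~1 kbp (sd 50), 1% substitution errors, divergence 0.8 — describe a small
community of long reads with clearly distinct composition signatures, the
regime where composition-based binning is expected to work well. These are
also the conditions used by the package's own validation, chosen once:
1,500 reads keeps a full 1000-sweep Gibbs run on ~3 million tokens to a
couple of minutes, while the read length and error rate mirror the
long-read simulated-community setting the method targets.

Passing tests on these communities show that the pipeline recovers
composition structure that is genuinely present. They do not show
performance on real data: real genomes share composition between related
taxa, have repeats, horizontally transferred segments and skewed GC within
a genome; real sequencers produce indels and quality-dependent errors;
real communities have many more species and very uneven abundances. The
Markov simulator makes none of these hard cases, and the `divergence`
knob can make the problem arbitrarily easy or impossible (`divergence = 0`
gives statistically identical genomes, on which F1 falls to chance).

## Numerical and testing notes

* Topic counts: `T = 20` is the default working well for small simulated
  communities; around 100 is a better operating point for large or real
  datasets. At `T = 2` performance degrades markedly (information loss),
  which `topic_sweep()` demonstrates; the package treats the sweep as an
  experiment helper, not model selection.
* The sampler is validated against exhaustive enumeration of the collapsed
  joint on corpora of up to 6 tokens: pairwise topic-co-assignment
  probabilities from 50,000 post-burn-in sweeps agree within 0.02 on
  corpora whose posterior a single chain can traverse. Corpora consisting
  of multi-token single-word documents (e.g. two homopolymer reads) have a
  near-bimodal posterior whose modes a chain switches between only every
  few thousand sweeps; their co-assignment is checked by averaging
  independent seeded chains at a tolerance matching that switching rate.
  The sharp correctness check is separate and exact: the full conditional
  evaluated by the package is compared against the ratio of enumerated
  collapsed joints at every token of small corpora, to 1e-10.
* The weight update is validated against a numeric constrained optimizer
  (stationarity of the objective on the simplex) when no clipping
  triggers, and the delta update against hand algebra (uniform weights
  give `delta = K_delta * S` for total dispersion `S`).
* Scoring: precision/sensitivity are validated against independent loop
  implementations and checked for invariance to cluster/species
  permutations. F1 reproduces published worked examples to 4 decimals.
* Problem sizes in the test suite are deliberately modest (hundreds of
  reads, reads of a few hundred bp) except for one full-scale recovery run
  at the simulator defaults; the whole suite runs in a few minutes on one
  core.

## Known limitations

* `K` must be supplied; the method neither infers the species count nor
  rejects outlier reads (every read is assigned, so precision and
  sensitivity coincide when nothing was excluded before clustering).
* Single chain, single restart by default: on hard (low-divergence or
  high-`T`) instances the topic space and the clustering can both settle
  in local optima; `n_restart` and comparing seeds are the pragmatic
  remedies.
* The simulator's error model is substitution-only by design; reads with
  many `N`s or shorter than 4 bp are dropped from the corpus rather than
  placed.

## A worked example

```{r example, eval = FALSE}
library(topicbin)

com <- simulate_community(n_species = 3, abundance = c(1, 3, 9), seed = 7)
res <- bin_reads(com$reads, K = 3, topics = 20, truth = com$truth, seed = 7)
res$scores
glance(res$lda)
tidy(res$skwic)
autoplot(res)

sw <- topic_sweep(com$reads, com$truth, topic_values = c(2, 10, 20),
                  K = 3, seed = 7)
plot_topic_sweep(sw)
```
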