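---
title: "Bayesian change-point segmentation of bisulfite accessible regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian change-point segmentation of bisulfite accessible regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseg)
```

## The problem

Bisulfite deaminates cytosines that are exposed in single-stranded DNA but
not those protected in duplex or chromatin. Treating intact nuclei with
bisulfite and deep-sequencing an amplicon therefore gives, molecule by
molecule, a binary readout of which C positions were single-stranded at the
moment of treatment: a C>T call on the top strand (or G>A in top-strand
coordinates for the bottom strand) marks an accessible site. Recurrent runs
of converted Cs — *bisulfite accessible regions* (BARs) — are of particular
interest in immunoglobulin V genes, where activation-induced deaminase
(AID) also requires single-stranded DNA to initiate somatic hypermutation.

Two things make calling BARs from such data statistically awkward. First,
the conversion probability is not two-state: accessibility varies
continuously between and even within regions, so a finite-state HMM is a
poor fit. Second, the informative sites are irregularly spaced along the
amplicon, so any prior on "a change occurred between these two observations"
must account for the gap width. `barseg` implements a continuous-state
Bayesian multiple change-point model that addresses both, plus the
clustering, patch-size and spatial-correlation machinery built around it.

## The model

Molecules are first grouped by accessibility pattern (see *Clustering*
below); within a cluster, summing the binary calls gives per-site binomial
counts. Let the informative sites be $\tau_1 < \dots < \tau_N$ with counts
$X_{\tau_t} \sim \mathrm{Binomial}(\theta_t, n)$, where $n$ is the
(duplicate-weighted) number of molecules. The accessibility parameter
$\theta_t$ is piecewise constant: latent indicators
$I_{\tau_t} \sim \mathrm{Bernoulli}(p_t)$ mark the sites where $\theta$
changes ($I_{\tau_1} = 1$ by convention), and at each change the new
$\theta$ is drawn from a $\mathrm{Beta}(\mu_0, \nu_0)$ prior written in
mean/sample-size form, i.e. $\mathrm{Beta}(\mu_0\nu_0, (1-\mu_0)\nu_0)$.

Because boundaries arise along the DNA as a Poisson process with rate
$\lambda$ per bp,
$$p_t = 1 - e^{-\lambda(\tau_t - \tau_{t-1})}, \qquad p_1 = 1,$$
so wider gaps between consecutive informative sites carry more prior change
mass — the irregular spacing of C positions is handled in the prior, not
ignored.

For a candidate segment $i..j$ sharing one $\theta$, conjugacy gives the
posterior $\mathrm{Beta}(\mu_{i:j}, \nu_{i:j})$ with
$$\nu_{i:j} = \nu_0 + mn, \qquad
  \mu_{i:j} = \frac{\nu_0\mu_0 + X_{i:j}}{\nu_0 + mn},$$
where $m = j-i+1$ and $X_{i:j}$ is the summed count. The normalizing
constant of that Beta, $c_{i,j} = 1/B(\mu_{i:j}\nu_{i:j},
(1-\mu_{i:j})\nu_{i:j})$, is the workhorse of the recursions: ratios like
$c_0/c_{i,j}$ are exactly the Beta-binomial marginal likelihood of the
segment (up to binomial coefficients, which are constant across
segmentations and omitted everywhere, including in the enumeration oracle,
so that all marginals are directly comparable).

Two dynamic-programming passes then yield exact posteriors in
$O(N^2)$–$O(N^3)$ time:

* a **forward** pass over $p_{i,t}$, the probability that the most recent
  change at or before $\tau_t$ happened at $\tau_i$;
* a **backward** pass over $q_{j,t+1}$, the probability that $\tau_j$ is
  the last site before the next change after $\tau_t$. The boundary term
  $q_{t,t+1} = p_{t+1}$ is exact: marginally, the data after a fresh change
  are distributed identically whether or not the change occurred, so the
  future carries no information about $I_{\tau_{t+1}}$ on its own.

Combining the two gives, for every site $t$, a full posterior distribution
$w_{i,j,t}$ over the segment $(i,j)$ containing it, with weights
proportional to $p_{i,t}\, q_{j,t+1}\, c_{i,t} c_{t+1,j} / (c_{i,j} c_0)$
(the Beta-ratio factor rejoins the two half-segments). From it follow the
two quantities plotted per cluster:

* the posterior accessibility mean
  $E(\theta_t \mid X) = \sum_{i \le t \le j} w_{i,j,t}\, \mu_{i:j}$, and
* the posterior change probability
  $\Pr(I_{\tau_{t+1}} = 1 \mid X) = \sum_i w_{i,t,t}$, the total weight on
  segments ending exactly at $t$. The printed form of this quantity admits
  more than one reading of its normalization; the implementation uses the
  segment-end marginal, which is manifestly a probability and is verified
  against exact enumeration (below) to $10^{-8}$.

### Hyperparameters

All hyperparameters are empirical-Bayes estimates, so the model has no
free knobs in routine use:

| parameter | default | meaning |
|---|---|---|
| $\nu_0$ | $n$ | prior worth one data point |
| $\mu_0$ | $\sum_t x_t / (Nn)$ | prior mean = sample mean, clamped to $[10^{-6}, 1-10^{-6}]$ |
| $\lambda$ | grid search | 40 log-spaced values in $[10^{-4}, 1]$ per bp |

$\lambda$ maximizes the marginal likelihood
$f(x_{\tau_1},\dots,x_{\tau_N}) = \prod_t \sum_i p^\star_{i,t}$, available
as a by-product of the forward pass; ties go to the smallest $\lambda$.
Under the empirical $\mu_0$ rule the full-segment posterior mean
$\mu_{1:N}$ equals $\mu_0$ exactly — a useful internal consistency check.

Clusters of different sizes have different $n$ and hence different
posterior concentration; `scale_counts()` divides $x$ and $n$ by a common
factor, which provably leaves every $\mu_{i:j}$ unchanged while restoring a
comparable posterior variance $(\mu_0 + X/n)(1-\mu_0-X/n)/(1+n)$. Scaling
is exposed as an option and off by default. Scaled counts are real-valued,
so every factorial in the likelihood machinery is a gamma function.

### Validation by exact enumeration

`enumerate_posterior_oracle()` computes the same posteriors by brute force:
it sums over all $2^{N-1}$ assignments of $I_{\tau_2},\dots,I_{\tau_N}$,
weighting each configuration by its Bernoulli prior times the product of
Beta-binomial segment marginals. The oracle shares no code path with the
recursions and is the arbiter for every indexing convention in them. The
test suite requires agreement of posterior means, change probabilities and
log marginals to $10^{-8}$ over random instances with $N \le 10$; observed
agreement is at machine precision ($\sim 10^{-14}$).

## Clustering

Molecules are grouped before segmentation because distinct sub-populations
expose distinct regions; pooling them would average incompatible patterns.
Since the calls are binary, distance is Hamming; since Hamming is not
Euclidean, linkage is complete ($D(X,Y) = \max_{x \in X, y \in Y} d(x,y)$).
Identical molecules are deduplicated and clustered once with multiplicity
weights — complete-linkage merge heights do not depend on multiplicity, so
this is exactly equivalent to clustering the expanded matrix at a fraction
of the cost. Distinct rows are put in canonical lexicographic order first,
making the result invariant to input row order.

The number of clusters is the user's choice (the motivating analysis fixed
$k = 6$ per strand); `gap_statistic()` is advisory. Its reference
distribution resamples each column as an independent Bernoulli at the
column's empirical frequency: the classical uniform-over-range reference box
is degenerate for 0/1 data, while per-column Bernoulli preserves marginal
site accessibility. $B = 50$ reference draws by default; the selected $k$
is the smallest with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) -
\mathrm{se}(k+1)$.

## Patch sizes: four definitions

The historical definition calls a patch wherever an individual molecule has
$\ge 2$ consecutive converted Cs, ending at the last converted C
(`previous_patch_caller()`). That is conservative twice over: it ignores
model-based boundary uncertainty, and the true boundary can lie anywhere
between the last converted C and the next unconverted one. Because
boundaries follow a Poisson process, the expected boundary position given
that it falls between two consecutive Cs is their midpoint; the midpoint
("MP") variants therefore extend each end to the midpoint with the flanking
informative site (falling back to the last-C end at the amplicon edges, so
the midpoint size always dominates the last-C size).

The model-based ("new") size needs no run-calling at all: at the cluster's
peak site (maximal observed conversion frequency) the distribution
$\{w_{i,j,t}\}$ *is* the posterior distribution of the patch, and
`model_patch_size()` reports the expectation of the segment size under it,
in last-C or midpoint form. `call_bars()` declares a cluster to contain a
nontrivial BAR when $\ge 2$ consecutive sites have posterior mean
$\ge 3\mu_0$ (both the factor and the run length are exposed as options;
they operationalize a qualitative criterion), takes each maximal elevated
run, and extends it to the maximum-a-posteriori segment around the peak.
`patch_summary_table()` averages cluster-level means unweighted by default
— clusters, not molecules, are the replication unit when comparing
definitions — with size-weighted averaging available.

## The synthetic-data generator

`synthetic_spec()`/`simulate_matrix()` generate matrices with known truth:
each molecule draws a mixture component (a cluster archetype defined by
elevated-$\theta$ segments over a shared baseline), then independent
Bernoulli conversions per site. `default_synthetic_spec()` encodes the
study conditions this package was built around: a 346 bp amplicon with 80
irregularly spaced informative sites, a patternless majority (75.4% of
molecules), five BAR archetypes at proportions 8.1/5.9/4.5/3.6/2.5%
(together 24.6%), accessibility 0.3 inside a BAR and a 0.0073 baseline (the
observed top-strand conversion rate). `simulate_shm()` generates the much
sparser hotspot matrices of AID-driven mutation data.

What the generator does *not* emulate: sequencing or consensus errors, PCR
duplication, within-segment accessibility gradients, or correlated
conversion along a molecule. Passing tests therefore demonstrate
correctness of the inference given the model's own assumptions, not
robustness to all artifacts of real libraries.

One property of these conditions deserves emphasis. At $\theta = 0.3$ over
a ~5-site segment, about half the molecules carry $\le 1$ converted site
inside their own BAR and are indistinguishable from background molecules —
no clustering algorithm can assign them, and recovered cluster fractions
will undershoot the generating mixture proportions. Segmentation-level
recovery is unaffected (boundaries of a planted $\theta$ 0.3 vs 0.01
segment at $n = 500$, $N = 60$ are recovered within one site in every one of
50 replicates in the test suite). The end-to-end test that routes recovery
*through clustering* instead uses a separable regime ($\theta = 0.5$ over
6-site segments), where nearly all molecules carry an identifiable pattern;
this is a statement about the identifiability of the data, not about the
implementation.

## Numerical choices

* All recursions run in log space with per-site normalization; Beta-function
  ratios go through `lgamma`. Underflow is structurally impossible; any NaN
  aborts.
* Binomial coefficients are omitted from all marginals (constant across
  segmentations; required anyway once counts are real-valued after
  scaling).
* $\mu_0$ is clamped at $\varepsilon = 10^{-6}$ for all-zero or
  all-converted clusters to keep Beta parameters positive.
* Degenerate priors are honored exactly: $\lambda = 0$ collapses to the
  single-segment conjugate posterior everywhere; $p_t \equiv 1$ gives
  independent per-site posteriors.
* Clustering ties are resolved by `stats::hclust` after canonical row
  sorting, which fixes a deterministic merge order.
* The peak site of a BAR breaks frequency ties toward the lower position;
  the top-k hotspot selection does the same.
* Problem sizes in the test suite — enumeration-oracle instances at
  $N \le 10$, recovery at $N = 60$, $n = 500$, 50 replicates, end-to-end at
  1500 molecules per replicate — were chosen to exercise every code path
  with comfortable statistical resolution.

## Known limitations

* The model assumes conversions are independent across molecules and sites
  given $\theta$; chemically cooperative conversion or strand breathing
  would violate this.
* Cluster-then-segment is a hard assignment: molecules that cannot be
  assigned (see above) dilute cluster counts, and the model sees only the
  diluted binomial.
* The marginal-likelihood grid for $\lambda$ spans $[10^{-4}, 1]$ per bp;
  data whose change density falls outside that range would pin the
  estimate to a grid edge.
* `previous_patch_caller()` treats runs in site-index space; two converted
  Cs separated by a long C-free gap still form a run, exactly as the
  historical definition prescribes.

## A minimal session

```{r example}
sim <- simulate_matrix(default_synthetic_spec(n_sequences = 1500), seed = 11)
cl <- complete_linkage_cluster(sim$matrix, k = 4)
cl

rows <- cl$labels == 2
sub <- mutation_matrix(sim$matrix$calls[rows, , drop = FALSE],
                       sim$matrix$positions, "top")
fit <- segment_sites(to_site_counts(sub))
fit

call_bars(fit, cluster = cl$names[2], strand = "top")
```
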