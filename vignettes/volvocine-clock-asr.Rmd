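---
title: "Dating and ancestral-state methods in volvoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and ancestral-state methods in volvoclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volvoclock)
```

volvoclock implements the downstream inference stack of a fossil-calibrated
molecular-clock and ancestral-state study of the volvocine green algae: node
dating on a fixed rooted topology under four relaxed-clock rate processes
with soft-bound fossil calibrations, Mk-model ancestral-state reconstruction
with stochastic character mapping and parsimony oracles, clock-gene ranking,
leave-one-fossil-out cross-validation, and a pairwise-identity screen for
cryptic species. This vignette explains the models, the assumptions behind
them, the numerical choices, and what the synthetic-data experiments do and
do not demonstrate.

## The dating model

The topology is fixed; the parameters are the internal-node ages (My before
present, tips at age 0), one substitution rate per branch
(substitutions/site/My), and the hyperparameters of the rate process and of
the node-age prior.

**Node-age prior.** Node ages follow the complete-sampling birth-death
process conditioned on the root age: given the root age $t_1$, the non-root
ages are i.i.d. with density proportional to
$\lambda r^2 e^{-rt}/(\lambda - \mu e^{-rt})^2$ on $(0, t_1)$, with
$r=\lambda-\mu$; the critical case $\lambda=\mu$ reduces analytically to
$(1+\lambda t)^{-2}$ up to normalization (`bd_age_density`). The root age is
uniform on $(0, \mathrm{root\_max}]$ — 2000 My in the Archaeplastida-scale
configuration — unless the root itself carries a calibration. Birth and
death rates get vague exponential hyperpriors and are sampled;
$\mu < \lambda$ is enforced.

**Soft-bound calibrations.** A fossil constraint on the age of the most
recent common ancestor of two tips places 95% of its mass uniformly between
its minimum and maximum bound, with 2.5% in an exponential tail on each
side; a minimum-only bound places 95% in a diffuse exponential component
above the minimum (scale defaulting to the minimum itself) and 5% below it.
Tail rates are chosen so the density is continuous at each bound, and tail
masses of zero recover hard bounds. Calibrated nodes take this density *in
place of* the birth-death kernel. Because the ordering constraint
(parent older than child) and the rest of the joint prior still act on
calibrated nodes, the realized marginal tail mass in a prior-only run can
deviate slightly from the nominal value; the acceptance suite checks it to
within half a percentage point on a four-tip configuration where the
distortion is small.

**Rate processes.** Four per-branch rate models are available, with branch
$b$'s prior term conditioned on its parent branch where autocorrelated:

* `LN` — autocorrelated lognormal: $\log r_b \sim N(\log r_{pa(b)},
  \sigma^2 \Delta t_b)$, root branches anchored at the base rate $\nu$.
* `CIR` — Cox-Ingersoll-Ross mean-reverting diffusion with reversion
  $\theta$ and stationary Gamma law; the transition density is evaluated
  through the noncentral-$\chi^2$ representation (`dchisq` is log-stable
  where the scaled-Bessel form over- or underflows), and the stationarity
  condition $2\theta\nu/\sigma^2 > 1$ is enforced.
* `UGAM` — i.i.d. Gamma rates with mean $\nu$ and variance $\sigma^2$.
* `WN` — white noise: independent Gamma rates whose variance
  $\sigma^2/\Delta t$ shrinks with branch duration.

All four collapse onto the strict clock as $\sigma^2 \to 0$.

**Observation model.** The likelihood is a branch-length observation model,
not a full phylogenetic likelihood over alignments: the expected
substitution length of a branch is rate × duration, observed either as a
Poisson count over a stated number of sites (synthetic data) or as a branch
length with a normal error whose default SE is $\sqrt{\ell/\mathrm{sites}}$
floored at $10^{-6}$ (real input trees). This is a deliberate design
decision: the full-likelihood engine used upstream is an external published
tool, and the dating mathematics — priors, clock processes, calibrations,
HPD summarization — is the content this package implements and tests. Dates
produced through the normal approximation on real branch lengths should be
read accordingly.

**Sampler.** `mcmc_date` runs Metropolis-within-Gibbs. Internal nodes are
two-coloured by depth parity so that entire classes can be proposed at once
and accepted per node; a node's age slides uniformly inside its (max child
age, parent age) window on even sweeps and takes a reflected normal step
(SD 0.2 × window) on odd sweeps. Branch rates are Gibbs-sampled where the
gamma prior is conjugate to the Poisson counts (UGAM, WN) and updated by
log-scale random-walk Metropolis in parity classes otherwise. A whole-tree
scale move (ages × c, rates ÷ c) runs every sweep; expected branch lengths
are invariant under it, so only the priors enter its acceptance ratio.
Hyperparameters move by log-scale random walks. Chains are deterministic
given a seed; burn-in defaults to 20% and two chains per run, matching the
upstream study's settings (minimum 10,000 generations, ~20% discarded).
Convergence is assessed by rank-normalized split-$\hat R$ (floored at 1,
since finite-sample noise can push the raw estimate marginally below 1) and
effective sample sizes.

**HPD intervals** are shortest contiguous intervals containing
$\lceil 0.95\,n \rceil$ sorted draws, printed older-bound-first
(e.g. `"349-237"`), as chronogram intervals conventionally are.

**Fossil cross-validation** removes each calibration in turn, re-runs the
dating, and reports $D_i$ = posterior mean age of the calibrated node minus
the calibration midpoint (minimum, for minimum-only rows), plus
$\sum_i D_i^2$. A calibration in strong conflict with the rest shows the
largest $|D_i|$ when the remaining fossils anchor the time scale densely;
with very few fossils the outlier also distorts the other rows' deviations,
which is a property of the design, not of the implementation.

## Mk ancestral-state machinery

`mk_loglik` is Felsenstein pruning with per-node scaling; transition
probabilities come from an eigendecomposition of the rate matrix with a
scaling-and-squaring fallback for ill-conditioned cases. Rate-matrix
structures: `ER` (one rate), `ARD` (one rate per ordered pair), `ORDERED`
(adjacent-state transitions only, one rate per direction), and `CUSTOM`
(explicit mask). The root prior defaults to the stationary distribution of
the fitted matrix, with `uniform` and `conditional` (root conditionals)
alternatives; the upstream study does not state its choice, and reported
counts on the fixture are insensitive to it. Missing tips (`"?"`)
contribute a vector of ones. `fit_mk` maximizes the likelihood by bounded
quasi-Newton on log rates (bounds $[10^{-9}, 10^3]$ per My, five seeded
starts); `akaike_weights` converts fits to AIC weights.

`marginal_asr` computes per-node marginal posteriors by an up-down pass
consistent with the same root treatment. `stochastic_map` samples full
character histories: node states from the joint conditionals (pruning plus
preorder sampling), then branch paths conditioned on their endpoints by
uniformization with rate bound $1.05 \times \max_i |q_{ii}|$ — endpoint
conditioning by rejection stalls on long branches, uniformization does not.
Histories are reproducible under a fixed seed.

Parsimony oracles give the deterministic floor for every history:
`fitch_count` (equal costs, missing tips as full state sets, polytomies
folded sequentially) and `sankoff_cost` (arbitrary cost matrices, `Inf`
encoding forbidden transitions, e.g. the loss-only treatment of full
meiotic hatching). For "number of independent origins",
`count_origins` minimizes, across *all* minimum-change reconstructions,
the number of transitions into the derived state set. This uses a
lexicographic (cost, gains) dynamic program, which is exact because both
objectives are sums over edges and child subtrees are independent given
the child state; ties in the reported single labeling break
deterministically by state order.

## The volvocine fixture

`build_volvocine_fixture` ships a 31-tip species-level chronogram whose
topology follows the study's tree (Goniaceae monophyletic; *Vitreochlamys*
sister to the Tetrabaenaceae; a *Chlamydomonas* clade sister to
Goniaceae + Volvocaceae; Volvocaceae = (section *Volvox*, (PVC,
(*Yamagishiella*, EVP)))) and whose node ages are the reported CIR-clock
means where the text states them (TGV crown 298 My with 95% HPD 349–237,
and so on); the remaining internal ages are fixed interpolations flagged as
such in the source. Trait codings come from main-text statements only —
anything resolved only in supplementary figures is `"?"` — and every coded
cell is traceable through the shipped provenance table. Sampling matters:
the fixture carries several unicellular *Chlamydomonas* and *Vitreochlamys*
lineages because with too few of them a symmetric Mk model reconstructs a
multicellular root, contrary to both parsimony and the study's own
reconstruction.

On this fixture the package reproduces the study's counts: 2 origins of
multicellularity (parsimony and modal stochastic maps agree), 3 origins of
anisogamy under both the 2-state and the unordered 3-state coding, 2 losses
of full meiotic hatching under the loss-only (irreversible) treatment, and
a minimum of 4 independent gains of sterile somatic cells across all
minimum-change reconstructions — the minimum is 4 rather than 5 because one
optimum concentrates the EVP-clade gains into a single crown gain plus two
*Eudorina* losses and a re-gain.

## Synthetic-data conditions

The generators return their ground truth next to every observable. Defaults
are desk scale: 20 tips, 1000 sites, 3 calibrations. Birth-death trees are
simulated forward and stopped one exponential waiting time after the n-th
birth (stopping exactly at the n-th birth would place a node at age 0);
under pure birth the root age then has mean
$\lambda^{-1}\sum_{k=2}^{n} 1/k$, which the suite checks. Rate histories
use one design rule for all four clock models
(`default_rate_process`): base rate $\nu = 0.002$ subst/site/My and a
coefficient of variation of 0.5 on a 15-My reference branch, so the four
processes are comparably — and moderately — non-clock-like rather than any
one being favoured. Calibrations are two-sided bounds containing the truth
by construction, with an optional planted outlier for cross-validation
tests.

The recovery suite simulates each clock model at these conditions over 20
replicates and requires 95% HPDs to cover at least 90% of true node ages,
with chains of 8,000 sweeps (12,000 for CIR, the slowest-mixing process).
What this shows: the joint prior, likelihood and sampler are mutually
consistent — data generated under each model are recovered with
approximately nominal uncertainty. What it does not show: robustness to
model misspecification, to alignment-level likelihoods, or to the scale of
the real 164-taxon analysis; the study's printed dates are carried as
fixture annotations, not re-derived.

## Gene ranking and the identity screen

Clock-gene statistics are the root-to-tip variance (population variance of
tip path lengths, zero for a clock-like tree; unrooted gene trees are
midpoint-rooted by default, outgroup-rooted when configured), the
bipartition concordance (shared non-trivial splits over the species tree's
splits restricted to the shared tip set; a flag switches the denominator to
the gene tree), and the total tree length. Selection is a deterministic
lexicographic sort — concordance down, variance up, length down — taking
the top k (8 or 16 in the motivating study); whether the upstream tool
weighted rather than sorted is not stated, so the simple stable sort is
used.

The cryptic-species screen is classical Needleman-Wunsch with affine gaps
(match +5, mismatch −4, gap open 10, extend 0.5 by default — the common
nucleotide scheme — or a substitution matrix for proteins). Adjacent
gap-in-A/gap-in-B columns are permitted, which matters: an alignment with
no aligned residues can be optimal for short dissimilar sequences, and the
enumeration oracle in the test suite checks exactly this. Percent identity
is reported under two conventions (identical columns over all columns, or
over gap-free columns only) because the published strain-pair values
(92.47%, 91.25%, 98.06%) do not pin the convention; those values require
external database sequences and are documentation anchors, not
machine-checked results.

## Numerical choices and limitations

* Matrix exponentials: eigendecomposition per rate matrix, reused across
  branches; Padé scaling-and-squaring fallback when the eigenvector matrix
  is ill-conditioned (reciprocal condition below $10^{-10}$).
* The node-age move windows make proposals automatically valid, so the
  ordering constraint never costs rejections by itself; hard bounds
  (root maximum, zero tail masses) act through the prior.
* `sim_seq_pair` hits its target identity to within $1/\mathrm{length}$ by
  construction; `hpd_interval` requires at least 100 draws.
* Polytomies are rejected by default and admitted only where they occur in
  practice (gene trees with collapsed low-support branches); ASR resolves
  them by sequential folding, equivalent to arbitrary zero-length
  resolution.
* No co-estimation of topology, no correlated-character tests, no hidden
  rates, and no MCMC over Mk parameters (maximum likelihood plus AIC
  weights stand in for the Bayesian ASR variant of the upstream toolchain;
  where the two upstream tools disagreed, this package implements the
  stochastic-mapping estimator and the parsimony oracles only).
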