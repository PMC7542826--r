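---
title: "Modelling chromosome-number and sex-chromosome evolution with karyevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chromosome-number and sex-chromosome evolution with karyevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevo)
```

## The model

karyevo treats the haploid chromosome number $n$ of a lineage as a
continuous-time Markov chain on the bounded integer interval
$n_{\min} \dots n_{\max}$. Three processes move the chain:

* **fission** — $n \to n+1$ at rate $\delta$ (a centromeric split, or more
  generally any gain of one chromosome);
* **fusion** — $n \to n-1$ at rate $\phi$ (a Robertsonian-type join);
* **polyploidy** — $n \to 2n$ at rate $\rho$ (whole-genome duplication).

An optional **demiploidy** transition $n \to \lceil 1.5\,n \rceil$ (triploid
intermediates, e.g. via unreduced gametes) is supported with a default rate
of zero and is not exercised in the standard analyses. Transitions whose
target leaves the state space are dropped rather than redirected, so no
probability mass is moved to a state that would misrepresent the event — a
doubling that would overshoot $n_{\max}$ simply cannot happen in the model.
The "simple" model is the $\{\delta, \phi\}$ pair; the "complex" model adds
$\rho$ and nests the simple one exactly at $\rho = 0$.

The generator can be linked to a binary trait (we use it for reproductive
mode): the state space doubles to (haploid number, trait state), each trait
state carries its own chromosome rates, and the trait flips with rates
$q_{01}, q_{10}$. This is the construction used to ask whether asexual
lineages tolerate polyploidy better than sexual ones.

### State-space bounds

The model needs a finite $n_{\max}$. The default rule,
`default_n_max()` $= 2\max(\text{observed}) + 1$, keeps one whole-genome
duplication from the largest observed count inside the state space while
keeping the rate matrix (and hence every likelihood evaluation) small. The
lower bound is 1: a genome cannot have fewer than one chromosome.

### Likelihood

`log_likelihood()` is Felsenstein's pruning algorithm. Ambiguous tip counts
(several published values for one species) enter as uniform probability
vectors over the candidate set; missing tips as vectors of ones. Branch
propagation $e^{Qt}v$ is computed by *uniformization*: with
$\Lambda = \max_i |Q_{ii}|$ and $R = I + Q/\Lambda$ (a stochastic matrix),

$$e^{Qt}v = \sum_{k \ge 0} \mathrm{Pois}(k; \Lambda t)\, R^k v,$$

truncated ten standard deviations past the Poisson mean. Because every term
is a non-negative mixture of probability vectors, the scheme is stable in
exactly the regimes where an eigendecomposition of this (non-reversible,
strongly non-normal) generator becomes numerically singular, and the sparse
structure of $R$ — at most a handful of transitions per state — makes each
term cheap. Conditional likelihoods are renormalised at every node, so
underflow is impossible even on large trees. The R-level
`make_propagator()` (used where full $P(t)$ matrices are needed, as in
ancestral reconstruction) takes the eigendecomposition route when a
reconstruction check passes and falls back to scaling-and-squaring matrix
exponentials otherwise; zero-length branches always get the identity
exactly.

### Unit-tree rescaling

Rates and branch lengths trade off exactly: multiplying all rates by $c$
and dividing all branch lengths by $c$ leaves the likelihood unchanged. We
therefore estimate on trees rescaled to unit root depth
(`rescale_to_unit()`) and report rates back-transformed to events per
million years (`back_transform_rates()`), using each tree's own root depth.
This makes chains comparable across trees of a posterior sample whose root
ages differ.

## Inference design

**ML and model choice.** `fit_ml()` maximises the pruning likelihood with
bounded quasi-Newton search from three spread-out starting points (and, via
`chrom_lrt()`, from the simple model's optimum when fitting the complex
model — which guarantees the nested-likelihood ordering numerically).
`likelihood_ratio_test()` compares the two models. Because the polyploidy
rate is constrained to $\rho \ge 0$, the null value sits on the boundary of
the parameter space and the large-sample null distribution of the LRT
statistic is the equal mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, not
$\chi^2_1$. The default (`boundary = TRUE`) uses the mixture — our null
simulations confirm it rejects at the nominal 5% rate, where the plain
$\chi^2_1$ p-value rejects at about half that. `boundary = FALSE` gives the
conventional $\chi^2_1$ value for comparability with software that ignores
the boundary.

**MCMC over a posterior tree sample.** Phylogenetic uncertainty is handled
the way the underlying study design prescribes: one Metropolis–Hastings
chain per tree (default 1000 stored generations), the first 25% discarded
as burnin, 100 states sampled without replacement from the post-burnin
portion of each chain, back-transformed to per-MY units per tree and pooled
— 100 trees × 100 samples = 10 000 pooled draws. Tip-count ambiguity is
resolved by one seeded uniform draw per (tree, chain), so repeating the
analysis across the tree sample also integrates over count uncertainty.

*Priors.* Unit-tree rates get independent exponential priors with mean 100.
The scale is chosen from the regime the model is built for: time-calibrated
insect phylogenies have root depths of roughly 300 MY and empirical per-MY
rates reach ~0.4, i.e. unit-tree rates up to ~10²; a prior concentrated
near zero on that scale would not be weakly informative but would instead
dominate the weakly identified overall rate magnitude in near-saturated
clades. Mean 100 keeps the prior essentially flat over the relevant range
while still proper.

*Proposals and initialization.* Per-parameter sliding windows reflected at
zero, each window tuned every 25 generations during burnin towards a
25–45% acceptance rate (tuning stops at the end of burnin, so the sampled
portion is a fixed kernel). Chains start at a cheap maximum-likelihood
point rather than at the prior mean: with a deliberately weak prior the
posterior can sit orders of magnitude below the prior mean, and a
short chain started there would spend its sampling phase in the transient.
With the likelihood term disabled the sampler reproduces its prior
(Kolmogorov–Smirnov distance < 0.05), which is the convergence check we
rely on in place of per-run diagnostics.

*Comparing clades.* `hpd_interval()` returns the shortest interval holding
⌈0.95 N⌉ sorted draws; `compare_rates()` declares two clades significantly
different in a rate when their 95% HPD intervals are disjoint. No
multiple-testing correction is applied — the comparison rule is reported
as-is, mirroring standard practice for posterior interval comparisons.

## Ancestral states, stochastic maps, event counts

`marginal_ancestral_states()` combines rootward (pruning) and tipward
("outside") conditionals into per-node marginal posteriors under fixed
rates; in the pipeline the rates are each tree's posterior means, and
per-clade root vectors are averaged across the tree sample
(`average_mrca_state()`) — the pie-chart semantics of posterior-averaged
ancestral states. Ties in the most-probable state break towards the smaller
chromosome number, a deterministic and conservative rule (the paper-scale
analyses are insensitive to it; ties occur only in degenerate symmetric
cases).

`stochastic_map()` samples full character histories conditional on the tip
data: node states from the joint reconstruction (root marginal, then each
child given its parent), then each branch path conditional on its endpoints
by modified rejection sampling, with a uniformization-based conditional
sampler as the fallback after a bounded number of rejections — never silent
truncation. Each realized jump carries its event type (fission, fusion,
polyploidy, or trait gain/loss), which is what lets us count fusion versus
fission events under the chromosome model rather than merely state changes;
where two event types share a target (state 1 doubling to 2 is also a
fission step) the type is apportioned by relative rate.
`count_fusion_fission_events()` averages per-map counts per tree and
compares fusion with fission counts by a paired t-test across trees,
flagging the degenerate zero-variance case instead of reporting a
meaningless statistic.

For sex chromosome systems we collapse multi-XY to XY (`collapse_scs()`),
drop parthenogens and unknowns, fit the two-state all-rates-different model
per tree by ML (`fit_mk2_ard()`; cross-checked against `ape::ace` in the
test suite), and reuse the same reconstruction and mapping machinery with
the fitted 2×2 generator.

## The genus-level fusion/fission table

`summarize_genus()` averages haploid autosome numbers per sex chromosome
system within genera (species with several candidate counts contribute
their within-species mean). `classify_mechanism()` encodes the comparative
logic: if XO→XY transitions arise by fusing an autosome to the X, XY
species should carry *fewer* autosomes, so a lower XY mean is classified as
fusion; an increase of at least one autosome as fission; and a positive
increase smaller than one chromosome as "neither", because a single fusion
or fission must shift the mean by a whole chromosome in at least one
species. The one-autosome threshold is a configurable argument — the
underlying comparison has no canonical cutoff, and this choice reproduces
the published labels, including the asymmetry between a +0.2 ("neither")
and a −0.2 ("fusion") difference. For transitions to multi-XY the
reference mean is XY when present, otherwise XO, and any non-decrease is
classified as fission-consistent (a sex-chromosome fission leaves the
autosome count unchanged). The packaged `table1_fixture()` carries the
published 23-genus table; `tabulate_mechanisms()` reproduces its headline
fractions (16/17 fusion for XO→XY; 6/10 versus 4/10 for multi-XY).

## Tip rates and genome-size regressions

`tip_rates()` computes, per tree, (tip count − most probable chromosome
number of the tip's immediate ancestor) / terminal branch length, then
averages signed (directional) and absolute values across the tree sample.
Zero-length terminal branches are skipped with a message rather than
producing infinities. `ols_fit()` wraps `stats::lm`; `pgls_fit()` is
generalized least squares with the Brownian-motion covariance
(`ape::vcv`), the minimal defensible phylogenetic correction when no
further model detail is specified — no $\lambda$ estimation, by design.
Genome sizes are used untransformed, in Mbp; when a species has several
estimates their mean is used.

## Synthetic data

The generator module produces every input the pipeline consumes, and its
defaults describe the study conditions the package is calibrated against:
posterior-like sets of birth–death trees with 100–250 shared tips and a
~300 MY root, chromosome histories at per-MY rates in the 0.003–0.42 band
with root states near the inferred ancestral haploid numbers (6–10),
two-state SCS histories at per-MY rates near 0.002, a minority of asexual
lineages, genome sizes log-normal around 6 000 Mbp (covering roughly
2 000–18 000 Mbp), ~10% ambiguous counts and mostly missing genome sizes.
Trees are simulated conditioned on the tip count and then scaled to the
configured root age — the shape of an empirical time-calibrated posterior,
whose absolute depth comes from calibrations, not from the branching
process; the pure-birth branching-time distribution of the unrescaled
generator is checked against the Yule expectation in the tests.
`simulate_chromosomes()` is an exact Gillespie simulation that returns the
full event history, so tests can replay histories event-by-event and
compare realized event counts with Poisson expectations.

Two things the synthetic data deliberately do not emulate: correlated tree
sets (each simulated tree is an independent draw rather than a sample from
one Bayesian posterior), and taxonomy that follows the phylogeny exactly
(synthetic genera are label blocks; orders are contiguous clades of the
first tree). Passing recovery tests therefore demonstrate the estimators'
behaviour under the model's own assumptions — they do not certify
robustness to tree misspecification or taxonomic error in real data.

In the parameter-recovery experiments each tree of the set receives its own
simulated history under the true rates and its own chain; pooling then
mimics an empirical posterior tree sample centred on the truth without
conflating estimator error with tree error.

## Problem sizes and numerical choices

The test suite and the acceptance script scale the study design down to
sizes a laptop handles comfortably while keeping every statistical claim
intact: likelihood oracles run on ≤4 tips × ≤6 states where brute-force
enumeration is exact; null LRT calibration uses 200 datasets of 50 tips;
paper-scale recovery uses 10 trees × 100 tips at the published
Blattodea-excluding-Isoptera rates (fusion 0.420, fission 0.385, polyploidy
0.004 per MY, 300 MY root); HPD-disjointness power uses 20 replicates of
two 100-tip clades with a tenfold fission-rate difference; stochastic-map
calibrations use 10 000 maps. The acceptance script re-runs a 5-tree ×
100-tip version of the full analysis from scratch.

Other numerical decisions, collected: propagator truncation error is far
below the 1e-10 row-sum contract; conditional likelihoods are renormalised
at every node; eigen-based propagators clamp round-off negatives (~1e-14)
to zero; HPD ties go to the lowest window; most-probable-state ties go to
the smaller state; optimizer non-convergence is flagged on the returned
fit, never silently accepted; Mk2 fits landing on the zero boundary are
flagged because one rate is then unidentifiable.

## Known limitations

* The boundary-corrected LRT is *conservative* in finite samples: the score
  for the polyploidy rate at zero is negative in far more than half of
  50-tip null datasets (whole-genome doublings are hard to mimic by chance),
  so the polyploidy MLE is exactly zero much more often than the asymptotic
  50% and the realised type-I error sits well below the nominal level. The
  test never overstates support for polyploidy; calibration improves with
  tree size and count dispersion, and the null-calibration test in the
  suite documents the deficit rather than hiding it.
* Rates are homogeneous within a clade; there is no speciation/extinction
  coupling (no SSE-style models) and no chromosome-arm (fundamental number)
  accounting.
* The overall rate *magnitude* in near-saturated clades is only weakly
  identified (the fission/fusion ratio is much better determined); with the
  weak prior this shows up as wide HPDs rather than bias.
* The genus-level fusion/fission classification is comparative, not
  model-based: it cannot separate sex-chromosome turnover from fusion when
  autosome counts happen to coincide, and it uses only genera harbouring
  two or more SCS types.
* PGLS assumes Brownian residuals with known covariance; no measurement
  error in genome sizes is modelled.
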