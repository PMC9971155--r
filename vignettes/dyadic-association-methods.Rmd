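---
title: "Quantifying inter- and intrasexual social bonds from focal-sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter- and intrasexual social bonds from focal-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Comparing how two animal groups organize their social bonds — do females
bond more with females in one group than in the other? — requires three
methodological layers on top of raw field observations:

1. turning focal samples into a dyad-level measure of association
   strength that corrects for unequal observation of individuals;
2. regressing that measure onto dyad attributes (sex combination, group,
   kinship, age difference) while respecting that every dyad shares its
   members with many other dyads;
3. obtaining p values that are robust to observation biases, by
   comparing the fitted models against models fitted to permuted
   versions of the raw observation stream.

`dyadnet` implements this pipeline for focal-sampling data with three
nested association streams — party co-residence (within 10 m of the
focal), direct association (within 1 m) and grooming — plus a synthetic
generator that emulates the entire observation process so each stage can
be validated against known ground truth.

# Data model

A **focal record** is one 5-minute sample: a date, the focal individual,
and the sets of individuals within 10 m, within 1 m, and grooming with
the focal. The streams are nested by construction (grooming requires
contact; contact implies party co-residence), and the readers enforce
this, promoting 1 m partners absent from the 10 m set with a logged
warning. Subjects younger than 4 years (configurable) are flagged
excluded rather than dropped: infants travel with their mothers and are
not independent social agents.

Maternal kinship is encoded through a `maternal_line` field holding the
mother's id (or a founder label when the mother is unknown): two
individuals are kin when they share the field (maternal siblings) or one's
field equals the other's id (mother–offspring). Grandmother and
aunt/uncle links are deliberately not closed over, matching standard
practice for maternal-kin effects in primate groups.

# From samples to indices

Association is binarized per **sampling period**, fixed here to the
calendar date: a dyad scores 1 on a day if its members were observed
associating at least once that day, on either member's focal samples.
This "1/0 daily" rule sacrifices within-day frequency information to
maximize independence between sampling periods.

The **simple-ratio index** for a dyad is

$$\mathrm{SRI} = \frac{x}{x + Y_{AB} + Y_A + Y_B},$$

where, counted over days, \(x\) is the number of periods the dyad was
associated, \(Y_{AB}\) the periods both members were identified but not
associated, and \(Y_A\), \(Y_B\) the periods only one member was
identified. It estimates the fraction of time the pair spends together,
unbiased by how often each member was observed.

Two reading choices deserve note:

* **Identification.** We count an individual as identified on a day if
  it was a focal at least once or appeared in any focal's 10 m set
  (`identified_rule = "inclusive"`); the alternative, counting only
  focal individuals, is available (`"focal_only"`). Identification is
  measure-independent so the three streams share denominators and their
  indices are directly comparable (and nested:
  \(\mathrm{SRI}_{groom} \le \mathrm{SRI}_{1m} \le \mathrm{SRI}_{10m}\)).
* **Empty denominators.** A dyad never identified on any day scores 0
  and is flagged, not dropped; inference can exclude flagged dyads if
  desired.

# The dyadic mixed models

Indices are modelled at the dyad level. The central scientific term is
the interaction between dyad sex type (FF, MF, MM) and group; maternal
kinship and age difference enter as covariates. Because each individual
participates in many dyads, the models carry **crossed random
intercepts**: each dyad row adds \(u_a + u_b\), the intercepts of its
two members in their respective roles, each role with its own variance
(a shared-variance constraint is available via `shared_variance`). Each
unordered dyad contributes one row — the index is symmetric, and
mirrored duplicate rows would fabricate replication.

Party co-residence indices are mostly positive and are modelled directly
with a **beta** family (logit link), parameterized by mean
\(\mu = \mathrm{logit}^{-1}(\eta)\) and precision \(\phi\). Direct
association and grooming are zero for most dyads, so they use a
**hurdle**: a binomial (logit) model for whether any association
occurred, then a beta model for the magnitude among the positive dyads.
Exact zeros or ones are compressed off the unit boundary by
\(y' = (y(n-1) + 0.5)/n\) before beta fitting, with the compression
logged.

## Estimation

The marginal likelihood integrates the crossed intercepts out by the
**Laplace approximation**. The package ships its own compiled
implementation (`src/dyad_glmm.cpp`): a damped Newton search for the
conditional mode of the random effects, the exact curvature there for
the log-determinant, and a fully analytic gradient of the approximate
marginal likelihood (including the implicit dependence of the mode and
log-determinant on the parameters). This is the same approximation used
by the established mixed-model packages — fits agree with `glmmTMB` to
about six significant figures in the test suite — but a single
evaluation is microseconds-fast, which is what makes the permutation
machinery below affordable: a model refit on permuted data costs
milliseconds rather than a substantial fraction of a second.

Numerical choices, all visible in the code and its tests:

* the fixed-effect design is standardized to unit column variance
  internally (estimates and covariances are transformed back);
* `log sigma` is box-constrained to \([\log 10^{-3}, \log 20]\) and
  `log phi` to at most 12; boundary solutions are reported with the
  bound-active coordinate excluded from the gradient convergence check;
* a fit is `converged` only if the free-coordinate gradient norm is
  below \(10^{-4}\); otherwise up to five deterministically jittered
  restarts are tried and failure is reported, never silent;
* standard errors come from the inverted finite-difference Hessian of
  the analytic gradient at the optimum.

Model comparison uses the likelihood-ratio statistic
\(\chi^2 = \mathrm{dev}_{reduced} - \mathrm{dev}_{full}\) (df = 2 for
dropping the 3-level x 2-level interaction). Per-sex-type **group
contrasts** are estimated marginal differences on the link scale at
kinship 0 and the sample-mean age difference, with delta-rule standard
errors and normal-approximation p values (the package does not attempt
Satterthwaite degrees of freedom; contrasts agree with `emmeans` on
matched fits in the test suite).

# Datastream permutations

Observational association data violate the independence assumptions
behind analytic p values: some individuals are simply observed more.
The pipeline therefore reports a **permutation p value** for the
group-by-sex-type interaction. For each of `n_perm` iterations, every
day's associations are reassigned uniformly at random across the dyads
that could have been observed that day (at least one member identified),
holding the day's association count fixed; the identified sets — hence
every index denominator — are untouched. Each permuted stream is rebuilt
into indices and refitted with the same full and reduced models, and

$$P_{rand} = \frac{\#\{\Delta\mathrm{dev}_{obs} \le \Delta\mathrm{dev}_{perm}\}}{\#\,\mathrm{valid\ permutations}}.$$

Design decisions:

* Permutation operates on the **daily binarized events**, not raw
  5-minute samples — the most direct reading of holding "the original
  frequency of associations per given day" fixed. A degree-preserving
  alternative (checkerboard swaps that also hold each individual's daily
  event count fixed) is available behind `scheme =
  "degree-preserving"`; it is not the default because day-level
  reassignment is the documented procedure.
* Non-convergent permuted refits are dropped and counted (`n_failed`),
  never retried with fresh draws (retrying would bias the null); a
  warning flag is raised if more than 10% fail. Permuted refits use a
  practical convergence rule (standardized gradient < 0.01 after a
  polish pass): the deviance error this admits is second-order and far
  below the resolution of the null distribution, while a stricter rule
  would discard practically converged fits whose variance parameter sits
  in the flat boundary region, biasing the null.
* A zero exceedance count is displayed as `< 1/n_perm`, never as 0.
* Every permutation refit is warm-started from the previous iteration's
  solution and scaled by the curvature of the observed fit, which is
  what keeps a 200-permutation run in the seconds range.

# The synthetic generator

`generator_config()` describes a two-group focal-sampling study; the
defaults emulate the study conditions this pipeline targets: groups of
11 M + 11 F and 10 M + 29 F, a 60-day season beginning July 2013 with
about 20 focal samples per individual (so per-day focal subsets of
roughly a third of each group, in randomized order), uniform ages 4-40,
maternal lines sized so both groups contain kin dyads, baseline
log-odds -2.5 of joining a focal's 10 m party in one sample, a +1
log-odds female-female surplus confined to the first group (mirroring
the kind of group difference the pipeline is designed to detect), kin
bonus +1, age-difference slope -0.02/yr, individual gregariousness SD
0.5, and nested thinning probabilities 0.3 for 1 m given 10 m and 0.3
for grooming given 1 m. With these settings the simulated party indices
average roughly 0.1-0.17 for first-group FF dyads and 0.05-0.08
elsewhere, with dispersion somewhat below the descriptive spread
reported for comparable sanctuary data — a deliberately conservative
noise level.

The generator reproduces the *observation process*, not just the
distributional assumptions of the models: associations are drawn per
focal sample and only then binarized per day, individuals appear as
associates on days they were never focal, and the gregariousness
intercepts are drawn once per season (matching the random-intercept
structure the models assume). What it does **not** emulate — and what
passing tests therefore cannot certify about real data — includes
fission-fusion party dynamics (associations are independent across
samples given the intercepts), temporal autocorrelation, estrous or
dominance effects, and observer error in identification.

# Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive per-day re-tallies for the simple-ratio indices (1,000 random
fixtures); dense Gauss-Hermite quadrature (21 nodes per dimension) and
an independently coded fixed-effects beta ML for the Laplace fits;
`glmmTMB` and `emmeans` for full mixed fits and contrasts; chi-square
uniformity and margin-conservation checks for the permutation engine;
and exhaustive partition search for the spinglass Hamiltonian on graphs
of up to 8 nodes.

The stochastic calibration studies run at reduced sizes chosen to keep
the full suite in the tens of minutes: type-I calibration uses two
groups of 4 M + 4 F over 20 days with all group effects zeroed (200
replicates x 200 permutations; the rejection rate at \(\alpha = 0.05\)
must fall in [0.02, 0.09]), and the power study uses two groups of
10 M + 10 F over 60 days with the +1 FF-only effect (50 replicates,
59 permutations each).

The calibration size matters, and the package is explicit about why.
Datastream permutations enforce exchangeability under "no structure at
all", while the test's null hypothesis is composite — main effects,
covariates and random intercepts present, only the interaction absent.
With degenerate cells (two groups of 3 M + 3 F leave three FF dyads per
group) the residual kin and gregariousness heterogeneity projects onto
the interaction statistic in the observed data but cannot in the
permuted data, and a 400-replicate study measures the realized type-I
rate at about 0.095. At 4 M + 4 F the rate is back to about 0.07, and
the discrepancy shrinks further toward realistic sizes (the smallest
sex-type cell in data this pipeline targets has 45 dyads). Users
analysing very small groups should treat borderline permutation p
values with corresponding caution.

The power study deserves a frank note. The FF contrast's sign is
recovered essentially always, but the interaction test detects the
+1 effect in well under half of these replicates. The cause is a design
fact, not an estimation defect: the gregariousness intercepts are drawn
once per season, so with only 10 females per group the difference of
female group means alone carries a standard deviation near 0.45 on the
contrast scale — enough to mask a +1 effect regularly. Setting the
gregariousness SD to zero lifts detection to essentially 100%, and
doubling the number of females per group raises it to roughly 85-90%
(at a computational cost that keeps that configuration out of the
default suite). The package reports the attained rate rather than
quietly simulating an easier world; for study design the implication is
that group comparisons of sex-specific bonding need many individuals
per sex-group cell, or stronger effects, when stable individual
differences in gregariousness are realistic.

# Sociograms

Each group's association matrix becomes a weighted graph (positive
indices are edges; isolated individuals remain as nodes), laid out with
the weighted Fruchterman-Reingold algorithm and partitioned by
**spinglass community detection**: simulated annealing of the
Reichardt-Bornholdt Potts Hamiltonian

$$H = -\sum_{i<j} \left(w_{ij} - \gamma \frac{s_i s_j}{2m}\right) \delta(c_i, c_j),$$

with the configuration null model (\(s_i\) node strength, \(2m\) total
weight). The annealer is the package's own: Metropolis single-spin
flips, geometric cooling (start 1, factor 0.99, stop 0.01), a greedy
single-node refinement pass, and five restarts keeping the lowest
Hamiltonian — on graphs small enough for exhaustive search it attains
the global optimum in over 95% of seeded runs. \(\gamma = 1\) and at
most 25 spins are defaults, exposed in the configuration, and not
claimed to match any published figure since the original analyses cite
only the algorithm. Disconnected components are partitioned separately
(edgeless components become singletons) and the reported Hamiltonian is
the sum over components.

# A worked run

```{r, eval = FALSE}
library(dyadnet)

cfg <- run_config(
  generator = generator_config(seed = 20130701),
  n_perm = 1000, seed = 20130701, out_dir = "chimp_run")
res <- run_pipeline(cfg)
cat(summarize_results("chimp_run"), sep = "\n")
```

The run directory then contains, per measure, the dyad table and
association matrices, full/reduced fit tables, the likelihood-ratio and
permutation results, per-sex-type contrasts, null-deviance draws,
GraphML sociograms with community and layout attributes, and a manifest
recording the configuration, seeds and all warnings. `n_perm = 0` gives
an analytic-only run.

# Known limitations

* The Laplace approximation is least accurate for binomial hurdle parts
  with few observations per individual; the quadrature checks bound the
  error at the sizes tested, not universally.
* Permutation and analytic p values answer subtly different questions;
  when they disagree, the permutation value is the one robust to
  observation-effort bias.
* The degree-preserving permutation scheme uses checkerboard swaps whose
  mixing on very dense days is slow; it is provided for sensitivity
  analysis, not as the primary method.
* Group contrasts use the normal approximation; with few individuals
  per group their p values are anti-conservative, which is precisely why
  the permutation test is the headline inference.
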