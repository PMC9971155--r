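# dyadnet

Dyadic association networks from focal-sampling data: simple-ratio
indices, hurdle beta/binomial mixed models with crossed member
intercepts, datastream (prenetwork) permutation inference, and
sociograms with spinglass communities.

## What problem this solves

Behavioural ecologists comparing the social structure of two animal
groups — for example, whether female–female bonds are stronger in one
chimpanzee group than its neighbour — start from focal samples: five
minutes on one individual, recording everyone within 10 m, within 1 m,
and grooming. Getting from there to a defensible group comparison
requires (i) association indices that correct for unequal observation of
individuals, (ii) dyad-level regression models that respect that every
individual appears in many dyads, and (iii) p values robust to
observation biases. `dyadnet` implements that pipeline end to end,
together with a synthetic-data generator that emulates the whole
observation process so every stage is testable against ground truth.

The core quantities:

* **Simple-ratio index** per dyad and stream (party co-residence at
  10 m, direct association at 1 m, grooming), computed on daily 1/0
  sampling:

  `SRI = x / (x + Y_AB + Y_A + Y_B)`

  with `x` the days the pair was associated, `Y_AB` the days both were
  identified but apart, and `Y_A`, `Y_B` the days only one was
  identified.

* **Dyadic GLMMs**: `SRI ~ sex_type * group + kinship + age_diff +
  (1 | member_A) + (1 | member_B)` with a beta family (logit link) for
  party co-residence and a binomial-then-beta hurdle for the sparser 1 m
  and grooming streams. The Laplace-approximated likelihood and its
  analytic gradient are compiled in the package (they match `glmmTMB`
  to ~6 significant figures but evaluate orders of magnitude faster,
  which makes the permutation test practical).

* **Datastream permutations**: each day's associations are reassigned
  uniformly across the dyads observable that day, keeping the daily
  association count and all index denominators fixed; full and reduced
  models are refitted to every permuted stream and
  `P_rand = #(obs Δdev ≤ perm Δdev) / n_perm` tests the
  group-by-sex-type interaction.

* **Sociograms**: weighted Fruchterman–Reingold layouts and communities
  from simulated annealing of the Reichardt–Bornholdt Potts Hamiltonian
  (configuration null model), exported as GraphML/edge lists.

## A worked example

```r
library(dyadnet)

# a synthetic two-group study: 11M+11F and 10M+29F, 60 days,
# ~20 focal samples per individual, +1 logit female-female surplus in
# group 1
sim <- simulate_study(generator_config(seed = 20130701))
dt  <- build_dyad_table(sim$records, sim$roster)
dyad_counts(enumerate_dyads(active_roster(sim$roster, "g1")))

dt$y <- dt$sri_party
full <- fit_dyad_glmm(dt, model_spec("y", family = "beta"))
red  <- fit_dyad_glmm(dt, model_spec("y", family = "beta",
          fixed = ~ sex_type + group_id + kin + age_diff))
likelihood_ratio(full, red)
group_contrasts(full)

perm <- run_permutation_test(sim$records, sim$roster,
                             "party10m", "sri", n_perm = 200, seed = 7)
perm
```

Output from this exact script:

```
   FF    MF    MM total
   55   121    55   231

LRT: chi2 = 6.957, df = 2, p = 0.03085

  sex_type estimate        se statistic            p
1       FF 1.092473 0.2539119  4.302568 1.688295e-05
2       MF 0.281548 0.2676276  1.052014 2.927931e-01
3       MM 0.358660 0.3336797  1.074863 2.824361e-01

<permutation_result> party10m / sri (uniform-day)
  observed delta-deviance = 6.957, n_perm = 200 (8 failed)
  P_rand = 0.0625
```

Read: the female–female group contrast recovers the injected +1 logit
surplus almost exactly (+1.09, `z = 4.3`: FF party association is
stronger in group 1), with no material MF or MM difference. The 2-df
omnibus interaction test is far more conservative than the targeted
contrast — analytically marginal (`chi2 = 6.96`, `p = 0.031`) and not
significant under the stricter datastream permutation null
(`P_rand = 0.0625`) — a deliberate illustration that omnibus
permutation tests of sex-specific bonding need large per-sex samples,
discussed at length in the methods vignette.

The full pipeline (all three measures, hurdle parts, contrasts,
sociograms, manifest) runs as:

```r
run_pipeline(run_config(generator = generator_config(seed = 1),
                        n_perm = 1000, out_dir = "run1"))
cat(summarize_results("run1"), sep = "\n")
```

A thin CLI over the same functions lives at `inst/cli/dyadnet.R`
(subcommands `simulate`, `analyze`, `permute`, `sociogram`, `report`).

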