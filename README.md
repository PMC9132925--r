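# seedburial

Analysis of multi-year seed-burial experiments on soil seed banks: how fast
buried seeds lose viability and germinability, whether decline differs
between groups of species (e.g. invasive vs naturalized aliens), and how
long each species' seed bank persists — with phylogeny accounted for.

The package is written for experiments of the classic design: replicate
nylon bags of seeds buried per species, one triplet of bags exhumed per
year, every seed classified in the laboratory as germinated (with or
without gibberellic-acid stimulation), viable-but-non-germinated, or dead.

## What it computes

**Derived statistics and classification.** Per bag: seed viability
(viable/buried), germinability (germinated/viable exhumed), germination
(spontaneous/buried), all as percentages with full count validation. Per
species: transient / short-term persistent / long-term persistent seed-bank
class from the presence of viable seeds at 1.5 yr and after 5.5 yr.

**Phylogenetic logistic mixed models.** Per-bag binomial responses on the
logit scale,

&nbsp;&nbsp;&nbsp;&nbsp;η = Xβ + u_phy + u_species + u_triplet + u_rowseq + u_rownum + e,

with u_phy ~ N(0, V_phy·C) for the Brownian correlation matrix C of a
user-supplied Newick tree (species missing from the tree are grafted onto
their genus), iid intercepts for the design terms, and a fixed-variance
per-bag overdispersion term. Estimation is bespoke compiled MCMC
(Metropolis-within-Gibbs with exact conjugate variance updates under
parameter-expanded half-Cauchy priors); outputs are posterior summaries
with CI-based significance, Pagel's λ = V_phy/(V_phy + ΣV_g + V_e + π²/3)
per draw (denominator conventions configurable), and population-level
decline curves with credible bands over 0–10 years.

**Ellis–Roberts viability equation.** Per species, probit(ν) = K_i − p/σ by
least squares (probit or percent scale; fixed or free intercept), P50 =
σ·K_i in closed form with non-declining species flagged as +Inf, and
median/range P50 summaries for invasive vs naturalized groups.

**Synthetic experiments.** A generator with the real design as defaults
(59 species = 21 invasive + 38 naturalized, 3 bags × 7 years × 100 seeds,
pure-birth tree, phylogenetically correlated species effects with known
λ, group-level slope differences, bag-level binomial noise) and complete
ground truth, plus `run_recover()` to score slope, λ and P50 recovery.

## Worked example

```r
library(seedburial)

sim  <- simulate_burial_experiment(sim_config(rng_seed = 7))
corr <- phylo_correlation(sim$tree)
m    <- build_model(sim$records, sim$traits, corr,
                    model_spec("viability", "status"))
post <- sample_posterior(m, chain_config(seed = 3))   # desk-scale: 20k steps
summarize_effects(post)
```

```
                    term posterior_mean posterior_mode ci_lower ci_upper significant
1            (Intercept)        1.73057          1.974    0.900    2.449        TRUE
2                   time       -0.88146         -0.877   -0.943   -0.820        TRUE
3      statusnaturalized        0.00706         -0.108   -0.604    0.580       FALSE
4 time:statusnaturalized        0.30811          0.310    0.236    0.383        TRUE
```

Viability declines ~0.88 logits/yr in the invasive reference group; the
naturalized group declines significantly more slowly (interaction +0.31
logits/yr, CI excluding 0 — the generator's true difference is +0.25), while
the groups start at the same level (status main effect not significant,
matching the generator's equal intercepts).

```r
pagel_lambda(post)                       # full latent-scale denominator
#> lambda: mean 0.300, 95% CI [0.171, 0.450]
pagel_lambda(post, include_link_variance = FALSE, include_residual = FALSE,
             denom_terms = "species_identity")   # species-level share
#> lambda: mean 0.788, CI [0.562, 0.928]         # generator truth: 0.8

predict_curve(post, m, times = c(0, 4, 8))
#>         group time fit_pct lo_pct hi_pct
#> 1    invasive    0  83.965 71.097 92.049
#> 2    invasive    4  15.093  7.076 24.221
#> 3    invasive    8   0.536  0.202  0.964
#> 4 naturalized    0  84.591 74.260 90.330
#> 5 naturalized    4  36.743 23.646 47.879
#> 6 naturalized    8   5.682  3.020  9.027

vf <- fit_viability_all(fate_summary(sim$records), sim$traits)
group_p50(vf, sim$traits)
#>         group central range_low range_high n_finite n_infinite
#> 1    invasive   3.261     2.892      7.936       21          0
#> 2 naturalized   4.259     2.917     13.992       38          0
```

Invasive species reach 50% viability after ~3.3 years (median across
species), naturalized after ~4.3 — the generator's sharper invasive
decline, recovered from the bag counts.

File-based runs use `run_simulate()` / `run_analyze()` / `run_recover()`,
or the CLI dispatcher:

```sh
Rscript -e 'seedburial::sb_cli()' simulate --out data/sim --seed 4
Rscript -e 'seedburial::sb_cli()' analyze --records data/sim/records.tsv \
    --traits data/sim/traits.tsv --tree data/sim/tree.nwk --out results/
```

Production chains (1,000,000 steps, 10,000 burn-in, thinning 100; 9,900
retained draws) are `chain_config(1e6, 1e4, 100)`.

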