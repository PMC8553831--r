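# evofoodweb

Do disturbed communities breed generalists? `evofoodweb` is an
eco-evolutionary food-web simulator built to ask that question the way
theoretical community ecologists do: species live on a continuous body-size
axis, their feeding interactions follow Gaussian kernels, their biomasses
follow an allometric bioenergetic consumer-resource model, and evolution
proceeds by introducing new species — mutants similar to abundant residents,
or invaders whose trait novelty is controlled by a *strangeness* parameter
`z`. Sweeping `z` across simulations turns invasion into a disturbance dial,
and the package's metrics layer measures what that disturbance does to the
evolution of diet breadth.

## The model in brief

Each species carries three fixed traits: body mass `m`, feeding center `f`
and feeding range `s` (the SD of its feeding kernel in log10 mass units).
The attack rate of consumer `i` on a resource of mass `m_j` is

    a_ij = m_i^0.75 * 1/(s_i sqrt(2*pi)) * exp(-(log10 f_i - log10 m_j)^2 / (2 s_i^2))

so specialists (small `s`) hit harder on fewer prey — an explicit
efficiency/generalism trade-off. Consumer biomass follows

    dB_i/dt = sum_j e g_ij B_i B_j  -  sum_j g_ji B_j B_i
              -  sum_{j!=i} c_ij B_i B_j  -  x_i B_i

with a type-II functional response `g`, metabolic loss `x_i = 0.3 m^-0.25`,
and interference competition `c_ij = c0 * I_ij / I_ii` given by the overlap
integral of the two feeding kernels. The basal resource obeys
`dB0/dt = n0 - sum_j g_j0 B_j B0 - l B0` (consumer-free equilibrium
`n0/l = 2`). Every 100 time units the community is culled at the extinction
threshold `1e-8` and one new species is introduced at that same biomass:
an invader with probability `p = 0.2` (traits Gaussian around a random
resident with SD `z`), a mutant otherwise (SD 0.1, parent chosen by
individual density `B/m`). See the methods vignette
(`vignettes/invader-strangeness.Rmd`) for every equation, default and
numerical decision, including why handling time defaults to
`h = 0.4 m^-0.75`.

## A worked example

One scaled-down run (horizon 2e5 instead of the production 25e6) with
moderately strange invaders:

```r
library(evofoodweb)
p <- fw_params(horizon = 2e5, z_invader = 2,
               community_interval = 500, turnover_interval = 1000)
rec <- run_simulation(p, seed = 1)
rec
#> <fw_record> z=2 seed=1 status=completed  species ever=2001  extant at horizon=3
t(round(as.matrix(sim_metrics(rec)[, -(1:3)]), 4))
#> sd_resource                0.5091
#> sd_community               4.2984
#> mean_turnover              0.1559
#> mean_mutant_s              0.5352
#> median_mutant_s            0.4616
#> mean_realized_range        0.4240
#> lifespan_slope            -0.6477
#> mean_lifespan_specialist 358.3333
#> mean_lifespan_generalist 258.6728
```

Reading the numbers: 2001 species were introduced (the ancestor plus one
every 100 time units) and 3 were alive at the horizon — assembly at this
scale is a steady churn of failed establishments. The basal resource
biomass fluctuated with SD 0.51 around its mean and the community biomass
with SD 4.3 (the disturbance metrics); 15.6% of the extant set turned over
per 1000-step window (Jaccard dissimilarity). Viable mutants carried a mean
feeding range of 0.54 (floor 0.3), consumers attacked 42% of their
community above 10% of their maximal attack rate, and the lifespan slope
of −0.65 says specialists still outlived generalists in this particular
run — the quantity whose *rise* with `z` is the study's persistence signal.

A strangeness sweep and its trend summary:

```r
recs <- run_sweep(seq(0.5, 5, length.out = 10), replicates = 3,
                  params = p, seed = 1)
trend_report(metrics_table(recs))
```

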