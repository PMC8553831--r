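---
title: "Eco-evolutionary food-web assembly and the invader-strangeness experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary food-web assembly and the invader-strangeness experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evofoodweb)
```

## The model

`evofoodweb` simulates the assembly of food webs on a continuous body-size
axis. Every species carries three heritable traits, fixed for its lifetime:

* body mass $m_i \ge m_0$, its position on the size axis;
* feeding center $f_i > 0$, the prey body mass it attacks best;
* feeding range $s_i \ge 0.3$, the width (SD, in $\log_{10}$ mass units) of
  its Gaussian feeding kernel.

The kernel is a normal density over $\log_{10}$ prey mass,
$$N_{ij} = \frac{1}{s_i\sqrt{2\pi}}
  \exp\!\left[-\frac{(\log_{10} f_i - \log_{10} m_j)^2}{2 s_i^2}\right],$$
and the mass-specific attack rate is $a_{ij} = m_i^{0.75} N_{ij}$. Because
$N$ is normalised, a narrow kernel buys a high peak: specialists are more
efficient on their focal prey, generalists spread a fixed capture budget
over a wider range. This efficiency/generalism trade-off is the selective
force the experiment probes. Networks are technically fully connected —
kernel tails are never truncated in the dynamics; only the realized-range
*metric* applies a threshold.

Biomass densities follow an allometric bioenergetic consumer-resource
model. With a type-II functional response
$$g_{ij} = \frac{1}{m_i}\,
  \frac{a_{ij}}{1 + \sum_{k \in \mathrm{prey}} h_i a_{ik} B_k},$$
consumer biomass obeys
$$\frac{dB_i}{dt} = \sum_{j \in \mathrm{res}} e\, g_{ij} B_i B_j
  - \sum_{j \in \mathrm{cons}} g_{ji} B_j B_i
  - \sum_{j \ne i} c_{ij} B_i B_j - x_i B_i,$$
and the non-evolving basal resource (body mass $m_0 = 1$) obeys
$dB_0/dt = n_0 - \sum_j g_{j0} B_j B_0 - l B_0$, so its consumer-free
equilibrium is $n_0/l = 2$. Interference competition between consumers is
proportional to the overlap of their feeding kernels,
$$c_{ij} = c_0 \frac{I_{ij}}{I_{ii}}, \qquad
  I_{ij} = \int N_{ik} N_{jk}\, d(\log_{10} m_k)
  = \frac{\exp\!\left[-\frac{(\log_{10} f_i - \log_{10} f_j)^2}
      {2(s_i^2+s_j^2)}\right]}{\sqrt{2\pi (s_i^2+s_j^2)}},$$
with no intraspecific term ($i \ne j$). The closed form of the overlap
integral (a Gaussian product integral) is verified against adaptive
quadrature in the test suite.

## Parameters

All constants live in one `fw_params()` object:

| parameter | default | meaning |
|---|---|---|
| `n0`, `l` | 1, 0.5 | resource inflow (sets the time scale) and outflow |
| `m0` | 1 | resource body mass; body-mass floor |
| `e` | 0.85 | assimilation efficiency |
| `c0` | 0.05 | interference-competition strength |
| `h_coeff`, `h_exp` | 0.4, −0.75 | handling time $h_i = 0.4\, m_i^{h_\mathrm{exp}}$ |
| `x_coeff`, `x_exp` | 0.3, −0.25 | metabolic loss $x_i = 0.3\, m_i^{-0.25}$ |
| `a_exp` | 0.75 | attack-rate allometry |
| `p` | 0.2 | invasion probability per introduction |
| `z_mutant` | 0.1 | mutant trait SD |
| `z_invader` | sweep variable | invader strangeness |
| `eps` | $10^{-8}$ | extinction threshold = introduction biomass |
| `s_floor` | 0.3 | minimum feeding range |
| `intro_interval` | 100 | time between introductions |

### Why handling time scales as $m^{-0.75}$

The ratio of maximum mass-specific ingestion to metabolism under the
functional response above is $e/(m_i h_i x_i)$. With
$h_i = 0.4\,m_i^{-0.75}$ this ratio is mass-independent,
$0.85/(0.4 \cdot 0.3) \approx 7.1$ — the classic bioenergetic
consumption-to-metabolism ratio ($y \approx 8$ scaled by assimilation
efficiency) that this model family inherits. An exponent of $-0.25$
instead makes the ratio decay as $m^{-0.5}$, so no consumer heavier than
$m \approx 50$ could ever gain more than it respires — the $m = 100$
ancestor would starve at saturated resources and assembly could never
start. We therefore default to the mass-independent scaling and expose the
exponent as an ordinary parameter for sensitivity analysis.

## Assembly rules

A run starts at $t = 0$ from the basal resource at $B_0 = 2$ and a single
ancestor ($m=100$, $f=1$, $s=0.4$) at biomass $\varepsilon = 10^{-8}$.
Every 100 time units, in this order:

1. **integrate** the ODE system over the elapsed interval;
2. **cull**: every species with $B_i < \varepsilon$ (strictly below — a
   population sitting exactly at the introduction biomass survives) is
   removed and its death time recorded;
3. **introduce** one new species: an invader with probability $p$, a
   mutant otherwise. Mutant parents are drawn with probability
   proportional to individual density $B_i/m_i$; invader parents
   uniformly. Child traits are Gaussian around the parent with SD
   `z_mutant` (mutants) or `z_invader` (invaders); the child starts at
   biomass $\varepsilon$, deducted from the parent for mutants and
   injected from outside for invaders;
4. **record** any outputs due at that time.

Trait mutation operates on the $\log_{10}$ scale for $m$ and $f$ and on
the linear scale for $s$, all with the same SD: the kernel and the overlap
integral are defined in $\log_{10}$ mass space, and $s$ is itself a width
in those units. Values below the floors are redrawn rather than clamped,
to avoid probability atoms at the boundary; both choices are switchable
(`trait_scale`, `floor_mode`). There is no upper bound on any trait, and
$f$ is not constrained relative to $m$. A parent pushed below
$\varepsilon$ by the mutant deduction is culled at the *next* boundary
check, consistent with culling being a boundary operation.

A consumer's own biomass is included among its potential prey (the kernel
tail at its own mass), since the model states no exclusion rule and the
realized-range metric explicitly includes the focal consumer; the
`cannibalism` switch disables it.

## Numerical choices

Integration uses an embedded Runge–Kutta–Fehlberg 4(5) scheme (compiled)
with adaptive step control, `rtol = 1e-6` and `atol = 1e-12` by default.
The attack, handling, metabolism and competition coefficients are fixed
while the species set is fixed, so they are precomputed once per
inter-introduction segment. Negative excursions (necessarily below the
absolute tolerance) are clamped to zero after each accepted step. The
compiled path is cross-checked in the tests against `deSolve::lsoda`
driving the pure-R right-hand side, against the analytic consumer-free
solution, and against a root-finder solution of the two-node (resource +
ancestor) equilibrium.

Step-size underflow or non-finite states raise a simulation failure;
`run_simulation()` then restarts the whole run with a derived fresh seed
(as does a community-level extinction), up to `max_restarts` times, and
reports the restart count. Determinism holds per `(params, seed)`: one R
RNG stream drives kind choice, parent selection and trait draws in
sequence. (Sub-streams per component were considered and dropped — a
single stream keeps records bit-reproducible with base R tooling, and the
components are unit-tested in isolation with their own seeds.)

## Metrics

* `sd_resource` / `sd_community`: sample SD over time of basal-resource
  and summed community biomass (species introduced at a recording time are
  excluded from that record).
* `mean_turnover`: Jaccard dissimilarity
  $(|A \setminus B| + |B \setminus A|)/|A \cup B|$ between consecutive
  composition snapshots. The source description ("percentage change in
  composition") admits several formulas; Jaccard is bounded and symmetric.
  The alternative $(\mathrm{gained}+\mathrm{lost})/|A|$ sits behind
  `turnover_method = "relative"`.
* `mutant_range_summary`: mean/median feeding range of *viable mutants*
  (survived ≥ 100 time units, born after burn-in, mutants only — invader
  traits are directly manipulated by the experiment and would bias the
  metric).
* `realized_range`: fraction of the community (basal resource + all
  extant species, including the focal consumer) attacked at
  ≥ 10% of the consumer's maximum attack rate; the threshold locus is
  $|\log_{10} f - \log_{10} m_j| = s\sqrt{2\ln 10}$, used as an
  independent oracle in the tests.
* `lifespan_slope`: gamma log-link GLM coefficient of uncensored lifespan
  on $\log_{10} s$ within one run. "Log-scaled data" could also mean
  transforming the response; that reading sits behind `log_response`.
* `binned_persistence`: mean uncensored lifespan of specialists
  ($s \le 0.32$) and generalists ($s \ge 0.39$); intermediates excluded.

Species alive at the horizon are flagged censored and excluded from
lifespan statistics. All record-level metrics apply a burn-in (default
50,000 time units): at production recording intervals the first community
sample falls at $t = 50{,}000$ anyway, and species data from before that
time are discarded as assembly transient, so the burn-in simply makes the
desk-scale measurement design match the production one.

The trend layer replaces generalized additive models with a gamma GLM
slope plus a Spearman rank trend test (`spearman_trend`,
`trend_report`): the GAMs in the source analysis only certify monotone
trends with a non-linear dip, and smoothing-parameter replication is out
of scope. The generalist/specialist response difference is tested with a
Poisson log-link GLM containing a type × strangeness interaction
(`interaction_persistence_model`).

## Scales, and what the desk-scale tests do and do not show

The production design is 25 million time units per run (250,000
introductions), a 50-value strangeness grid on $[0.1, 5]$ with 100
replicate seed sets, and recording intervals of 100 (species),
10,000 (composition) and 50,000 (community biomass). The package runs
that configuration unmodified, but the bundled tests and the acceptance
script use a scaled design: horizon $2 \times 10^5$, 10 strangeness
values on $[0.5, 5]$, 3 replicates, with recording intervals 500 and
1,000 chosen to keep roughly the production number of recorded points per
run. A single scaled run takes a few seconds; the full scaled sweep a few
minutes.

Scaling down changes what is observable. Two findings are robust at desk
scale: the *lifespan slope* rises with invader strangeness (generalists
gain relative persistence), and the *viable-mutant feeding range* drifts
upward with strangeness once runs are long enough. The *disturbance*
metrics (biomass SDs, turnover) are a different matter: in the full-scale
study they are driven by strange invaders disrupting diverse,
multi-trophic webs through cascading extinctions. With Gaussian trait
steps of SD 0.1 per introduction, building such webs takes far longer
than $2\times 10^5$ time units — scaled runs hold 2–3 coexisting species,
and their biomass variability is dominated by dominance-switching events
that are, if anything, *more* frequent when invaders land close to
residents (low strangeness). Passing the structural and dynamical tests
therefore validates the mechanics of the simulator, not the claim that
the disturbance gradient is visible at this horizon; reproducing that
gradient requires production-scale runs.

The generator emulates the study conditions exactly (same equations,
constants, introduction scheme and recording structure). It does not
emulate spatial structure, adaptive foraging, environmental stochasticity
or temperature dependence, and traits are fixed within a species'
lifetime.

## A minimal session

```{r example, eval = FALSE}
p <- fw_params(horizon = 2e5, z_invader = 2,
               community_interval = 500, turnover_interval = 1000)
rec <- run_simulation(p, seed = 1)
sim_metrics(rec)

recs <- run_sweep(seq(0.5, 5, length.out = 10), replicates = 3,
                  params = p, seed = 1)
trend_report(metrics_table(recs))
```

## Known limitations

* Desk-scale horizons cannot reproduce the disturbance-metric gradient
  (see above); the acceptance suite reports this honestly rather than
  relaxing the check.
* The quasi-neutral early phase (a sub-threshold ancestor chain before
  the first establishment) makes run-to-run variability large at short
  horizons; restart-on-collapse handles full extinctions.
* Interference competition has no intraspecific term, so a monodominant
  resident is only limited through resource saturation; this is a model
  property, not an implementation choice.
* Lifespans are bounded below by the introduction interval (a species is
  only ever removed at a boundary), which discretises the lifespan
  distribution at small values.
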