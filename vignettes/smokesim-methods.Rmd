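---
title: "Modelling adolescent cigarette and e-cigarette choice under social influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent cigarette and e-cigarette choice under social influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesim)
```

## The model

`smokesim` is an agent-based microsimulation of how US high-school
adolescents take up, continue, combine and quit conventional cigarettes
(CC) and e-cigarettes (EC). A population of 3000 agents sits on a static
scale-free friendship network. Time advances in decision cycles of 30
days — the "current use" window of the National Youth Tobacco Survey
(NYTS) instrument — so one calendar year is 12 cycles and the default
2011–2014 horizon is 36 cycles.

At every cycle each agent chooses one of four mutually exclusive states:
non-use, CC only, EC only, or dual use. The choice is by random utility.
Non-use is the reference alternative with utility 0. For each product
$X \in \{CC, EC\}$ the component utility is

$$
V_X = \mu_X + \eta\,[\text{currently uses } X] + \phi f_X +
      \left(w_{peer}\,p_X + w_{soc}\,P_X\right)\,(1 + o_X)
      \;+\; [X{=}CC]\;\chi \left(w_{peer}\,p_{EC} + w_{soc}\,P_{EC}\right)
$$

where $p_X$ is prevalence among the agent's (at most four) close friends,
$P_X$ is population prevalence (dual users count in both products),
$f_X \in [0,1]$ is the agent's 30-day use frequency, and $o_X \in [0,1]$ is
the agent's current *openness* to the product. The four alternatives score
$U(\text{NONE}) = 0$, $U(\text{CC}) = V_{CC}$, $U(\text{EC}) = V_{EC}$ and
$U(\text{DUAL}) = V_{CC} + V_{EC} - \kappa$. Each agent picks the argmax of
$U_s + \tau \varepsilon_s$ with i.i.d. standard Gumbel shocks
$\varepsilon_s$, i.e. a multinomial logit with choice probabilities
$\mathrm{softmax}(U/\tau)$; with $\tau = 0$ the choice is the deterministic
argmax with ties broken in the fixed order NONE < CC only < EC only < dual.
The logit form has a closed-form oracle, which the test suite exploits
(Monte-Carlo choice frequencies against the softmax at $10^5$–$10^6$
draws).

Openness responds to perceived exposure
$E_X = \alpha p_X + (1-\alpha) P_X$:

$$
o_{EC} = \mathrm{clamp}_{[0,1]}\!\left(b_{EC} + \theta_{EC} + \gamma E_{EC}\right),
\qquad
o_{CC} = \mathrm{clamp}_{[0,1]}\!\left(b_{CC} + \theta_{CC} + \gamma E_{CC} + \chi E_{EC}\right)
$$

with $b$ the agent's fixed base openness, $\theta$ exogenous scenario
offsets, and $\chi$ the *crossover*: a one-way coupling by which EC
exposure raises openness toward CC (and, through the direct term above,
the social utility of CC). $\chi = 0$ makes the two products' social
influences independent. The coupling is one-way by default because the
asymmetric direction — EC popularity pulling adolescents toward combustible
smoking — is the mechanism of interest; a `crossoverBidirectional` switch
applies the same coupling CC→EC for sensitivity analyses. Both crossover
channels (openness and direct utility) share the single $\chi$ and can be
disabled individually (`crossoverOpenness`, `crossoverUtility`).

Updating is synchronous: all agents observe the same lagged environment,
choose at once, and the revised prevalences feed the next cycle. Use
frequency ramps by $0.25$ per cycle of continued use (capped at 1) and
resets to 0 on quitting, a simple bounded habituation that makes recent
adopters easier to dislodge than established users.

## Parameters

| Field | Meaning | Unit | Default |
|---|---|---|---|
| `muCC`, `muEC` | intrinsic taste | utility | −9.95, −6.63 |
| `eta` | habituation bonus for a currently used product | utility | 9.06 |
| `phi` | gain per unit 30-day use frequency | utility | 3.09 |
| `wPeer` | weight on close-peer prevalence | utility / prevalence | 4.18 |
| `wSoc` | weight on population prevalence | utility / prevalence | 4.15 |
| `alphaPeerMix` | peer share of perceived exposure | – | 0.5 |
| `gammaOpen` | openness response to exposure | – | 0.3 |
| `thetaCC`, `thetaEC` | scenario openness offsets | – | 0 |
| `crossover` | EC→CC coupling $\chi$ | – | 0 |
| `kappaDual` | cost of the dual alternative | utility | 0 |
| `tasteScale` | Gumbel shock scale $\tau$ | utility | 1 |

The defaults are the calibrated baseline: with them, the model initialised
from the 2011 NYTS marginals tracks the observed 2011–2014 prevalence
trend, with 6 of 8 year×product means inside the published 95% confidence
intervals (the 2012 and 2013 EC points are bridged by an S-shaped curve
that runs above the early observations, in exchange for reaching the 2014
level). On the utility scale only differences matter; the normalisation
$U(\text{NONE}) = 0$ identifies the levels, and quitting costs are not
modelled separately — the habituation term $\eta$ plays that role.

Scenario knobs $\theta$ and $\chi$ are intended for $[0, 0.3]$; values
outside warn rather than error. $\theta$ is additive on the openness scale
*before* clamping, so agents already at the ceiling do not respond — a
saturating, not linear, intervention.

## The synthetic population

No survey microdata ships with the package. `generate_profiles()` draws
agents from `PopulationMarginals`, whose defaults emulate the 2011 NYTS
high-school profile:

* **Smoking state**: NONE/CC-only/EC-only/dual = 0.839/0.146/0.003/0.012,
  matching 15.8% CC and 1.5% EC current use with most early EC users also
  smoking cigarettes.
* **Openness**: two 4-point survey items (would you accept an offered
  cigarette; do you expect to smoke next year), scored at equal spacings
  $\{0, 1/3, 2/3, 1\}$ and averaged. Responses are drawn *conditional on
  user status*: current users are concentrated at "definitely yes" (mean
  base openness ≈ 0.98) and non-users at the closed end (mean ≈ 0.11).
* **Smoking close friends** (0–4): also drawn conditional on user status
  (non-users mostly 0; users centred near 2).
* **Use frequency**: Beta(3, 1.3) fraction of the last 30 days for current
  users of a product, exactly 0 otherwise; initial users are treated as
  established.
* **Age**: uniform 14–18; age enters no behavioural equation and is carried
  as a descriptive attribute.

Two of these choices deviate from a fully independent-marginals design and
deserve justification. First, openness is near-deterministic in user
status: the items are answered affirmatively by current smokers almost by
definition, and — more importantly for the dynamics — without this
correlation CC users adopt e-cigarettes at the same per-capita rate as
never-smokers, so dual use never reaches observable levels. Since the
openness multiplier $(1+o_X)$ is the only agent-level term that
distinguishes a smoker evaluating e-cigarettes from a non-smoker, the
correlation is load-bearing. Second, friend counts correlate with user
status because smoking clusters in adolescent friendship networks and the
survey item reflects that. Setting the user distributions equal to the
non-user ones restores full independence; both are plain fields of the
marginals object.

The generator does *not* emulate: survey weights, item non-response, age
or sex gradients in smoking, school structure, or any joint distribution
beyond the two user-status conditionals above. Passing tests therefore
demonstrate internal consistency with the stated marginals, not fidelity
to unpublished joint features of the survey sample.

## The network

`build_scale_free()` grows a Barabási–Albert graph: `m` seed nodes, each
arriving node attaching `m` edges to distinct existing nodes with
probability proportional to degree, giving exactly `m(n − m)` edges, a
connected simple graph, and a heavy-tailed degree distribution. The
default is `m = 3` (mean degree 6). A mean degree of 4 — the naive reading
of the four-closest-friends instrument — leaves smokers' neighbourhoods
physically unable to contain the reported number of smoking close friends
(users report about two of four, but a random degree-4 neighbourhood holds
only ~0.6 smokers), which destroys the peer clustering the instrument
implies. With degree 6 and close friends still capped at 4, the
close-friend designation (`assign_close_friends()`) can satisfy most
agents: it selects, per agent, the achievable number of smoking close
friends nearest the surveyed count, records the per-agent residual, and
never alters the topology. Because designations are one-sided (an agent's
close friends need not reciprocate), the per-agent greedy choice is
optimal and no repair pass can improve it. Peer prevalence is computed
over the designated close friends; the full neighbourhood can be used
instead by assigning all neighbours as close friends.

The network is static over the whole horizon: no rewiring, no homophily in
formation, no cohort turnover. This is a deliberate simplification — the
population is closed over a three-year high-school window.

## Simulation, replicates, seeds

`run_replicate()` builds a fresh population and network for every
replicate from sub-seeds derived deterministically (by a fixed affine map
modulo $2^{31}-1$) from `baseSeed + replicateId`, then advances the cycles,
recording state fractions per cycle and at each survey anniversary.
`run_scenario()` averages a fixed number of replicates (default 100) and
reports means and SDs. Agents are processed in `agentId` order and
summation order is fixed, so results are bit-reproducible given the spec.
`run_grid()` sweeps the 4×4 lattice of openness offsets and crossover
values (0–0.3 by 0.1), applying the openness offset jointly to both
products, which is how the scenario narrative is phrased.

## Calibration and validation

`calibrate()` fits a named subset of utility parameters to yearly
prevalence targets with 95% CIs by minimising

$$
L = \sum_{y}\sum_{X \in \{CC,EC\}}
\left(\frac{\widehat{P}_{X}(y) - P^{obs}_{X}(y)}{\text{half-CI}_{X}(y)}\right)^2,
$$

so products measured more precisely weigh more — the natural loss when the
validation criterion is CI coverage. The search is Latin-hypercube seeding
over 60% of the evaluation budget followed by shrinking Gaussian local
refinement, with common random numbers across evaluations (every candidate
is scored on the same replicate seeds), which makes the objective
deterministic and the whole fit reproducible from `(seed, budget)`.
Replicate SD is the only uncertainty reported; the package deliberately
stops short of posterior inference over parameters.

The shipped defaults fix `alphaPeerMix`, `gammaOpen`, `kappaDual` and
`tasteScale` at documented values and were obtained by fitting the
remaining parameters to the NYTS trajectory; `validate_backward()` then
scores any scenario run against the packaged targets
(`inst/extdata/nyts_targets.csv`, overridable). The 2015 survey year is
excluded by design: the regulatory regime changed and the model's
assumptions stop applying.

Identifiability deserves a warning: `muEC` and `wSoc` act almost
collinearly on the late EC level, so freeing both recovers either poorly.
The parameter-recovery test in the suite frees `{muCC, wSoc}`, which
separate cleanly through the CC trajectory, and recovers the generating
`wSoc` to within a few percent with a budget of 200 evaluations.

## Numerical choices and degenerate inputs

* Ties in the deterministic argmax break in the fixed state order; with
  `tasteScale > 0` ties occur with probability zero.
* Probability vectors must sum to 1 within $10^{-9}$; validation errors
  name the offending field, and malformed profile files report the
  offending row.
* An agent with no close friends has peer prevalence (0, 0) by definition.
* A horizon of zero years is allowed and records only the initialisation.
* Openness is clamped to $[0,1]$ after all additive terms.
* Sub-seeds stay below $2^{31}$; all randomness flows through R's RNG.

## Problem sizes used by the test suite

Unit and property tests run on populations of 20–5000 agents with 1–3
replicates. The end-to-end acceptance checks run the full study
conditions — 3000 agents, 36 cycles, 100 replicates per scenario, three
scenarios — and a 200-evaluation self-calibration at 800 agents and 8
replicates per evaluation; these sizes were chosen so the scenario means
have Monte-Carlo standard errors well under 0.1 percentage points.

## Known limitations

* The utility algebra is a reconstruction; the openness multiplier
  $(1+o_X)$ bounds how strongly attitude can differentiate agents (a
  factor of at most 2 on the social term), which in turn caps how much
  faster smokers adopt e-cigarettes than non-smokers. With the weights
  needed to keep counterfactual responses moderate, the model
  under-produces dual use relative to the observed 2014 level and
  compensates partially through the initial dual share.
* The observed EC trajectory ends 2014 in near-exponential growth, which
  places the contagion loop close to criticality; exogenous openness
  offsets are therefore amplified, and the openness +0.3 scenario responds
  more strongly in this implementation than the moderate response the
  calibrated original reported.
* Static network, closed population, no media/advertising channel, no
  price effects, no nicotine-dependence pharmacology.
* NYTS-derived targets are point estimates with approximate CI bounds
  transcribed from published summaries; users with better values should
  supply their own targets file.
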