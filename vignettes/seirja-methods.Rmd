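---
title: "Modeling coupled opinion dissemination and polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coupled opinion dissemination and polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(seirja)
```

## The model

`seirja` simulates how a piece of contested information — a rumor, a
health-policy controversy, a price announcement — spreads through an online
social network while the opinions attached to it polarize. The two
processes are coupled: who is talking determines who exchanges opinions,
and the opinions people end up holding determine whether they keep
talking.

### Dissemination: an epidemic state machine driven by willingness

Each of the $N$ agents occupies one of four compartments, named after
their epidemiological analogues:

* **S (uninformed)** — has not yet received the information and holds no
  attitude;
* **E (silent)** — informed but not spreading;
* **I (communication)** — informed and actively spreading;
* **R (immune)** — permanently disengaged.

Unlike a classic compartmental model, transitions are not fixed
probabilities. They are driven by each agent's *communicating
willingness*

$$P_i(t) = \bigl(|x_i(t)| - 1\bigr)\,e^{1 - m_i(t)} + 1,$$

which increases with the extremity $|x_i|$ of the agent's attitude
$x_i \in [-1, 1]$ and with the external recognition $m_i$ its opinion has
accumulated. At the initial recognition $m = 1$, willingness equals
$|x|$; recognition above 1 pushes it toward 1, and recognition below 1
(after repeated rejections) can push it negative.

A silent agent starts communicating when $P \ge p$ (the communication
threshold); a communicating agent falls silent when $P < p$. Two routes
lead to immunity: willingness dropping below zero, and the *forgetting
effect* — a receipt clock $z$ starts at 1 on first exposure, ticks every
step, and exceeding the attention span $z_0$ forces disengagement.

### Polarization: heterogeneous bounded confidence

Opinions evolve by pairwise bounded-confidence interactions of the
Jager–Amblard family. For an interacting pair with gap
$g = |x_i - x_j|$:

* $g < d_1$: **assimilation**, each attitude moves toward the partner,
  $x_i' = x_i + \mu_i (x_j - x_i)$;
* $g > d_2$: **rejection**, each attitude moves away,
  $x_i' = x_i - \mu_i (x_j - x_i)$;
* otherwise the encounter is **neutral**.

Both thresholds are strict; updates use pre-interaction values and are
clipped to $[-1, 1]$. What makes the dynamic heterogeneous is the
per-agent coefficient

$$\mu_i = (1 + E_{ij})\,(1 - T_i)\,C_i^{\pm},$$

the product of three individual factors:

* **Embeddedness** $E_{ij} = n_{ij} / ((k_i - 1) + (k_j - 1))$ — the
  common-neighbor count of the pair over its maximum, a proxy for tie
  strength ($E = 1$ for mutual sole neighbors). Close ties transmit more
  influence; the $1 + E$ factor keeps weak ties from muting the exchange
  entirely.
* **Conservatism** $T_i = N\,T_0\,k_i^{-1} / \sum_l k_l^{-1}$, clipped to
  $[0, 1]$ — resistance to persuasion, inversely tied to degree (hubs see
  more of the network and are more open) and scaled so the pre-clipping
  population mean is exactly $T_0$.
* **Conformity** $C_i^{\pm} = \max(0, 2 w_i^{\pm} - 1)$ — each agent
  tracks mainstream degrees $w^+ + w^- = 1$, its running perception of
  which camp dominates; every interaction steps the perceived camp of the
  partner up by $\gamma$. Conformity toward the partner's camp
  ($C^+$ when $x_j \ge 0$, $C^-$ otherwise) gates susceptibility. Both
  start at $w = 0.5$, so conformity — and with it every $\mu$ — is zero
  until interaction history accumulates.

Recognition closes the loop between the two layers: every assimilative
interaction raises both parties' $m$ by 1, every rejection lowers it
by 1, so agents whose opinions resonate keep talking while agents who
meet rejection fall silent and eventually disengage.

### The coupled step

One unit of model time: (1) every agent communicating at the step's start,
in a fresh random order, contacts one uniformly random neighbor; an
uninformed partner first draws an attitude from the initial distribution,
enters the communication state if its willingness $|x|$ reaches $p$ and
the silent state otherwise, then the pair interacts; immune partners
ignore the contact; (2) attitudes, mainstream degrees and recognition
update per interaction, with attitude changes immediately visible within
the step; (3) after all interactions, willingness is recomputed and all
compartment transitions are applied synchronously; (4) receipt clocks
tick. The run stops when the summed squared one-step attitude change
satisfies $\sum_i (x_i(t) - x_i(t-1))^2 \le 0.1$ (checked from the second
step) or at `max_steps`.

A note on the stop rule: uninformed agents hold no attitude, so the
package evaluates the convergence sum with their attitudes taken as 0 —
a first receipt counts as a change from neutral. The alternative
(counting only attitude *movements* of already-informed agents) would
satisfy the tolerance at $t = 2$ in essentially every configuration,
because attitudes cannot move before conformity leaves zero; treating
receipts as changes lets the stop rule fire only once dissemination and
polarization have both settled, which is the only reading consistent with
multi-week simulated horizons. One consequence: with $\gamma = 0$
(frozen conformity) attitudes never move, yet the run still lasts until
the dissemination wave saturates rather than stopping at the first check.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `d1`, `d2` | assimilation / rejection thresholds | 0.3 / 0.7 | the empirical-scenario values, the only fully printed set |
| `p` | communication threshold | 0.5 | empirical-scenario value |
| `T0` | mean conservatism | 0.8 | empirical-scenario value |
| `gamma` | mainstream step per interaction | 0.1 | midpoint of the swept range 0.05–0.2 |
| `z0` | attention span (steps) | 70 | midpoint of the swept range 50–110 |
| `init_comm_frac` | initial communicator fraction | 0.1 | second value of the swept range 0.05–0.2 |
| `attitude_mean`, `attitude_sd` | initial attitude law | 0, 0.3876 | normal, clipped to $[-1,1]$; the spread keeps extreme initial opinions rare |
| `N` | population | 300 | the simulation-study scale |
| `stop_tol` | convergence tolerance | 0.1 | the stop rule's stated constant |
| `polar_threshold` | extremity cutoff | 0.8 | the only numeric extremity definition used anywhere in the workflow |

The initial attitude notation "N(0, 0.3876)" is read as mean and
*standard deviation*; reading 0.3876 as a variance (sd ≈ 0.62) would make
roughly 20% of initial opinions extreme, contradicting the intent that
only a few individuals start extreme. Draws outside $[-1, 1]$ are set to
the boundary, not redrawn.

Two declared-range ambiguities are resolved by clipping, switchable via
`clip_coefficients`: conformity $2w - 1$ spans $[-1, 1]$ but its declared
range is $[0, 1]$ (clipped below at 0 — the minority camp exerts no
pull), and the raw $\mu$ can reach 2 but is declared in $[0, 1]$
(clipped above). The recognition degree is declared in $[1, \infty)$,
yet the immunity-by-rejection route requires willingness below zero,
which the willingness formula permits only when $m < 1$; the package
therefore lets $m$ fall freely (a `recognition_floor` restores the
strict declared range, at the price of making that route unreachable).
The recognition update law itself (+1 assimilated, −1 rejected, both
parties) is the package's own resolution of an under-specified quantity,
and the headline compartment peaks are sensitive to it — see
*Limitations*.

## Networks

Three substrates are provided, all as simple undirected graphs: scale-free
(preferential attachment, `make_ba_network`), small-world (rewired ring
lattice, `make_ws_network`) and random (`make_er_network`). The
study-scale defaults (N = 300, `ba_m = 25`, `ws_k = 48`,
`er_p = 49.61/299`) match the three families at mean degree ≈ 48–50,
which is the only scale constraint that can actually be honored: at this
size and density the average clustering of *any* of the three families is
bounded below by the random-graph level ≈ 0.16, so the published
clustering figure near 0.09 for matched networks is treated as a scale
indication, not a target. The small-world rewiring probability defaults
to 0.1, the standard small-world regime. The attachment parameter
`ba_m = 25` is chosen to land the scale-free family at the same mean
degree.

## What a worked example looks like

```{r example, eval = FALSE}
params <- seirja_params()              # the baseline study conditions
ens <- run_ensemble(params, n_runs = 10, base_seed = 1)
ens
#> <ensemble_result> 10 runs; peak mean E 58.9, peak mean I 176.5;
#>   final mean polarizability 0.272
peak_count(ens, "E"); peak_count(ens, "I")
```

Sweeps reproduce the comparative experiments: `run_sweep()` over
`init_comm_frac`, `z0`, `p`, `T0` or `gamma`;
`run_polarization_grid()` for the conservatism-by-conformity grid read at
checkpoints t = 10, 20, 40, 70; `run_network_comparison()` for the three
substrates. `run_empirical_scenario()` configures the coupled model and
both classic baselines from a comment stream's summary and reports
daily-curve RMSEs.

## Baselines

The classic probabilistic SEIR baseline replaces willingness and
forgetting with three fixed coefficients (acceptance 1, dissemination
0.3, immunity 0.2 in the empirical scenario). The contact process is
one-contact-per-spreader-per-step, mirroring the coupled scheduler so
curves share a notion of "step". The classic Jager–Amblard baseline has
no compartments: everyone holds an attitude from the start and interacts
once per step with a fixed $\mu = 0.5$. Its defining behavior — and the
reason the coupled model exists — is that rejection feedback drives it to
essentially complete polarization (≈ 100% of agents beyond $|x| = 0.8$),
which real comment data never shows.

## The synthetic comment stream

No platform data ships with the package. `generate_comment_stream()`
emulates the *shape* of a crawled comment table — user id,
hour-resolution timestamp, sentiment score in $[-1, 1]$, plus
period-level summaries (total comments, distinct users, duration, mean
sentiment of the first three hours). Mechanism: a coupled simulation runs
at fixture scale (5 steps per mapped day); every communicating agent
emits its attitude plus N(0, 0.1) noise per step; the emission pool is
then calibrated — the first-three-hour block is resampled from the
earliest emissions and recentered to the requested mean, later comments
are resampled from later emissions with uniform within-day hours, and
emitters are split or merged onto exactly the requested number of user
ids. Summaries recomputed from the stream match the request (counts
exactly; first-3h mean within ±0.05).

What the fixture does *not* emulate: real diurnal activity rhythms
(within-day arrivals are uniform), reply threading, user-level activity
persistence across days beyond what the simulation induces, and the
heavy-tailed comment-per-user distribution of real platforms. Passing the
empirical-scenario tests therefore shows the pipeline is wired correctly
and the models are comparable on a common stream — not that any model
fits real social-media data.

`steps_per_day = 5` maps an 8–13-day period onto 40–65 steps,
commensurate with the ~70-step horizons of the parameter studies. The
period rules are: initial communicator fraction = first-3h comment share;
$z_0$ = three quarters of the period horizon; initial attitude mean =
first-3h mean sentiment with sd 0.4; and the mainstream step is
$\gamma = 1/\omega$ with $\omega$ = 40, 45, 50, 55 across periods — an
interpretation (the quantity $\omega$ is otherwise undefined) chosen so
conformity responsiveness declines as an event matures.

## Problem sizes and reproducibility

All headline computations run at the study scale: N = 300 (parameter
studies) or N = 500 (empirical scenario and baselines), 10-run ensembles,
horizons of 40–200 steps. A single default run takes well under a second;
the full test suite and the acceptance script each run in well under a
minute. Every stochastic element — network generation, initialization,
scheduling, fixture resampling — flows from explicit integer seeds; run
`r` of an ensemble uses `base_seed + r - 1`, and ensembles regenerate the
network each run (pass a fixed `net` for the shared-substrate variant).
Ensemble spread is summarized as the time-averaged relative standard
deviation (percent sample-SD over mean across runs, skipping times with
zero mean).

## Limitations

* **The recognition law is the model's soft spot.** The published model
  uses $m_{it}$ without stating its update rule. Under the implemented
  rule a single assimilative contact lifts a silent agent's willingness
  to $1 - e^{-1} \approx 0.63 > p$, so the silent pool drains quickly:
  peak silent counts sit near 60 of 300 and peak communication counts
  near 180, where the published figures show roughly 150 and 110. The
  *invariance* of both peaks to the initial communicator fraction — the
  claim those figures make — holds robustly. Reported peak levels should
  be read as conditional on the recognition rule.
* **Clipped conformity bounds polarization.** With conformity and $\mu$
  clipped to $[0, 1]$ and a high conservatism mean (many low-degree
  agents clip to $T = 1$ and never move), the coupled model under the
  empirical-period configuration reaches final polarizability around
  10–15%, below the published 50–80% band, while remaining far from the
  classic baseline's degenerate 100%. The unclipped variant
  (`clip_coefficients = FALSE`) adds a minority-camp repulsion channel
  and more extremity; it is provided for exploration, not as the default.
* **Network-family differences are within noise.** Final polarizability
  on the three matched substrates differs by a few points at most across
  ensemble seeds; the small-world-lowest ordering is reproduced on
  average but is not a robust effect at 10 runs.
* Opinions are scalar, networks are static and unweighted, and agents
  neither join nor leave — the varying-population and multidimensional
  extensions are out of scope.
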