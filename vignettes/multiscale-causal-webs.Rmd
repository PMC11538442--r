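---
title: "Multiscale causal webs from abundance time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale causal webs from abundance time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmweb)
```

`ccmweb` infers directed causal-interaction networks from ecological
abundance time series with convergent cross mapping (CCM), and studies how
the inferred network changes with the temporal and taxonomic resolution of
the data. This vignette is the package's account of the methods: the model
behind each component, the parameters that matter, the numerical choices,
and what the synthetic benchmarks do and do not show.

## Dynamic causation and cross mapping

The causal notion used throughout is *dynamic*: `X` causes `Y` when the two
variables are mechanistically coupled in a shared dynamical system, so that
a change in `X` propagates into the trajectory of `Y`. For deterministic
(possibly chaotic) dynamics, a delay embedding of the *affected* variable
reconstructs the joint attractor; states of `Y` therefore carry recoverable
information about their drivers. CCM operationalizes this: embed `Y` with
delay coordinates

\[
M_Y(t) = \{\,Y(t),\, Y(t-\tau),\, \dots,\, Y(t-(E-1)\tau)\,\},
\]

find, for each reconstructed state, its `E + 1` nearest neighbors (simplex
convention), and predict the driver as the weighted average
\(\hat X(t+t_p) = \sum_i w_i X(t_i+t_p)\) with exponential weights
\(u_i = \exp(-d_i / d_1)\), \(w_i = u_i / \sum u\). The skill
\(\rho = \mathrm{cor}(\hat X, X)\) is evidence that `X` influences `Y`.
Skill that *grows with library size* separates dynamic coupling from mere
correlation; `ccm_library_sweep()` provides that diagnostic.

Numerical conventions (all configurable):

* neighbor count `E + 1`; ties in distance broken by ascending time so
  output is deterministic;
* the query's own time is always excluded (leave-one-out); a wider
  exclusion window is available via `exclusion_radius`;
* if the nearest distance is exactly zero, all zero-distance neighbors
  share weight equally (avoiding 0/0);
* a constant prediction or observation vector has no defined correlation
  and is *flagged* degenerate (`rho = NA`), never silently scored 0;
* embedding rows containing missing values are dropped, as are prediction
  times whose target value is missing;
* predictions can be restricted to an evenly spaced subset of query times
  (`max_queries`) for long series; the neighbor library is never thinned.

The prediction offset follows the convention that `tp = -k` predicts the
driver `k` steps into the past of the query time, so a web built at delay
`tau` uses `tp = -tau`: the cross map then reads strictly
backward-in-time information at the probed timescale.

## Two null models for link acceptance

A directed link is never accepted on raw skill. Two null procedures are
implemented, matching the two data situations:

**Linear cross-correlation baseline** (`null_kind = "xcorr"`, used for
model data): accept `X -> Y` only when the best skill over an `E` scan is
positive and exceeds the maximum absolute lagged cross-correlation of the
pair. The lag span defaults to the temporal span of the embedding,
`(max(E) - 1) * tau`, and can be set to `0` for the plain lag-0
coefficient. The choice matters for slow channels: a consumer that
integrates its prey over a long window is, to first order, a lagged
low-pass filter of the prey series, and a lag-maximized baseline over a
window-sized span will capture most of that signal linearly. The
lag-matched default is the stricter test for "dynamics beyond linear
correlation"; the lag-0 variant asks only "beyond instantaneous
correlation".

**Seasonal surrogates** (`null_kind = "seasonal_surrogate"`, used for
monthly data): co-monitored taxa are strongly seasonally synchronized, and
shared seasonal forcing produces cross-map skill without any direct
coupling. The null therefore permutes the putative driver's values *within
each calendar month* (all Januaries shuffled among themselves, and so on),
preserving the seasonal profile while destroying all other dynamics. A
link is accepted when the observed skill strictly exceeds at least 95 of
100 surrogate skills. The driver side is shuffled by default; shuffling
the response instead empirically destroys the calibration (the response's
embedding is what anchors the cross map), and is available only as an
explicit option.

Additional acceptance conventions: `rho > 0` is required (a negative
cross-map correlation is not causal skill), and no multiple-testing
correction is applied by default, matching the per-link 95/100 rule; the
package reports every tested link so users can apply `p.adjust` downstream
if desired.

## The individual-based automata model

`run_iba()` simulates three trophic levels on a continuous toroidal square
(default 1000 x 1000): resources (replenished at 500 per step), primary
consumers (PC) that graze resources within radius 10, and secondary
consumers (SC) that take PCs within radius 100. PC survival and
reproduction react to grazing within one timestep (0 meals: starve; 1+:
survive; 2+: one offspring). SC survival and reproduction react to
consumption summed over a rolling 500-step window (3000 to survive, 5000
for an offspring, at most one offspring per 200 steps), so the two
consumer levels couple to their prey on timescales three orders of
magnitude apart. That separation is the point of the model: a causal web
built at delay 1 resolves the per-step channels, while the influence of
PCs on SCs acts through the consumption window.

The published description of such automata leaves many mechanics open, and
the stated rates put the model in a tightly constrained corner. Choices
here, all exposed as config options and selected after a systematic
viability study:

* **Resource-limited PC level.** Total PC meals per step cannot exceed the
  resource influx in steady state, which pins the PC population near
  300-400 regardless of its initial value (1500). The SC survival rule
  (3000/500 = 6 PCs per step) is therefore only satisfiable if an SC's
  intake tracks the *standing* PC stock.
* **SC movement** defaults to `"mix"` (relocate randomly each step): with
  a capture radius spanning a tenth of the arena and the largest speed,
  the SC is modeled as a wide-ranging forager. Under literal slow
  movement an SC re-grazes its own depletion halo and its intake falls to
  roughly half the survival requirement, extinguishing the SC level in
  every movement variant tried.
* **Offspring placement** defaults to uniform-random (the infinite
  dispersal limit, like the resource influx). Placement at the parent
  clumps the short-lived PC population into patches; those patches produce
  attractive slow population waves, but collapse to extinction under any
  viable SC predation pressure. A disc-dispersal compromise is available.
* **Founding SC cohort** ages are staggered over the window with histories
  pre-filled at the survival rate: a cohort of 20 founders with identical
  empty histories hits its first starvation check simultaneously and goes
  extinct as one block.
* **Starvation before a full window** is pro-rated (die when the rolling
  sum falls below the threshold scaled to the lived history); a strict
  grace period re-synchronizes the cohort.
* **Satiation** caps SC intake at 40 PCs per step; unlimited intake lets
  the founding cohort strip the prey level during the initialization
  transient.

With these defaults all three levels persist in most seeds (PC near 300,
SC of order 5, resources a few thousand), the per-step resource ledger
balances exactly, the spatial index provably matches exhaustive search,
and runs are bit-reproducible from the seed.

**Known limitation.** The multiscale acceptance analysis
(`iba_causal_webs()`) reliably recovers the four fast ground-truth links
(bidirectional resource-grazer coupling; SC influence on PCs and,
transitively, resources). The slow channel PC -> SC is *not* reliably
resolved at `tau = 500`: after the founder-attrition transient the SC
population settles into the wide dead zone of its window rule (sums
between 3000 and 5000 produce neither births nor deaths), and the slow
variance of the PC level under the stabilized dynamics almost never
crosses it, so the SC series carries most of its variance in the early
transient. Configurations that produce large slow prey oscillations
(clustered offspring) were all found to collapse; the combination of
persistent coexistence *and* sustained window-scale SC response was not
reached in any faithful parameterization tried. The corresponding
acceptance test states the full intended pattern and is expected to fail
on the slow-channel assertions; the fast-web assertions pass.

## The coupled logistic predator-prey model

`simulate_logistic()` iterates, for 10 prey `P` and 10 predators `R`,

\[
P_{T+1} = P_T + A_{PP} R_T - \alpha P_T,\qquad
R_{T+1} = R_T + A_{RP} P_T - \alpha R_T,
\]

followed elementwise by the reciprocal constraint `v -> 1/v` for `v > 1`.
`A_PP <= 0` (predators harm prey), `A_RP >= 0` (prey feed predators), no
intra-guild terms; a connectance parameter `C` fixes the number of
non-zero entries per cross block (`round(C * 100)`, positions uniform
without replacement). The self-damping `-alpha` (0.15) realizes the
interaction matrix diagonal of -0.15 -- the two are one term.

Two numerical decisions required care:

* **Interaction magnitudes** default to uniform(0.05, 0.15). The update
  has no intrinsic growth, so the linear part is stable and the system
  only stays alive when the cross coupling destabilizes the fixed point
  and trajectories bounce off the reciprocal fold. Magnitudes an order of
  magnitude smaller let every trajectory decay to zero at all
  connectances; the chosen range keeps >= 15 of 20 series non-degenerate
  at `C = 0.6` in nearly all seeds while never producing overflow.
* **Negative values are retained.** The printed constraint folds only
  values above 1. Clipping negatives to a small positive floor pins the
  prey (which receive only negative input) at the floor and collapses all
  dynamics; the oscillation through negative values is precisely what the
  reciprocal fold bounds. Non-finite values abort with a diagnostic.

`aggregate_and_score()` sums the raw prey and predator series and measures
the influence of predators on prey by cross mapping the predator aggregate
from the prey-aggregate embedding (`E = 5, tau = 1, tp = -1`) -- the driven
guild's states recover the driver. A collapsed run (aggregate variance
below 1e-12) is flagged degenerate rather than scored on its trivial decay
curve. `connectance_sweep()` repeats this over connectances drawn from
[0.3, 0.9] and summarizes the association with a one-sided Spearman rank
correlation; 100 simulations give a clearly positive association
(typically rho about 0.3, p < 0.01). The mechanism is threshold-like:
connectance controls whether and how strongly the collective oscillation
is excited, which the aggregate cross map then resolves.

## Synthetic monthly data

The field-style machinery (seasonal surrogates, monthly/annual webs) is
validated on generated data with the two properties that matter: strong
cross-series seasonal synchrony and optional nonlinear coupling.

`make_seasonal_pair()` runs latent chaotic logistic maps (growth rate 3.8,
`Y` driven by `coupling * X` in its update), multiplies both by a shared
sinusoidal seasonal envelope `1 + 0.4 sin(2 pi month / 12)`, and adds
Gaussian observation noise (sd 0.03). Seasonal synchrony lives in the
envelope -- modulating the *growth rate* of a chaotic map, tried first,
leaves almost no seasonal imprint on monthly means -- and within-month
shuffling destroys exactly the latent dynamics while preserving the
envelope, which is the null the surrogate test needs. With `E = 4`
embeddings the 95/100 rule accepts about 8-11% of uncoupled pairs over
long calibration runs (nominal 5%; the residual leak comes from the two
latent maps sharing an attractor geometry) and >= 95% of pairs at coupling
0.4 with 30 years of data.

`make_two_timescale_system()` is the desk-scale analogue of the automata
model's structure: `A` and `B` chaotic maps coupled at lag 1, and a slow
consumer `C` responding through a saturating sigmoid to the 24-sample
moving average of `B`, with `B` carrying a slow chaotic amplitude
component so that the slow channel transmits an aperiodic (not merely
periodic) signal. The `B -> C` channel is resolved at `tau = 24` against
the lag-0 linear baseline but not by linear correlation itself -- the
sigmoid hides it. A moving-average channel with no output nonlinearity is,
by contrast, essentially linear and invisible to any "beyond correlation"
criterion; this is worth remembering when interpreting slow-web results
on real data.

`make_grouped_community()` produces block-structured communities (same
update rule as the predator-prey model, no intra-group coupling, known
cross-block densities) as ground truth for `fine_scale_connectance()` and
the linked-versus-unlinked comparison of `linked_vs_unlinked_test()`
(one-sided Welch t-test: do causally linked aggregates span more
species-level links?).

## Scale of the shipped analyses

The test suite and the acceptance script run the full 15,000-step automata
simulation with both webs (`E = 1:10`; cross-map predictions at up to
4,000 evenly spaced query times per map against the full library), a
100-simulation connectance sweep, 100 brute-force oracle comparisons, 50
directionality replicates at series length 1,000, and 250 surrogate link
tests (200 null + 50 power, 100 surrogates each). These sizes reproduce
the qualitative findings while keeping a complete run in minutes on one
core; all are parameters, not limits.

## What passing tests do and do not show

The synthetic generators share the *statistical* structure of monthly
monitoring data (seasonality, synchrony, nonlinearity, noise) but not its
failure modes: irregular sampling, detection limits, taxonomic drift,
observation error correlated across taxa, or secular trends. Calibration
of the surrogate rule on generated pairs bounds its false-positive rate
under shared seasonal forcing only; a trend shared by two real series can
still produce spurious links, and the within-month shuffle does not
destroy trends. Conversely, the slow-channel analysis above shows that a
linear integrating channel is structurally hard for any
correlation-exceeding criterion; absence of a slow-web link is weak
evidence of absence.
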