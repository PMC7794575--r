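---
title: "Methods: the 15N tracer model, its calibration, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 15N tracer model, its calibration, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n15trace)
```

## The scientific problem

Net changes in soil NH4+ and NO3- concentrations are the residuals of much
larger, simultaneous production and consumption fluxes. Whether a soil
retains nitrogen or leaks nitrate depends on those *gross* rates — how fast
organic N is mineralized, how much of the resulting NH4+ is immobilized by
microbes versus oxidized to NO3-, and how fast NO3- is consumed again — and
none of them is observable from concentrations alone. Isotope pool dilution
makes them observable: when a pool is enriched in 15N, influx of unlabelled
N dilutes its enrichment while efflux removes N at the pool's current
enrichment, so the concentration and enrichment time courses jointly
identify influx and efflux separately.

`n15trace` implements the numerical-model flavour of this technique for a
paired-labelling incubation: both inorganic N species are amended at equal
rates, with the 15N label on NH4+ in one treatment and on NO3- in the
other, and a process-based model of the whole N cycle is fitted jointly to
both treatments.

## Model structure

Five pools are tracked: NH4+, NO3-, labile organic N, recalcitrant organic
N, and exchangeable adsorbed NH4+. Each pool carries a total N amount
(mg N kg^-1^ dry soil) and an absolute 15N atom fraction. Ten one-directional
processes connect them (`process_table()`): mineralization of labile and
recalcitrant organic N (M_Nlab, M_Nrec), NH4+ immobilization into both
organic pools (I_NH4_Nlab, I_NH4_Nrec), adsorption and release of
exchangeable NH4+ (A_NH4, R_NH4), autotrophic nitrification (O_NH4),
heterotrophic nitrification of recalcitrant organic N (O_Nrec), DNRA
(D_NO3), and NO3- immobilization (I_NO3).

Each process follows zero-order, first-order or Michaelis-Menten kinetics.
Every flux carries the instantaneous atom fraction of its source pool — the
standard pool-dilution assumption of no isotopic fractionation — so the
total-N and 15N balances are closed by construction: the network only moves
N between pools. Incubation temperature and moisture are fixed by the
experimental protocol (25 °C, 60% water-holding capacity) and are not model
state; gaseous losses are outside the network.

Atom% excess (APE) is always relative to atmospheric N2 (0.3663 atom% 15N).
Time is days internally; sampling times given in hours are converted on
input, and rates are mg N kg^-1^ day^-1^ throughout.

### Initial conditions

The initial state mixes the natural-abundance soil background with the
amendment; the labelled species enters at natural abundance plus its atom%
excess, and each inorganic pool's atom fraction is the amount-weighted
mixture. The labile organic pool size `n_lab0` is not measurable and is
treated as a fittable parameter (bounds 0–200 mg N kg^-1^); the
recalcitrant pool is whatever remains of soil total N after subtracting
`n_lab0` and the *pre-amendment* inorganic N (total N is assayed on
unamended soil). The adsorbed pool starts empty: the exchangeable fraction
at equilibrium with the pre-label solution is operationally part of the
measured NH4+ pool, and only the exchange dynamics after label addition
matter.

## Numerical integration

The coupled equations are integrated with a fixed-step classical 4th-order
Runge–Kutta scheme (compiled core), default step 0.001 d. The grid is
refined so requested output times are hit exactly, and outgoing fluxes are
clipped within each step so no pool can be driven negative — this implements
the physical substrate limit of zero-order kinetics. Per-process flux
integrals are accumulated along the trajectory by trapezoidal quadrature,
which is what the 48-h average gross rates are computed from.

At the rate scales admitted by the default parameter bounds (first-order
k ≤ 10 d^-1^) the RK4 discretization error is orders of magnitude below
measurement precision; halving the step changes outputs by well under
10^-6^ relative. The calibration stage therefore runs its embedded
simulations at a coarser step (0.01 d), which leaves the misfit unchanged
to ~10^-7^ while making the tens of thousands of simulations per fit cheap.
Both steps are exposed as arguments.

## Calibration

### Misfit

The fitted data are, for each treatment, sampling time and inorganic pool,
the replicate mean and standard deviation of the concentration and of the
APE. The misfit is the weighted least-squares sum
`J = sum(((predicted - mean) / sd)^2)` over all records of both treatments,
i.e. −2 log-likelihood (up to a constant) under independent Gaussian errors
with known sds. Reported sds are floored — concentrations at
max(0.05 mg N kg^-1^, 2% of the mean), APE at 0.02 — because a sample sd of
three replicates is occasionally near zero and would otherwise produce an
effectively infinite weight; missing sds take the floor value.

### Sampler

Parameters are estimated by random-walk Metropolis within box bounds (a
uniform prior): acceptance probability `min(1, exp(-(J' - J)/2))`,
out-of-bounds proposals rejected. The default schedule is 3 chains × 30,000
iterations with the first half discarded. During burn-in the proposal is
adapted — a global step multiplier targets 20–45% acceptance and the
proposal shape follows the empirical covariance of the recent chain
(adaptive Metropolis) so that correlated ridges, such as the
anticorrelated autotrophic/heterotrophic nitrification pair, are traversed
along their long axis. Adaptation is frozen after burn-in so the retained
draws come from a fixed-kernel Metropolis chain. All randomness derives
from the user seed; identical seeds give bit-identical chains.

The misfit surface of this model family is multimodal. Two features recur:
a secondary mode in which the labile pool collapses (`n_lab0` → 0, with
mineralization reassigned to the recalcitrant pool), and a
mineralization–immobilization recycling ridge along which both M_Nlab and
I_NH4_Nlab grow together. Chains started from random prior draws regularly
settle in these structures. The package therefore initializes each chain
from the data: classical pool-dilution analytics
(`pool_dilution_rates()`) give model-free estimates of total NH4+
production/consumption and NO3- production/consumption from the first and
last sampling points; these are allocated across processes heuristically,
back-solved into kinetic parameters, jittered per chain, and refined by a
short greedy descent. Initialization is not part of the chain. As a
convergence diagnostic, a chain whose post-burn-in median misfit sits more
than 50 above the best chain's is flagged non-converged and excluded from
the pooled posterior (the fit records the decision); with the data-informed
initialization this is rare.

Reported point estimates are posterior means, uncertainties posterior sds,
intervals the 2.5/97.5 posterior percentiles. The 48-h average gross rates
are computed by simulating an evenly thinned subsample of the pooled
posterior draws (default 1500) and integrating each process flux; the
totals M_N = M_Nlab + M_Nrec and I_NH4 = I_NH4_Nlab + I_NH4_Nrec are formed
per draw so their summaries are exactly consistent with the components.
Because both treatments receive the same amendments, total-N dynamics — and
hence fluxes — are treatment-invariant, and one simulation per draw
suffices.

### Model selection

Kinetic variants are compared by AIC = J_min + 2p (J is already on the
−2 log-likelihood scale), smaller is better, exact ties broken by fewer
parameters and then input order. Plain AIC is the default; the small-sample
correction is available via a flag. The per-process kinetic assignments of
the default structure (first-order for the substrate-limited inorganic
processes, zero-order for mineralization of the large recalcitrant pool and
for heterotrophic nitrification) are a starting point, not a claim — AIC
selection among variants is the mechanism for choosing them on real data.

## Identifiability: what a 48-h dual-label design can and cannot resolve

With four sampling times over 48 h and two labelling treatments, the
well-constrained quantities are total mineralization (M_N), total NH4+
immobilization (I_NH4), and autotrophic nitrification (O_NH4). Several
structural limits are worth knowing:

* The adsorption/release pair (A_NH4, R_NH4) is a fast internal loop whose
  joint magnitude barely affects the observables; only its net effect is
  weakly constrained, so its posterior spreads over the prior.
* The split of mineralization and immobilization between the labile and
  recalcitrant organic pools is weakly identified; the totals are robust.
* Heterotrophic nitrification competes with autotrophic nitrification for
  the same NO3- production; the 15N routing separates them, but only to
  ±~0.2 mg N kg^-1^ day^-1^ at default noise. Because rates are
  nonnegative, a truly negligible O_Nrec acquires a small positive
  posterior mean and O_NH4 a compensating small negative bias.
* A component rate is resolvable in *relative* terms only when it is a
  non-negligible share (roughly ≥ 10%) of its pool's total turnover. In a
  high-nitrification arable soil where NH4+ immobilization is ~2% of NH4+
  consumption, I_NH4 is the small difference of two large, well-measured
  numbers: its posterior interval is honest but its relative error is
  necessarily large. The package's recovery tests apply their 25%
  relative-error check only to rates above this threshold; interval
  coverage is still checked for all headline rates.

## The synthetic study design

The generator reproduces the incubation design the model was built for: two
treatments (15NH4NO3 at 9.44 atom% excess; NH415NO3 at 9.75), both species
amended at 20 mg N kg^-1^, destructive sampling at 0.5, 12, 24 and 48 h,
three replicates. Replicate noise is Gaussian — 3% relative on
concentrations, 0.05 APE absolute on enrichments, truncated at the physical
bounds by redrawing — and the emitted table carries replicate means and sds,
the same format a real incubation provides. These noise magnitudes are
assumptions (instrument-error models are rarely published); they are
surfaced as the `noise_model()` defaults.

Two reference soils anchor the land-use contrast: a forestland-like truth
(M_N 3.95, I_NH4 6.67, O_NH4 1.99 mg N kg^-1^ day^-1^; immobilization
dominating NH4+ consumption) and a cropland-like truth (M_N 4.84, I_NH4
0.34, O_NH4 14.54; nitrification dominating), with soil properties at the
corresponding group means. Because published results are 48-h *average
rates*, not rate constants, the generator back-solves kinetic parameters
from target average rates: a per-process multiplicative update iterated to
a joint fixed point (`solve_params_for_rates()`), deterministic and exact
to 10^-8^ relative.

The cohort generator draws 11 forestland and 8 cropland soils around the
group means, with the quoted group errors used directly as the Gaussian
sampling spread — with these spreads, truncation at physical bounds is
negligible and generated group means stay centred, which is the generator's
contract (the corresponding field ranges are wider; the cohort is
deliberately conservative). C/N is recomputed from the drawn SOC and TN,
never drawn independently. Within each group, I_NH4 is positively and
O_NH4 negatively coupled to SOC (correlation 0.6 by construction), so the
cohort reproduces the directions of the SOC–immobilization and
SOC–nitrification relationships; mineralization, the NO3--consuming
processes and the adsorption exchange have no built-in land-use difference.
What passing tests on this cohort demonstrate is that the statistics
pipeline detects contrasts and correlation signs of the magnitude the
design encodes — not that real field soils behave this way; the generator has
no spatial structure, no slope-position effects, and no seasonal dynamics.

## Derived indices and statistics

From the gross rates: nitrification capacity O_NH4 / M_N; NO3- retention
capacity (I_NO3 + D_NO3) / (O_NH4 + O_Nrec); the O_NH4 / I_NH4 ratio; and
the soil NO3-/NH4+ concentration ratio. A zero denominator flags the index
undefined rather than coercing it to zero, and undefined values are dropped
pairwise from statistics.

Group comparisons use the independent-samples t test (equal-variance by
default, Welch optional), preceded by a Kolmogorov–Smirnov normality check
per group that is reported but never gates the test; relationships use
Pearson correlation. No multiple-testing correction is applied — the
analysis mirrors a field study's convention of reporting per-variable
tests at α = 0.05.

## Runoff flux accounting

Event-based NO3- export is the sum over events of c_i × q_i / 100, with
c in mg L^-1^ and q (discharge depth) in mm; the /100 is the exact unit
conversion to kg N ha^-1^, kept literal. Interflow, overland flow and a
whole-catchment outlet are separate pathway labels with subtotals. All
pathways must supply discharge as depth (mm); converting volumetric weir
discharge to depth over the catchment area is the caller's responsibility.

## Problem sizes used in the packaged checks

The packaged test suite exercises the full pipeline at the study's own
design: 10-seed parameter-recovery runs at both land-use truths with the
default 3 × 30,000 MCMC schedule, 20-replicate AIC-selection and
cohort-statistics experiments, and 100-draw conservation sweeps. Each full
fit takes tens of seconds on one core; the recovery block is the dominant
cost. The acceptance script fits one synthetic dataset per land-use truth
at the default schedule and reruns the cohort statistics and the flux
identity from scratch.

## Known limitations

* One fit per soil sample; no hierarchical pooling across soils.
* No isotopic fractionation, no gaseous N losses, no
  temperature/moisture response — the model describes a closed, constant-
  condition incubation, not the field.
* The uniform box prior plus nonnegativity means weakly identified rates
  (A/R exchange, O_Nrec, small I_NH4) carry prior-volume bias; read their
  posteriors as upper-bound-style statements, not point estimates.
* Analytic pool-dilution initialization assumes the enrichment time course
  is usable (positive APE at first and last sampling); fully exhausted or
  unlabelled pools fall back to prior-draw screening.
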