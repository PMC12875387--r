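---
title: "Methods: chamber fluxes, cumulative emissions and life-cycle climate metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber fluxes, cumulative emissions and life-cycle climate metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alfaghg)
```

## Scope and model

`alfaghg` implements the accounting chain of a static dark-chamber
greenhouse-gas campaign in an irrigated alfalfa system: a 3 × 4 factorial
crossing seasonal irrigation (0, 100, 300 mm, split over three harvest
cycles as 0/0/0, 40/30/30 and 120/90/90 mm) with fertiliser N (0, 60, 120,
180 kg N ha⁻¹), three replicate plots per treatment, sampled from
mid-March regreening to the late-September harvest.

The chain has four stages, each a pure function of its inputs:

1. **Flux estimation.** Headspace concentrations (or GC peak areas
   calibrated through a certified standard, $C_S = A_S C_0 / A_0$) are
   regressed on elapsed minutes; the OLS slope feeds the ideal-gas chamber
   formula $F = (M/22.4)\,(273/(273+T_a))\,60\,H\,dC/dt$. The formula
   assumes 1 atm (no altitude correction) and a linear accumulation over
   the 30-minute deployment — nonlinear (HMR-style) chamber models are out
   of scope.
2. **Cumulative emission.** Trapezoidal integration between sampling dates,
   $GF = \sum_i \tfrac{F_{i+1}+F_i}{2}(t_{i+1}-t_i)\cdot 24\cdot K$, with
   $K = 10^{-5}$ (N₂O, CH₄) or $10^{-2}$ (CO₂). Fluxes are estimated on the
   gas-molecule mass basis and converted to element mass in this single
   audited step (×28/44, ×12/44, ×12/16), so totals are kg N ha⁻¹ and
   kg C ha⁻¹.
3. **Resource metrics.** WFPS $= \theta_v/(1-\rho_b/\rho_p)$ with
   $\rho_p = 2.65$ g cm⁻³ unless overridden; IWP $= Y/I$; PFPN $= Y/N$.
4. **Climate metrics.** The fertiliser-induced emission factor against the
   matched same-irrigation unfertilised control; soil GWP
   $= 265\,GF_{N_2O} + 28\,GF_{CH_4}$; input-chain GWP
   $= \sum_i \mathrm{Amount}_i \cdot EF_i$; GHGI $=$ GWP per tonne of hay.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| chamber height `H` | 0.30 | m | cubic 30 cm chamber |
| sampling protocol | 0/10/20/30 | min | four syringe draws per deployment |
| QC threshold | r² ≥ 0.80, n ≥ 3 | — | standard chamber practice; the protocol itself reports no QC rule, so this is a package decision |
| near-zero band | 2 × σ_slope | slope units | r² is uninformative when no concentration change occurred; σ_slope propagates the per-sample concentration SD through the OLS design |
| particle density ρ_p | 2.65 | g cm⁻³ | mineral-soil convention |
| GWP₁₀₀ weights | 265 / 28 | kg CO₂-eq kg⁻¹ | 100-year horizon, N₂O / CH₄ |
| input emission factors | 8.3, 0.79, 0.55, 2.66, 55.4 | see README | regional input-chain inventory values |
| GWP mass basis | `"element"` | — | see below |

## Design choices where the design was open

**Mass basis of the soil GWP term.** The cumulative totals reach the GWP
step in element mass (kg N, kg C). Applying the 265/28 weights to those
totals literally (the `"element"` default) best reconciles the printed
annual totals of the reference campaign; a `"gas"` option converts to
gas-molecule mass (×44/28, ×16/12) first. Both paths are tested; the switch
lives in the configuration so no downstream code hard-codes a basis.

**IWP denominators.** Published per-harvest IWP values for this class of
campaign are consistent with dividing each harvest's yield by the *total*
seasonal irrigation volume, not by the per-harvest split (per-harvest
division would imply implausibly small harvest yields). The package
therefore uses the seasonal volume for both per-harvest and annual IWP.

**Undefined metrics.** IWP at 0 mm, PFPN and EF at 0 kg N are undefined,
represented as `NA` and written as "–" — never 0 or infinity, matching how
such cells are typeset in field-trial tables.

**Harvest partitioning.** Intervals are half-open `(h₁, h₂]` with the
season start closed; when no record falls on a boundary the boundary flux
is linearly interpolated. This makes per-harvest additivity exact
(tested to 1 × 10⁻⁹ relative) rather than approximate.

**Edge handling.** No extrapolation beyond the first and last pass-QC
records; the seasonal integral starts at the first record. The basal
fertiliser application (40 % of the seasonal rate at autumn sowing)
precedes the sampled season and is not an in-season event, though the full
seasonal rate still enters EF, PFPN and the input inventory. The winter gap
is not interpolated across: integration covers the sampled season only.

**EF pairing.** Each fertilised treatment is paired with the N0 control at
the same irrigation level, never with a single global control: irrigation
changes the unfertilised baseline.

**Duplicate timestamps** within a chamber deployment are rejected as
invalid input rather than averaged — a duplicated syringe time indicates a
recording error, and averaging would silently change the OLS design.

## The synthetic campaign generator

The generator is phenomenological — daily piecewise-exponential pulse
dynamics, not a process-based biogeochemistry model — because the target
system supports only phenomenological structure: pulse timing, driver
windows, sink behaviour.

* **Drivers.** Soil temperature follows a seasonal half-sine (8 °C at the
  season edges, +20 °C amplitude, 1.5 °C daily noise). WFPS sits on a
  per-water-level baseline (27 / 29.5 / 33 %), jumps by 0.28 % per mm of
  irrigation or rain and relaxes at 0.07 d⁻¹ — repeated wet–dry cycles,
  wider under high irrigation. Available N (baseline 25 mg kg⁻¹) jumps by
  2.0 mg kg⁻¹ per kg N applied, decays at 0.05 d⁻¹ and declines over the
  season.
* **N₂O** = baseline (25 µg m⁻² h⁻¹, modulated mildly by moisture) plus
  event-triggered gamma-shaped pulses, amplitude 10 µg m⁻² h⁻¹ per kg N
  applied, rising to a peak five days after application and gated by a
  50–60 % WFPS window. The rise-then-decay shape matters: emission maxima
  trail management events by several days in this system, and an
  instantaneous event-day jump would be integrated poorly by a protocol
  whose event sampling starts on day 1.
* **CO₂** follows a Gaussian temperature response centred at 17.5 °C with a
  moisture multiplier increasing in WFPS (moist soils sustain root and
  microbial respiration, giving the high-irrigation treatments the larger
  seasonal totals) and a mild available-N multiplier.
* **CH₄** is a persistent sink, `min(0, −90 + 1.2·WFPS)` µg m⁻² h⁻¹:
  uptake weakens as pores fill, but the mean response never becomes a
  source.
* **Noise.** Daily multiplicative lognormal flux noise (sdlog 0.1, mean
  one) and Gaussian GC measurement noise of 1 nL L⁻¹ (N₂O), 4 µL L⁻¹
  (CO₂) and 4 nL L⁻¹ (CH₄) — about 0.2–0.3 % RSD at ambient, typical of a
  well-maintained GC. Replicate-level variance is not constrained by any
  published value, so these SDs are free parameters chosen to be
  instrument-realistic while keeping the pipeline's stated recovery budget
  (below) attainable.
* **Sampling schedule.** Routine visits every 8 days; after each
  irrigation/fertilisation event, visits on days 0, 1, 3, 5, 7 and 9 (a
  pre-application morning measurement on the event day, then the
  alternate-day window spanning the 7–10-day practice); one extra visit the
  day after heavy (> 10 mm) rain.
* **Yields** use a concave water × nitrogen response with the optimum at
  120 kg N ha⁻¹ under high water and per-harvest bases summing to
  ~11.8 t ha⁻¹ for the unirrigated, unfertilised reference.
* **Determinism.** Every random stream is seeded from (master seed, stream
  name), one stream per plot and purpose, so adding plots or gases never
  perturbs existing streams and a fixed seed reproduces the bundle
  bit-for-bit.

What the generator does **not** emulate: spatial autocorrelation between
plots, instrument drift, winter fluxes, frozen-soil physics, or calibrated
reproduction of any particular campaign's measured magnitudes. Passing
recovery tests therefore demonstrates that the *accounting chain* is
correct and adequately sampled for pulse dynamics of this time scale — not
that the simulator predicts real fields.

## Numerical behaviour and verification

* The trapezoid implementation is closed-form; it matches a 1-minute
  fine-grid integral of the piecewise-linear interpolant to < 10⁻⁶
  relative (observed: machine precision) over 100 random series.
* The forward chamber model is the exact algebraic inverse of flux
  estimation: 1 000 random fluxes round-trip to < 10⁻⁹ relative noise-free,
  and with measurement noise the mean recovered flux is unbiased within
  two standard errors.
* On a full simulated campaign (36 plots, ~44 sampling dates, three gases)
  the pipeline recovers each treatment's seasonal cumulative N₂O within
  5 % of the generator's daily-grid integral of the noise-free response;
  across probe seeds the maximum error is 2.4–3.9 % with a residual mean
  bias of about +1 % from trapezoid discretization of pulse tails.
* Exactly collinear chamber series return r² = 1 and the exact slope; an
  exactly constant series returns slope 0 with r² undefined (`NA`), which
  QC passes through the near-zero band.

Problem sizes in the test-suite and acceptance script — one simulated
campaign per run, 100 oracle series, 1 000 round-trip fluxes — are the
package's chosen desk-scale defaults; the full suite runs in well under a
minute of simulation time.

## Known limitations

* Linear chamber accumulation only; strongly nonlinear deployments are
  flagged `nonlinear` and excluded rather than refit.
* QC exclusion of low-r² deployments can censor very small fluxes when GC
  noise is large relative to the slope; the near-zero band mitigates but
  does not eliminate this, and heavily censored series bias trapezoid
  totals (bridged valleys integrate high).
* Uncertainty propagation stops at replicate standard errors; no gap
  filling or process modelling.
* The LCA boundary covers the listed inputs only (no machinery
  manufacture, transport, or soil carbon stock change), and soil CO₂ is
  excluded from GWP by design.
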