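---
title: "Quantifying drug-membrane interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-membrane interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerlab)
```

`bilayerlab` packages the analysis chain used to characterize how small
amphiphilic drugs (the worked examples use the PDE-5 inhibitors sildenafil,
vardenafil and tadalafil) alter the physical chemistry of model lipid
membranes. Four experimental readouts are covered, each with its own module,
plus seeded synthetic generators that emulate every input class with known
ground truth. This vignette explains the models, the tunable parameters and
the numerical choices; the README shows the day-to-day workflow.

## Boundary potential from carrier-mediated conductance

A lipophilic probe cation (the K⁺–nonactin complex, valence $z = +1$)
partitions into the bilayer according to the Boltzmann distribution, so the
steady-state membrane conductance it produces reports the membrane boundary
potential $\varphi_b$ — the total potential jump between the membrane
interior and the bulk solution. When a modifier changes $\varphi_b$ by
$\Delta\varphi_b$, the conductance ratio after/before addition obeys

$$\frac{G}{G_0} = \exp\!\left(-\frac{ze\,\Delta\varphi_b}{kT}\right),
\qquad
\Delta\varphi_b = -\frac{kT}{ze}\,\ln\frac{G}{G_0}.$$

`boltzmann_delta_phi()` and `conductance_ratio_from_delta_phi()` implement
the pair; they are exact algebraic inverses (tested to $10^{-12}$
relative). Constants are CODATA-exact, so $kT/e = 25.693$ mV at the default
298.15 K (room temperature, 25 °C). The sign convention stores
$\Delta\varphi_b$ signed: for a cationic probe a conductance increase means
the boundary potential *decreased* ($\Delta\varphi_b < 0$). Summary tables
print the magnitude of the decrease, matching how such results are usually
tabulated.

Concentration dependences are described by the Langmuir adsorption
isotherm,

$$\Delta\varphi_b(C) = \Delta\varphi_b(\max)\,\frac{C}{C+K},$$

with $\Delta\varphi_b(\max)$ the plateau at saturating modifier
concentration and $K$ (µM) the desorption constant — the inverse affinity
of the drug for the membrane. Two fitters are provided:

* `fit_langmuir_nonlinear()` — Levenberg–Marquardt least squares
  (`minpack.lm`), the recommended estimator. Points are weighted by
  $1/\mathrm{sd}^2$ when every concentration carries a positive replicate
  sd, otherwise unweighted; whether the original analyses were weighted is
  not documented, so weighting is applied only when the replicate
  information to support it exists.
* `fit_langmuir_linearized()` — the classical linearizations.
  `"double_reciprocal"` regresses $1/\Delta\varphi_b$ on $1/C$ (intercept
  $1/\Delta\varphi_b(\max)$, slope $K/\Delta\varphi_b(\max)$).
  `"plateau"` starts from the saturation-region mean (concentrations
  ≥ 120 µM by default, where titrations of this kind visibly level off) and
  regresses $\Delta\varphi_b(\max)/\Delta\varphi_b(C)$ on $1/C$, whose
  slope reads off $K$ directly. For perfect Langmuir data this regression
  has intercept exactly 1; when the largest measured concentrations are not
  fully saturating the plateau mean underestimates the magnitude of the
  true plateau, which shows up as an intercept $c_0 \ne 1$. Dividing both
  estimates by $c_0$ restores the identity, so plateau mode reproduces the
  generator exactly on noiseless data while reducing to the plain slope
  reading when the plateau is genuinely saturated. This one-step correction
  is the package's own design choice; without it the mode would be biased
  by construction whenever $K$ is not ≪ the plateau threshold.

Fits are performed on replicate-aggregated mean curves (the conventional
presentation); `build_titration_curve()` aggregates replicate-wise
Boltzmann conversions as mean ± sd with $n$ reported, and refuses data
without a per-replicate $C=0$ baseline.

## Dipole potential by di-8-ANEPPS ratiometry

The dipole potential $\varphi_d$ is probed with the voltage-sensitive dye
di-8-ANEPPS. The excitation ratio $R = I_{420}/I_{520}$ (emission 670 nm)
compensates for fluidity-driven intensity changes and maps linearly onto
$\varphi_d$:

$$\varphi_d = \frac{R + a}{b}.$$

The defaults $a = 0.3$, $b = 0.0043\ \mathrm{mV}^{-1}$ follow the
dual-wavelength ratiometric calibration methodology this mapping comes
from; both are arguments of `dipole_calibration()` because calibration
constants vary between instruments. Only $b$ affects potential
*differences* — the package's reported quantity — so the choice of $a$ is
cosmetic, and a property test asserts the invariance. `dipole_titration()`
produces $\Delta\varphi_d(C)$ curves in the same container as the
boundary-potential module, so the Langmuir machinery is reused unchanged.

## Single-channel (gramicidin A) analysis

Gramicidin A forms single-file cation channels whose conductance senses the
dipole potential at the pore mouth. The analysis chain is:

1. **Baseline** — `estimate_baseline()` takes the mode of a kernel-smoothed
   amplitude density (median fallback), robust while the channel is closed
   at least half of the time. Records near 50% occupancy should supply
   `baseline_pA` explicitly, since the two density modes then compete.
2. **Idealization** — `idealize_half_amplitude()` uses the half-amplitude
   threshold, the field standard for single-level pores, with ±10%
   hysteresis around the half-amplitude level to suppress noise-driven
   re-crossings. Events shorter than `min_duration_s` are merged into the
   surrounding level; the default is twice the low-pass filter rise time
   ($2 \times 0.3321/f_c \approx 0.66$ ms at 1 kHz), because shorter
   excursions are attenuated by the filter and cannot be measured reliably.
   Segment amplitudes exclude one rise time after each transition.
   Residual limitation: events only slightly longer than the minimum are
   still partially attenuated (a fourth-order filter settles more slowly
   than its nominal rise time), so occasional low outliers appear in the
   event conductance list; they widen the fitted peak slightly but leave
   the peak mean well inside the stated tolerances.
3. **Conductances and histograms** — one conductance per opening,
   $g = (\bar{I}_{\text{open}} - I_{\text{closed}})/V$ in pS
   (`events_to_conductance()`), binned at 0.5 pS by default
   (`build_conductance_histogram()`). Amplitude analysis conventionally
   uses 500–1000 events; counts outside that range warn rather than error.
4. **Peak fitting** — `fit_normal_peaks()` maximizes the multinomial
   likelihood of the *binned* counts under a normal mixture (bin
   probabilities from the normal CDF), so the estimator respects the
   binning. Initial means come from histogram local maxima, with three
   deterministic jittered restarts. The objective deliberately uses
   unconditioned bin probabilities: renormalizing over the histogram range
   lets a component drift far outside the range and degenerate into a
   near-geometric tail that absorbs outlier bins.
5. **Goodness of fit** — `chi_square_gof()` pools adjacent bins until every
   expected count reaches 5, computes the Pearson statistic, and uses
   $\mathrm{dof} = \text{pooled bins} - 1 - (3 n_{\text{peaks}} - 1)$. The
   test attains its nominal 5% type-I error on model-generated histograms
   (checked by simulation with 200 replicates). On very narrow histograms
   the test is infeasible; the peak fit then stands with the χ² fields set
   to `NA` and a warning.

`gv_curve()` assembles per-voltage conductance summaries and
`conductance_increment()` reports the percent change of treated vs control
peak means — e.g. 22 → 28 pS is +27.3%, 22 → 26 pS +18.2% (exact
arithmetic is reported; no rounding to "20–25%" style statements).

## Macroscopic (nystatin) currents

Nystatin forms multichannel ensembles whose pore-forming activity senses
membrane curvature stress; the readout is the ratio
$I_\infty/I_\infty^0$ of steady-state transmembrane currents after vs
before modifier addition. `steady_state_current()` averages a window and
warns when the fitted linear drift across the window exceeds 5% of the
mean. `activity_ratio()` places the windows automatically — the final 20%
of each phase, capped at 60 s, with the post-addition window constrained to
start after a user-set `settle_time_s` (how long steady state takes after
addition is an experimental judgement; 100 s with the default 20 s
relaxation time leaves the residual transient below $e^{-5}$). The ratio's
standard error comes from the delta method on the two window means, and the
estimate is exactly invariant to overall current rescaling.

## DSC melting features

Lipid melting is summarized by the pretransition temperature $T_p$, the
main-transition peak temperature $T_m$, the full width at half maximum
$T_{1/2}$, and the calorimetric area. The extraction chain
(`baseline_subtract()`, `detect_transitions()`,
`main_transition_features()`, `pretransition_features()`, or the wrapper
`extract_transition_features()`) makes every numerical rule explicit so
results are bit-reproducible:

* baseline = straight line through the two flank means (first/last 5% of
  the grid), validated on the detrended signal so that drift cannot mask a
  peak overlapping a flank;
* apex by quadratic interpolation of the three samples around the maximum;
* width by linear interpolation of the half-height crossings;
* area by trapezoidal integration over the contiguous region above 1% of
  the apex;
* pretransition searched in $[T_m - 12, T_m - 2]$ °C and declared
  *suppressed* below 5% of the main apex height. The literature reports
  suppression qualitatively; the 5% prominence rule is this package's
  operationalization, chosen so the decision is testable.

`compare_to_control()` reports $\Delta T_m = T_m^{ctl} - T_m^{trt}$
(positive for the usual drug-induced downshift) and
$\Delta T_{1/2} = T_{1/2}^{trt} - T_{1/2}^{ctl}$ (positive for
broadening), matching the sign conventions of published tables.

## Synthetic generators

The raw recordings behind published tables of this kind are rarely
deposited, so the package ships forward models for every input class;
their defaults are the study conditions of the worked reproduction:

* `gen_titration()` — Langmuir-true titrations at 5–240 µM. Noise is
  applied in potential space and then mapped through the Boltzmann relation
  (boundary space) or the inverted ratiometric calibration (dipole space),
  so fitted-residual assumptions match the space the analysis averages in.
* `gen_single_channel_trace()` — continuous-time two-state Markov gating
  (exponential dwells, stationary initial state), amplitude $gV$, additive
  Gaussian noise, and a fourth-order causal Butterworth low-pass standing
  in for the acquisition chain (5 kHz sampling, 1 kHz cutoff by default).
  The filter topology is a simulation choice; Butterworth is used because
  it is the causal design available in the underlying signal library, and
  the analysis stages are insensitive to the distinction at these
  bandwidths.
* `gen_macroscopic_trace()` — a step-and-relax record: constant baseline,
  then exponential approach (τ = 20 s default) to baseline × fold-change.
* `gen_thermogram()` — two-state van't Hoff melting,
  $C_p(T) = \frac{\Delta H_{vH}^2}{R T^2}\frac{K}{(1+K)^2}$ with
  $K = \exp\!\big(\frac{\Delta H_{vH}}{R}(1/T_m - 1/T)\big)$, scaled to a
  target calorimetric area, plus a broad Gaussian pretransition, linear
  baseline and optional noise. The half-height condition
  $K/(1+K)^2 = 1/8$ gives the closed-form width
  $\mathrm{FWHM} = 2\ln(3+2\sqrt{2})\,R T_m^2/\Delta H_{vH}
  \approx 3.5255\,R T_m^2/\Delta H_{vH}$, exposed as `vant_hoff_fwhm()` /
  `vant_hoff_enthalpy_for_fwhm()`. The $1/T^2$ prefactor shifts the
  apex below $T_m$ by $\sim 4R^2T_m^3/\Delta H_{vH}^2$ — negligible
  (< 0.001 °C) for cooperative lipid transitions, a few hundredths of a
  degree only for the broadest peaks in the property sweep.

Every generator is deterministic under a fixed seed. What the generators do
**not** emulate: channel-to-channel conductance variability (the dominant
width of experimental amplitude histograms), open-channel excess noise,
multi-peak substates, baseline wander, nystatin pore-assembly kinetics, and
asymmetric or multi-component DSC peaks. Round-trip tests therefore
demonstrate that the analysis stages are correct and unbiased inverters of
the stated forward models — not that they would be this accurate on every
real recording.

## The reproduction run

`reproduce_tables()` regenerates the full synthetic study: all Langmuir
rows (three inhibitors × POPC, POPC/Chol, POPC/POPG boundary titrations
plus POPC dipole titrations), the four gramicidin conductance levels with
their increments, the three nystatin fold-changes, and the DSC control and
treated feature sets. Each estimate is compared with its generator truth —
noiseless round trips at 10⁻⁴ relative, the stochastic single-channel
chain at 0.3 pS, activity ratios at 1%, DSC temperatures at 0.02–0.03 °C —
and the run reports `pass = TRUE` only if every cell is within tolerance.
Output is a full-precision `report.csv` plus a readable `report.md`; two
runs with the same seed are byte-identical. Where a desorption constant is
not documented for a condition (dipole and POPC/POPG rows), the POPC value
is reused as generator truth — this affects only the synthetic curve
shape, not the recovered plateau.

Problem sizes were chosen to keep a full run light: 60 s single-channel
records (≈ 200 events each; amplitude work conventionally uses 500–1000
events, and the peak-mean tolerance of 0.3 pS is met comfortably at 200),
400 s macroscopic records at 100 Hz, and 0.01 °C thermogram grids.

## Known limitations

* The half-amplitude detector targets single-level pores; substate analysis
  and missed-event (dwell-time) corrections are out of scope.
* Conductance histograms of synthetic single-channel records are much
  narrower than experimental ones, because per-channel variability is not
  modeled; the χ² test is then often infeasible on default bins (fit
  returned with `NA` goodness of fit).
* Absolute dipole potentials depend on instrument calibration constants;
  only differences are comparable across setups.
* The Langmuir machinery assumes a single adsorption class; charged-lipid
  systems are treated empirically, without Gouy–Chapman surface-potential
  modeling.
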