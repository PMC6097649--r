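---
title: "Passive cable modelling of D1 and D2 medium spiny neurons: models, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive cable modelling of D1 and D2 medium spiny neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models the package implements, the assumptions
behind them, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical and design choices that
were genuinely open. It states no empirical result that the test-suite and
`scripts/acceptance.R` do not themselves compute.

## The scientific problem

Medium spiny neurons (MSNs) are the principal projection neurons of the
striatum, split into direct-pathway (D1 dopamine receptor-expressing) and
indirect-pathway (D2) populations. In the aged Q175 heterozygous mouse model
of Huntington's disease, D1 MSNs remodel selectively: their dendritic
arbors become longer and more branched in the 20–100 µm annulus around the
soma, thin spines are lost while stubby spines accumulate, and spontaneous
excitatory currents become rarer. Because dendrites filter synaptic charge
on its way to the soma, these structural changes have electrical
consequences that cannot be read off anatomy alone. The package provides
the quantitative chain from reconstructed (or synthetic) morphology to those
electrical consequences: passive compartmental simulation,
frequency-domain electrotonics, synaptic simulation under voltage clamp,
feature extraction mirroring the experimental analyses, and the
group-comparison statistics.

## Passive compartmental model

Dendrites are passive cables with fixed specific membrane capacitance
`Cm = 0.9 µF/cm²`, axial resistivity `Ra = 100 Ω·cm`, specific membrane
resistance `Rm = 17.3 kΩ·cm²` and leak reversal `E_L = −84.4 mV`
(`passive_params()`), giving a membrane time constant
`τ_m = Rm·Cm = 15.57 ms`. These are the mean values obtained by fitting
passive models of reconstructed MSNs to subthreshold recordings from the
same cells; they are deliberately identical across groups so that simulated
group differences are attributable to morphology alone. Spine surface area
is not added to the membrane, and no voltage-gated conductances are
included: `simulate_model()` exposes the solver hook where conductances
would enter, but the package ships passive-only, because the question it
addresses is what dendritic geometry, by itself, does to signalling.

Each section is discretized into the smallest odd number of equal-arc
compartments whose length does not exceed 1/100 of the section's
electrotonic length constant at 100 Hz, where
`λ(f) = λ_DC / Re√(1 + iωτ_m)` and `λ_DC = √(Rm·d/4Ra)` with the section's
length-weighted mean diameter. The odd-count rule keeps a collocation point
at each section midpoint. Compartment membrane areas are computed from the
morphology's own tapered-cylinder pieces, so total membrane area is
conserved exactly; axial resistances integrate `4Ra/(πd²)` through the
linear taper. The soma is a single isopotential spherical-equivalent
compartment (surface-preserving), because reconstruction-level soma detail
is neither available nor needed for these questions.

Integration is second-order implicit (Crank–Nicolson) with a fixed 0.05 ms
default step; each step solves the branched system directly with a
tree-ordered (Hines) elimination, so stiffness never constrains the step.
Synaptic conductances are evaluated at step midpoints. Voltage clamp is
ideal — the clamped node's row is replaced by the command value and the
electrode current is recovered from the nodal balance — because no electrode
model is described for the simulations being mirrored. Convergence is
property-tested: halving the step or quadrupling the compartment count
changes somatic voltages by well under 1%.

## Electrotonics

The frequency-domain analysis does not use the discretized model at all: it
applies the exact hyperbolic recursion for sealed-end tapered cables to the
traced geometry, segment by segment (`impedance_tree()`). For each segment,
`γ(ω) = √(1 + iωτ_m)/λ_DC` and `Z_∞ = R_∞/√(1 + iωτ_m)` with
`R_∞ = (2/π)√(Rm·Ra)·d^(−3/2)`; input impedances fold leaf-to-root through
`Z = Z_∞ (Z_L + Z_∞ tanh γl)/(Z_∞ + Z_L tanh γl)`, terminal tips are sealed,
and the soma's RC membrane loads the root. Voltage-transfer factors
`V_far/V_near = Z_L/(Z_L cosh γl + Z_∞ sinh γl)` chain along paths in both
directions, giving the outward attenuation `L_out(x) = ln|V(soma)/V(x)|`
(source at the soma) and inward attenuation `L_in(x) = ln|V(x)/V(soma)|`
(source at `x`). Log attenuations add along paths, which is what makes the
morphoelectrotonic transform (`met_transform()`) well defined: every segment
is redrawn with length proportional to its incremental `L`.

The discretized time-domain engine then serves as an independent oracle:
the test-suite checks that steady-state sinusoidal amplitude ratios and
input impedances from simulation agree with the closed forms within 2% at
0, 100 and 500 Hz on random trees, and with textbook cylinder formulas
(`R_∞ coth(l/λ)`, `ln cosh(l/λ)`) within 1%.

Two averaging schemes are provided for the mean attenuation profile because
the choice is not uniquely determined by common usage: the default averages
`L` over all root-to-tip paths (one value per terminal tip — tips are the
unambiguous endpoints of "all traversed paths"), and a per-point scheme
averages over every traced point. The scheme is recorded in the output
rather than silently fixed. The frequency grid defaults to 0–500 Hz in
25 Hz steps, the band into which somatic spikes and synaptic events
decompose.

One physical point deserves emphasis because it is easy to get wrong: under
an ideal somatic voltage clamp, the recorded EPSC scales with the transfer
impedance `Z_tr(x)` (clamp current `= i_syn·Z_tr/Z_in(soma)`), not with the
unclamped voltage attenuation. The test-suite therefore checks the
consistency of time- and frequency-domain attenuation by regressing
`ln(EPSC amplitude)` on `ln|Z_tr|` at the event's dominant frequency
(`1/(2π√(τ_rise·τ_decay))`), where it finds unit slope.

## Synapses and EPSC analysis

Synapses are AMPA-type double-exponential conductances
`g(t) ∝ e^(−t/τ_decay) − e^(−t/τ_rise)` normalised so the peak equals
`g_max` for *either* ordering of the time constants — the fitted empirical
values (`g_max = 0.21 nS`, rise 2.29 ms, decay 1.80 ms) have rise larger
than decay, so no ordering may be assumed — with reversal at 0 mV, and the
alpha-function limit taken when the constants are within 1%. Note the
double exponential is exactly invariant under exchanging its two time
constants: the pair is identifiable only as an unordered set, and
`fit_synapse_params()` documents its result accordingly.

`place_synapses()` supports uniform-per-length density placement and exact
per-region counts, with "proximal/medial/distal" defined as equal thirds of
the maximum traversed path distance (mirroring how dendrites were selected
for imaging). `sequential_activation()` activates each synapse once at
50 ms intervals under somatic clamp and records baseline-to-peak amplitudes
(baseline = median of the 5 ms before each event), flagging responses that
have not decayed. `fit_distance_decay()` regresses `ln(amplitude)` on
distance with group interaction terms, reporting per-group space constants.

`fit_synapse_params()` is two-stage. Stage 1 adjusts `g_max`, `τ_rise`,
`τ_decay` so the simulated mean single-event somatic EPSC matches the
target; when the caller supplies the averaged event waveform the match is
least squares on the waveform (well conditioned up to the τ exchange),
otherwise on the scalar amplitude/rise/decay statistics. Twin optimizer
starts cover both τ orientations. Stage 2 tunes the per-synapse Poisson
rate by bisection until the *detected* somatic frequency over a 50 s
interval (by default) matches the target within 2%; the candidate event
streams are drawn once at a high rate and thinned, so the objective is
deterministic and monotone in the rate. A frequency-matching window of
50 s carries ~9% Poisson counting noise at 2 Hz; round-trip tests that need
tighter rate recovery therefore lengthen the window (a parameter), which
is a property of the estimator's sampling error, not of the fit.

EPSC detection (`detect_epscs()`) inverts and lightly smooths the clamp
current (0.75 ms boxcar), takes local maxima at or above the 5 pA threshold
(the stated maximum RMS noise of the recordings), and counts near peaks
separately only when each rises a full threshold above the inter-peak
minimum. Rise and decay time constants are fitted on the averaged aligned
event, as in the mirrored analysis; per-event 20–80% rise times are also
reported. On pure 2.5 pA RMS noise the false-event rate is below 0.05 Hz.

## Feature extraction

The extractors operationalise the experimental definitions: `Vr` is the
pre-stimulus mean; `Rn` the slope of the best-fit line through the linear
portion of the steady-state V–I relation, with "linear portion" defined by
iteratively dropping the largest-|I| point until R² ≥ 0.99 or three points
remain (the original analysis left this to the analyst); `τ` from a
single-exponential fit to the −10 pA response (log-linear seed refined by
nonlinear least squares); rheobase as the injected current at the first
spike on a 10 s dual ramp (0–100 then 0–200 pA), so cells whose rheobase
exceeds 200 pA are flagged unavailable exactly as they would be in the rig;
AP features from the second spike of the weakest 200 ms step with at least
three spikes. Spike threshold is the voltage where dV/dt first exceeds
20 mV/ms — a standard operational surrogate for the manual cursor
measurement — computed on a 0.25 ms-smoothed derivative so recording noise
cannot fake the criterion. Steady state for steps is the mean of the last
25% of the step.

## Synthetic data: what it emulates and what it does not

Every generator is seeded, draws all randomness from its seed without
touching global RNG state, and returns its own ground truth so that
extractors can be held to account.

**Electrophysiology.** Per-cell true values are drawn from normal
distributions whose means, SEMs and sample sizes are the published
per-group values (SD reconstructed as `SEM·√n`, since only SEM and n are
printed). The trace generator is phenomenological: an RC subthreshold
membrane with the drawn `Vr`, `Rn`, `τ`; a quasi-static V–I relation that
steepens smoothly near threshold so that the drawn rheobase (a current) and
the drawn AP threshold (a voltage) are honoured simultaneously — in real
MSNs the same reconciliation is performed by near-threshold inward
currents; stylized triangular action potentials with exact recorded
threshold, amplitude, rise and fall; and a linear rate-versus-current rule
above rheobase (0.15 Hz/pA default). Voltage noise defaults to 0.3 mV SD,
current noise to 2.5 pA RMS (at most half the detection threshold), both
configurable. EPSC trains are Poisson with lognormal amplitudes
(CV 0.4 by default — only means are published, and lognormal guarantees
positivity) and double-exponential kinetics (rise 2 ms, decay 6 ms,
typical of somatic AMPA events). Passing tests on these traces certify the
extractors against known truth; they do not certify behaviour on artifacts
the generator omits (electrode drift, series-resistance error, seal
instability, biological spike-shape variability).

**Morphology.** Trees grow outward in 5 µm steps with direction jitter;
tips bifurcate with a path-distance-dependent rate and stop at a drawn
maximal extent (mean 185 µm). At each bifurcation one child continues at
near-parent calibre toward the drawn extent while the other forms a
shorter, thinner side branch (16–45 µm, about half the parent diameter) —
the pattern seen in real MSN arbors, where higher-order branches taper and
terminate early. Group configurations differ only where the anatomy
differs: the Q175-D1 configuration raises the bifurcation rate in the
20–100 µm window (0.05/µm versus 0.013/µm), and the Q175-D2 configuration
adds a weak distal (130–150 µm) elaboration. These generator parameters are
**calibration outputs**, documented as such: no numeric morphometry means
were published (the comparisons are plots and significance statements), so
the defaults were chosen once to land total length in the realistic MSN
range (~1.2–1.8 mm) and to reproduce the published group *orderings* —
greater length, nodes and endings in Q175-D1 concentrated at 20–100 µm,
no significant D2 totals difference with a modest 130–150 µm increase.
They are not presented as measurements. The thin-side-branch growth rule is
also what gives the generator its published electrotonic signature: short
thin side branches add membrane load near the soma (which lowers the
whole-cell input impedance and deepens *inward* attenuation at every tip)
while contributing little outward path attenuation — so inward attenuation
at 400–500 Hz separates the groups while outward attenuation does not, the
direction the modelling of the real reconstructions found.

**Spines and puncta.** Spines are placed beyond the 20 µm aspinous zone
with per-subtype densities (wild type: 0.55 thin, 0.35 mushroom, 0.15
stubby, 0.03 filopodia per µm; Q175-D1: 0.36 thin, 0.25 stubby, others
unchanged — thin loss with stubby gain at roughly conserved mushroom
density). Shaft apposition densities per channel are the published group
values (read as per-µm; the printed "per mm" unit is three orders of
magnitude below one punctum per imaged dendrite and is taken as a typo),
and the Vglut1:Vglut2 ratio lands near the published 1.5:1. Punctum
geometry is simplified to a straight shaft with offset heads; apposition
calling operates on xy footprints and z-slice spans, not on image stacks.

## Statistics

`compare_two()` gates on Shapiro–Wilk at α = 0.05 per group (t-test with
pooled variance when both pass, Mann–Whitney otherwise) and records which
path ran. The two-way genotype × cell-type analysis is an ordinary
between-subject linear-model ANOVA with interaction and Type II sums of
squares for unbalanced cells; the original report labels it
"repeated-measures", but the design has no repeated factor and the printed
degrees of freedom match a between-subject layout, so that is what is
implemented. The post hoc family is the four contrasts of interest
(genotype within each cell type, cell type within each genotype), with no
multiple-testing correction by default (none was described; Holm is
available). `median_ci_overlap()` implements the percentile-bootstrap 95%
CI of the median used to justify pooling sexes and lines. `firing_glm()`
regresses firing rate on genotype, cell type, rheobase, input resistance
and injected current with pairwise interactions, dropping aliased terms.

## Numerical choices and degenerate inputs

* Zero-length or negative-diameter sections, missing SWC parents, and
  parent cycles are hard errors at read time; morphoelectrotonic output is
  the one place zero drawn lengths are legal.
* Sealed tips are represented exactly (`coth`/`1/cosh` limit forms), not by
  large finite loads.
* The synapse peak-normalisation uses the analytic peak time
  `t_p = τ_r τ_d/(τ_d − τ_r)·ln(τ_d/τ_r)`, valid for both orderings; the
  alpha limit replaces it within 1% of equality.
* Event times are quantised to the integration step (≤ 0.05 ms error at the
  default step).
* The V–I "linear portion" prune stops at three points; τ fits fall back
  from nonlinear to log-linear if the optimizer fails.
* `findInterval`-based Sholl shells are half-open `[r, r + w)`; the
  innermost count at radius zero is defined as the number of primary
  dendrites.

## Problem sizes used in the checks

The packaged acceptance checks run cohorts of 25 morphologies per group for
attenuation comparisons, 4 models per group with 45 synapses each for the
distance-decay comparison, 2 models per group with 300 synapses each for
the EPSC floor, published per-measure sample sizes (up to 89 cells per
group) for the significance-pattern check, 50-cell cohorts for extractor
error, and a coarsened (λ/33) model with 45 synapses for the synapse-fit
round trip. These sizes were chosen as the smallest that leave the
stochastic checks well-powered.

## Known limitations

* Dendrites are passive; the somatic active-conductance hook ships empty,
  so simulated spikes and rheobase live only in the phenomenological
  generator, never in the cable model.
* The soma is a sphere; axons, spine membrane area and spine-neck
  resistance are not modelled.
* The significance-pattern check inherits the replication mathematics of
  the published effect sizes: comparisons published near p ≈ 0.02–0.05
  rerun on fresh draws at the same n are significant only ~40–65% of the
  time, so the joint pattern across all measures reproduces in a minority
  of seeds. The per-measure directions, by contrast, are stable. Rheobase
  is the extreme case: reconstructing per-cell SDs as `SEM·√n` implies that
  about a quarter of wild-type D1 cells exceed the 200 pA ceiling of the
  dual-ramp protocol; those cells are flagged unavailable exactly as in the
  rig, and the censoring nearly erases the group difference — evidence that
  the published rheobase distribution was not normal with that SD. The
  package keeps the documented conventions rather than tuning around the
  inconsistency. See the acceptance suite for the exact check.
* The apposition geometry is a cartoon (straight shaft, circular
  footprints); it validates the calling rules, not image segmentation.
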