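---
title: "Methods: atropisomer stability, kinetics and chiroptical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atropisomer stability, kinetics and chiroptical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atropos)
```

# Scope

`atropos` implements the desk-scale statistics of an atropisomer
characterization campaign for axially chiral small molecules — the kind of
biaryl-like chiral axis found in colchicine's AC ring system. Five analysis
stages are covered: torsional-profile processing and barrier extraction,
racemization kinetics and Eyring analysis, Boltzmann-weighted VCD
(vibrational circular dichroism) processing and absolute-configuration
assignment, dihedral occupancy analysis of trajectory-derived time series,
and NCI-60-style growth-inhibition statistics. The quantum-chemistry,
molecular-dynamics and wet-lab instruments that produce the raw inputs are
out of scope; a synthetic-data module generates statistically controlled
stand-ins for all of them, so every stage is testable end to end with known
ground truth.

# Torsional profiles and barrier extraction

A torsional profile maps the chiral-axis dihedral chi to a relative energy.
Iterative relaxed scans are typically run over a raw window such as
180–540°; `fold_to_principal()` maps angles by
`chi' = ((chi + 180) mod 360) − 180` into (−180, 180]. The two scan
endpoints fold onto the same angle but need not be isoenergetic (the scan
can end on a different methoxy rotamer than it started on); the lower
energy is kept. Folding validates full-circle coverage by requiring the
largest folded angular gap to be no more than twice the median gap.

Because poses at chi and −chi are enantiomeric and hence exactly
isoenergetic, `symmetrize_enantiomers()` replaces each mirror pair by its
pointwise minimum, reporting on [0, 180]. Profiles are always re-referenced
so the minimum is 0 kcal/mol.

`locate_stationary_points()` finds local extrema by discrete comparison
with periodic neighbours and refines each by a 3-point parabolic fit
through the extremum and its two grid neighbours. The parabolic refinement
is this package's choice for sub-grid precision on a 10° grid: the vertex
of the interpolating quadratic is exact for locally quadratic wells, and on
realistic cosine-series profiles it recovers ground-state dihedrals to a
few hundredths of a degree (the test suite cross-checks refined barriers
against dense 0.1° brute-force scans, which serve as the oracle, never as
the production path). Flat triples (three equal energies) are reported at
the grid point with a flatness flag.

`enantiomerization_barrier()` connects the global-minimum dihedral chi_g to
its mirror image −chi_g along the two rotation paths — through the planar
syn orientation (0°) or the anti orientation (±180°) — and returns the
lower of the two path maxima relative to the refined ground-state energy,
with the path label and refined transition dihedral. A profile whose global
minimum sits at 0 or 180° has no chiral axis and is rejected.

`free_energy_barrier()` assembles a free-energy barrier from
stationary-point records carrying electronic energies and thermal
free-energy corrections, enforcing the standard vibrational validation: a
ground state must have zero imaginary frequencies and every transition-state
candidate exactly one. `classify_axis()` maps a barrier to the medicinal
chemists' stability classes with half-open boundaries
[0, 22) / [22, 30) / [30, ∞) kcal/mol. The half-open upper boundary keeps a
30.2 kcal/mol axis in class 3 — consistent with describing such a barrier
as sitting at the frontier of class 3 — and a 22.1 kcal/mol axis in
class 2.

```{r torsion-example}
gen <- gen_torsion_profile(chi0 = 101.1, syn_barrier = 35,
                           anti_barrier = 30.2, increment = 10)
bar <- enantiomerization_barrier(fold_to_principal(gen$profile))
bar
classify_axis(bar$barrier)
```

# Racemization kinetics

The kinetic model is first-order interconversion of the two enantiomers
with a one-way microscopic rate k, so the enantiomeric excess decays as
`ee(t) = ee0 · exp(−2kt)`. The factor of two — racemization is observed at
twice the enantiomerization rate — is applied consistently: fitted slopes
of `ln|ee|` versus t equal −2k, and all barriers are computed from the
one-way k. This convention is stated prominently because conflating the
two rates shifts every barrier by `RT ln 2` (about 0.6 kcal/mol at 135 °C).

The Eyring equation `k = κ (k_B T / h) · exp(−ΔG‡ / RT)` uses
R = 1.987204 × 10⁻³ kcal mol⁻¹ K⁻¹, k_B/h = 2.083661 × 10¹⁰ s⁻¹ K⁻¹ and
transmission coefficient κ = 1 (the universal default when no value is
known). `eyring_rate()` and `barrier_from_rate()` are exact inverses.

`fit_rate_from_timecourse()` regresses `ln|ee|` on time, unweighted by
default. When the measurement error is additive on ee with constant
standard deviation — the usual situation for detector-limited
chromatographic peak areas — the log-transformed noise is heteroskedastic
with variance ∝ 1/ee²; the `weights = "inverse-variance"` option applies
weights proportional to the squared predicted ee from a preliminary
unweighted fit. Points with |ee| at or below 10⁻⁶ are treated as noise that
crossed zero and dropped with a warning.

`eyring_regression()` fits `ln(k/T)` against 1/T (slope −ΔH‡/R, intercept
`ln(k_B/h) + ΔS‡/R`) and reports `ΔG‡(T_ref) = ΔH‡ − T_ref · ΔS‡`. With the
three or so temperatures typical of racemization studies, a residual-based
covariance would rest on one degree of freedom and its ±2σ interval would
cover far below nominal; when every rate carries a standard error (as
rates from `fit_rate_from_timecourse()` do), the parameter covariance is
instead propagated from those per-rate uncertainties through a
fixed-variance sandwich. The test suite verifies calibration by simulation:
over 200 replicates at three temperatures and 1% ee noise the ΔG‡ bias is
below 0.05 kcal/mol and ±2σ coverage is at least 90%. A single-temperature
fit returns `ΔG‡ = barrier_from_rate(k)` with ΔH‡ and ΔS‡ undefined; both
modes exist because published barriers rarely state how many temperatures
were used.

`min_barrier_from_no_racemization()` converts a null observation — no
detectable ee loss after heating for a given duration — into a barrier
lower bound via `k_max = −ln(1 − d)/(2 · duration)` at detection threshold
d. The default d = 0.02 (2% ee loss) reflects typical chiral-HPLC
integration precision. The result is a lower bound ("the barrier is at
least this large"), even though informal usage sometimes reports such
projections as "the" barrier.

```{r kinetics-example}
eyring_rate(31.2, celsius_to_kelvin(135))
min_barrier_from_no_racemization(celsius_to_kelvin(145), 10 * 3600, 0.02)
```

# Boltzmann weighting and VCD

Conformer populations follow `w_i ∝ exp(−ΔE_i/RT)` with either free or
electronic energies (both weightings are common and comparing them is a
useful robustness check). Conformers contributing less than the threshold
(default 1%) are dropped and the rest renormalized — the conventional
reporting cutoff. Weighted spectra are pointwise convex combinations on a
common grid; grids are merged by linear interpolation onto the finer grid
restricted to the overlap.

Experimental VCD blocks are processed exactly as the standard dual-PEM
measurement protocol prescribes: block-average each enantiomer, form the
half-difference (Ē1 − Ē2)/2 — which cancels instrument baseline common to
both enantiomers and doubles the chiral signal-to-noise — and offset to
zero at an anchor wavenumber (default 2000 cm⁻¹, a signal-free region).
The output is exactly zero at the anchor by construction.

Computed harmonic frequencies overestimate band positions, so calculated
spectra are x-axis scaled before comparison; typical factors for hybrid
functionals with triple-zeta bases fall in 0.968–0.985. The search mode
scans σ ∈ [0.96, 1.00] in steps of 0.001, maximizing similarity to a
reference spectrum.

Spectral similarity is the normalized inner product (a Carbó-like index)
over a stated window, 1000–1700 cm⁻¹ by default (the mid-IR fingerprint
region). Commercial VCD-comparison software uses proprietary similarity and
confidence metrics; the normalized inner product is the standard open
substitute and is documented as such. It is symmetric, scale-invariant in
each argument, and bounded in [−1, 1]. `assign_configuration()` compares
the experimental VCD with the calculated aR spectrum and its negation (the
aS prediction); the sign winner gives the assignment and the similarity
difference the margin, with margins below 0.1 (configurable) declared
inconclusive rather than forced to a call.

Aggregation (e.g. hydrogen-bonded dimers of tropone-bearing compounds)
mixes a second component into the observed VCD.
`fit_mixture_fraction()` models the observation as
`s · ((1 − f) · monomer + f · aggregate)` and minimizes the squared
residual over the scale s > 0 and fraction f ∈ [0, 1]; for fixed f the
optimal scale is closed-form, leaving a 1-D bounded search. This convex
two-component model with a single global scale and no baseline term
(baselines are handled upstream by anchoring) is this package's
operationalization of "combining" monomer and dimer spectra; the dimer
basis spectrum is an input, never computed here. Proportional basis spectra
make f unidentifiable and are rejected.

# Dihedral occupancy

Trajectory-derived dihedral series are binned into left-closed windows
`[k·w, (k+1)·w)` anchored at 0° on the full circle and reported at folded
midpoints (so 5° windows give midpoints like 82.5°); counts are conserved
across the ±180° seam. Summaries are circular: the mean is
`atan2(mean sin, mean cos)`, the spread `sqrt(−2 ln R̄)`, and the range is
the smallest arc containing all observations — a naive min/max would be
meaningless for seam-straddling data, and whether published "ranges" are
circular is often unstated, so the convention is fixed here and documented.
The arithmetic-versus-circular choice for the "average" is likewise
resolved in favour of the circular mean. `compare_states()` adds the
circular shift between modal bins and the histogram overlap coefficient
`Σ min(p_bound, p_unbound)`.

The synthetic sampler is a Metropolis chain on the circle targeting
`exp(−E(chi)/RT)` with Gaussian proposals of 5° and 10% burn-in, with
profile energies interpolated linearly and periodically. A 5° random walk
mixes slowly (traversing 360° takes on the order of (360/5)² steps), so
convergence assertions about its histograms are made in expectation over
several seeds rather than on one arbitrary chain.

# Growth-inhibition statistics

The five-dose screen reduction follows the published NCI-60 conventions,
implemented here as external conventions rather than novel methodology:
percent growth `PG = 100(Ti − Tz)/(C − Tz)` for net growth and
`100(Ti − Tz)/Tz` for net kill; GI50/TGI/LC50 as the concentrations where
PG crosses +50/0/−50, interpolated linearly in log10 concentration; levels
with no crossing censored at the nearest tested bound, never fabricated.
Mean-graph statistics use the geometric mean (censored entries contribute
their bound, flagged), the selectivity range is max − min in log units, and
COMPARE-style correlations are Pearson r over the mean-graph deltas of
common cell lines with censored lines dropped (the delta construction
makes r invariant to per-compound potency shifts, isolating the
selectivity pattern), significant above r = 0.5. Whether published COMPARE
runs used deltas or raw values, and how they handled censored lines, is
generally unstated; deltas with censored lines dropped is this package's
documented choice.

# The synthetic-data module

Every generator is seed-deterministic and returns its ground truth
alongside the data, so each analysis stage closes a recovery loop.

* **Torsional profiles** are 3-term cosine series
  `E = Σ c_n (1 + cos n·chi)` with coefficients solved from stationarity
  at ±chi0 and the two barrier heights relative to the well. Three terms
  is the minimal basis reproducing the qualitative shape of biaryl-like
  axes: planar and perpendicular maxima, two enantiomeric minima, and
  syn/anti barrier asymmetry. An optional `asym · sin(chi)` term breaks
  the mirror symmetry to emulate scan hysteresis; Gaussian energy noise is
  additive.
* **Racemization courses** apply the exact first-order decay with rates
  from the Eyring equation, additive Gaussian ee noise (the instrument's
  integration error is approximately amplitude-independent), and a 10⁻⁶
  ee floor. Default study conditions mirror a variable-temperature
  campaign: 12 points over 5 ee half-lives per temperature, 1% noise.
* **Spectra** are sums of Lorentzians `A γ² / ((ν − ν_i)² + γ²)` — the
  natural lineshape for solution IR bands — with signed VCD amplitudes;
  the aS enantiomer negates the VCD and leaves the IR unchanged.
* **Dihedral series** come from the Metropolis sampler above.
* **Screen panels** are linear latent-mechanism models
  `fingerprint = base + loadings · mechanisms + residual`, which makes the
  implied pairwise correlations available in closed form.

Gaussian additive noise is used throughout because no error model is
available for the emulated instruments and Gaussian noise makes recovery
tolerances analyzable. What passing tests show is therefore that the
analysis stages are correct and statistically calibrated under these
idealized conditions; real scans carry correlated hysteresis errors, real
VCD baselines drift nonlinearly, and real screen fingerprints have heavier
tails, none of which the generators emulate.

# Numerical choices and problem sizes

Tolerances and sizes used by the tests and drivers, chosen as realistic
desk-scale settings: scan increments of 10° with 0.1° brute-force oracle
grids; Eyring round-trip tolerance 10⁻⁹ kcal/mol; 200-replicate
calibration runs for kinetics and 100-seed loops for mixture fractions and
screen correlations; Metropolis chains of 10⁵ samples for density
convergence and 2 × 10⁴ for the occupancy drivers; 1 cm⁻¹ synthetic
spectral grids with 5 cm⁻¹ experimental-style output. Degenerate inputs are
rejected with specific errors (achiral profiles, proportional mixture
bases, zero-variance fingerprints, sub-floor ee points) rather than
returning misleading numbers.

# Known limitations

Single-rotor profiles only: coupled rotors and multi-dimensional torsional
surfaces are out of scope. The kinetics assume equal-well first-order
enantiomerization without tunneling corrections. The mixture model is
two-component with one global scale. Dihedral analysis consumes
pre-extracted angle tables, not trajectories. None of the quantum-chemical
quantities (energies, VCD rotational strengths, dimer spectra) are
computed here — they are inputs, and the synthetic module's stand-ins are
labelled as such.
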