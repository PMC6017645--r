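---
title: "Models and methods behind sbdnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sbdnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

sbdnmr quantifies weak protein--peptide binding from solution-NMR
observables, in the setting typified by the Hsp70 substrate-binding domain
(SBD) binding its model peptide NRLLLTG: millimolar affinity, slow exchange
on the chemical-shift timescale, and intensity-based readout from 2D
¹H--¹⁵N HSQC spectra. This vignette explains the models the package fits,
the assumptions behind them, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Intensity-based titration and the ligand-depletion isotherm

Under slow exchange a titration does not shift peaks; it redistributes
intensity between separate free-state and bound-state signals. The package
fits the *loss* of free-state intensity: for residue $r$ at total ligand
concentration $L$,

$$ f_\mathrm{bound}(L) \;=\; 1 - \frac{I_r(L)}{I_{0,r}}
   \;=\; \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2P}, $$

the exact single-site mass-action solution with ligand depletion ($P$, $L$
are total concentrations, mM throughout). At millimolar $K_D$ and
sub-millimolar protein the depletion correction is not optional: at the
reference conditions (0.3 mM protein) the free-ligand and total-ligand
curves differ substantially over the titration range, and the hyperbolic
approximation would bias $K_D$ upward.

`fit_kd()` minimises the summed squared deviation between observed and
model bound fractions over *all* selected residues and titration points
with a single shared $K_D$ and no per-residue nuisance parameters: the
reference intensity $I_{0,r}$ is taken from the zero-ligand spectrum, so
each residue's curve is already normalised. The optimisation is a bounded
one-dimensional search (`stats::optimize`) over $K_D \in [10^{-4}, 10^3]$
mM at an absolute tolerance of $10^{-8}$ mM; a 1-D bounded search cannot
miss the global minimum of this unimodal objective, which avoids
multi-start machinery entirely. Residues are selected by the intensity
ratio at a reference titration point (default 1.2 mM):
$I(1.2\,\mathrm{mM})/I_0 < \overline{\mathrm{ratio}} - 0.8\,\sigma$, with
sample standard deviation ($n-1$) and both the multiplier and the reference
point configurable. The ratio statistics are computed over all residues
present in the reference table. The weighting of the global fit is
deliberately uniform (unweighted least squares); residue-level uncertainty
enters through the Monte-Carlo step instead, in which every intensity
(including $I_0$) is resampled from $\mathcal{N}(I, \sigma_I)$ and the fit
repeated — the spread of replicate $K_D$ values is the reported
uncertainty. Replicates default to 1000 and the seed is mandatory, so
results are exactly reproducible.

Degenerate input (no residue showing decaying intensity) cannot identify
$K_D$; the fit warns and pins the estimate at the upper search bound rather
than returning an arbitrary interior value.

## Two-site exchange lineshapes and the kinetic bound

The exchange module implements the closed two-site Bloch--McConnell system
free $\leftrightarrow$ bound with pseudo-first-order kinetics: populations
are fixed by the equilibrium bound fraction at the stated total
concentrations, the free→bound rate is
$k_{fb} = k_\mathrm{off}\, p_b/(1-p_b)$ (detailed balance holds exactly),
and both states share the single average transverse relaxation rate
quoted for binding-engaged residues (21 s⁻¹). The absorption spectrum is
the real part of the steady-state solution
$S(\nu) = \mathrm{Re}\,[\mathbf{1}^{\!\top}(2\pi i\nu I - A)^{-1}\mathbf{p}]$
with $A = i\Omega - R_2 + K$, evaluated in closed form for the 2×2 system
on a frequency grid (default ±300 Hz around the free resonance at 0.05 Hz
spacing). Peak positions and heights are refined by three-point parabolic
interpolation through each grid maximum. Each unit-population absorption
Lorentzian integrates to ½ in Hz units, so the total integral equals half
the total magnetization regardless of $k_\mathrm{off}$ — a conservation
check the tests enforce to 1%.

The kinetic bound inverts this simulation: `max_koff_for_shift()` bisects
on $k_\mathrm{off}$ (absolute tolerance 0.1 s⁻¹) for the largest rate at
which the *displacement of the free-peak maximum* from its no-exchange
position stays within a stated tolerance (5 Hz in the reference analysis).
Loss of a resolved free peak — merged lines, or departure from slow
exchange ($k_\mathrm{ex} \ge 2\pi\,\Delta\nu$) — is treated as exceeding
the tolerance. A subtlety worth stating: the displacement of the
*absorption maximum* is not the displacement of the eigenvalue frequencies
of $A$. With broad lines (R₂ = 21 s⁻¹, FWHM ≈ 6.7 Hz against a 58 Hz
separation) overlapping tails and eigenvector mixing pull the maximum
several times further than $\mathrm{Im}(\lambda)/2\pi$ moves. The package
deliberately uses the peak-maximum displacement — that is the quantity an
experimentalist reads off a simulated or measured spectrum, and it is what
reproduces a ≈30 s⁻¹ bound at the reference parameters, whereas an
eigenvalue-based criterion would allow rates more than twice as large.
Correspondingly, the eigenvalue oracle in the test suite validates peak
extraction where the equivalence is exact — narrow lines (R₂ = 2 s⁻¹) and
weak exchange ($k_\mathrm{off} \le 5$ s⁻¹) — and the full lineshape is
treated as authoritative outside that regime.

$k_\mathrm{on}$ is derived as $k_\mathrm{off}/K_D$ with the mM→M
conversion made explicitly at that interface. Regime classification calls
exchange slow below $k_\mathrm{ex} = 2\pi\Delta\nu$ (the same boundary
that defines when a free peak exists) and fast above $5\cdot 2\pi\Delta\nu$.

## Relaxation and heteronuclear NOE

R₁/R₂ series are fitted as $I(t) = A e^{-Rt}$ — two parameters, no
baseline offset — by Levenberg--Marquardt (minpack.lm) initialised from
the log-linear regression of the positive intensities. Delays are stored
in ms (the reference schedules, with their duplicated points, ship as
`delays_r1()`/`delays_r2()`); rates are reported in s⁻¹. The noise
estimate comes from the duplicated delays: for duplicate differences
$\Delta_j$, $\sigma = \sqrt{\mathrm{mean}_j(\Delta_j^2)/2}$, since each
difference of two equally noisy measurements has variance $2\sigma^2$.
Monte-Carlo rate uncertainties resample all points with that $\sigma$ and
refit. The heteronuclear NOE is the plain ratio
$I_\mathrm{sat}/I_\mathrm{unsat}$ with first-order error propagation of
the spectral noise through the ratio.

## PRE profiles

PRE analysis here is intentionally qualitative, matching how the
measurement is used for this system: ratios $I_\mathrm{para}/I_\mathrm{dia}$
per residue with propagated uncertainties, three proximity classes, and a
signed apo-vs-bound comparison flagging residues whose ratio change
exceeds twice the combined uncertainty ("closer" when the ratio drops).
The class thresholds (bleached < 0.1, attenuated < 0.85) are the package's
operationalisation of the usual distance statements for a nitroxide label
— complete bleaching inside roughly 10 Å, detectable attenuation to
roughly 25 Å — because the underlying reports give distances, not ratio
cut-offs; both are configurable arguments, not constants. No conversion of
ratios to Γ₂ rates or distances is attempted. Residues with good
diamagnetic signal but no detectable paramagnetic peak are reported as
candidate-bleached rather than silently dropped, and residues present in
only one spectrum are reported missing, never as zero.

## Ensemble geometry

NMR depositions order models by energy, so "the 10 lowest-energy
structures" is implemented as the first 10 MODEL records and "the
lowest-energy structure" as MODEL 1 — both overridable. Author residue
numbering is used directly. Distances are plain Cα--Cα Euclidean norms;
summaries are per-model values with mean and sample sd, and a single-model
summary reports sd 0 and carries an explicit flag. Parsing is delegated to
bio3d behind the module surface, with pre-validation providing the error
contract (no ATOM records; unbalanced MODEL/ENDMDL), alternate locations
other than blank/'A' dropped, and insertion codes rejected (absent from
the relevant entries). For multi-chain crystal files the default chain is
the first one containing both residues of a pair; when the two molecules
of an asymmetric unit disagree, run the query once per chain. The
deposited reference ensembles themselves are not redistributed with the
package; the deposited-structure comparison in the test suite runs only
when the user supplies those files locally, and all geometry code is
otherwise exercised against synthetic ensembles with constructed truths.

## What the generators emulate — and what they do not

Every generator is a pure function of its configuration including a
mandatory seed, and each fitting module has a round-trip test consuming
generator output.

* `gen_titration()` defaults to the reference study conditions: seven
  ligand points (0.075--6.0 mM) into 0.3 mM protein, 28 responsive
  residues, 3% Gaussian intensity noise. Noise is additive on peak-table
  intensities, emulating at table level what a spectral-region sd measures
  on the spectrum. Bound-state peaks are not generated, matching the
  fitting model's exclusive use of free-state losses.
* `gen_relaxation()` produces exponential decays at the reference delay
  schedules (duplicates included) with 2% noise by default.
* `gen_pre()` owns the forward distance→ratio model:
  $\Gamma_2 = K r^{-6}$,
  $\mathrm{ratio} = R_2/(R_2+\Gamma_2)\, e^{-\Gamma_2 t}$, with $K$
  calibrated at run time so a residue 10 Å from the label has ratio 0.02;
  under the defaults (R₂ = 21 s⁻¹, t = 1 ms) this puts a 25 Å residue near
  0.9. A pure exponential-in-$\Gamma_2$ law cannot satisfy both anchors at
  once under an $r^{-6}$ dependence; the amplitude factor supplies the
  long-range tail. Distances are measured from the label residue's Cβ (Cα
  fallback) to each amide's Cα proxy on model 1.
* `gen_ensemble()` jitters a template (by default an ideal-helix trace
  with Cα/Cβ atoms) with isotropic Gaussian noise and applies optional
  whole-residue displacement vectors so pairwise-distance truths are known
  by construction.
* `gen_itc()` and `fit_itc()` share one forward model: a well-stirred
  overflow cell in which each injection displaces an equal volume
  ($c \to c(1 - v/V_0) + c_\mathrm{syr}\, v/V_0$) and the heat of
  injection $i$ is
  $q_i = \Delta H\, V_0\, ([PL]_i - [PL]_{i-1}(1 - v/V_0))$. The default
  run is 25 × 1.5 µL of 5 mM peptide into 200 µL of 0.1 mM protein with
  stoichiometry fixed at $n = 1$ — at millimolar affinity the isotherm
  cannot resolve $n$, so only $(K_D, \Delta H)$ are fitted, with
  $\Delta H$ profiled out analytically (the model is linear in it) and
  $K_D$ found by bounded search on $\log_{10} K_D$. The first injection is
  included; no blank subtraction is modelled.

None of the generators simulate full 2D spectra, peak overlap,
assignment errors, baseline distortions, or temperature effects (the
relaxation data's nominal temperature is metadata only). Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artefact of real spectra.

## Problem sizes and numerical defaults

The recovery studies the package ships run at the sizes a desk check
warrants: 20-seed batches for titration and relaxation recovery, 400--1000
Monte-Carlo replicates, 50 regenerations for the
uncertainty-vs-spread comparisons, and 0.01--0.05 Hz lineshape grids —
each chosen as the smallest size at which the corresponding statistic is
stable to well within its test tolerance. Ties in peak-centre selection
round half away from zero; the ¹⁵N axis frequency is fixed at 0.10132905
of the ¹H frequency; peak tables are written with 17 significant digits so
doubles round-trip exactly.

## Known limitations

Chemical-shift-based (fast-exchange) titration fitting, multi-site or
cooperative binding, CPMG/CEST dispersion, model-free relaxation analysis,
Γ₂-based PRE distance restraints, and structure superposition are all out
of scope. The exchange simulation is strictly two-site with a single
shared R₂; three-site topologies and ¹⁵N-dimension exchange are not
modelled. The statements about the reference system's kinetics depend on
the stated 58 Hz separation and 21 s⁻¹ average rate; both enter as plain
arguments, so sensitivity to them is easy to explore.
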