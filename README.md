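# sbdnmr

Quantitative NMR interaction analysis for weakly binding protein–peptide
systems, built around the solution-NMR characterisation of the Hsp70
substrate-binding domain (SBD) binding its model substrate peptide
(NRLLLTG). At millimolar affinity the complex exchanges slowly on the
chemical-shift timescale: titration redistributes intensity between
separate free and bound HSQC peaks instead of shifting them, so the
dissociation constant must be extracted from intensity losses with an
exact ligand-depletion isotherm, and kinetic information comes from how
far exchange displaces the free-state line. This package implements that
analysis chain for spectroscopists and structural biologists working on
weak complexes:

* **Titration fitting** — global single-site K_D from per-residue
  free-peak intensities, using the exact mass-action bound fraction
  f = [(P+L+K_D) − √((P+L+K_D)² − 4PL)] / 2P, a σ-based
  responsive-residue selection criterion, and Monte-Carlo uncertainties
  (`fit_kd`, `select_responsive_residues`, `kd_uncertainty_mc`).
* **Two-site Bloch–McConnell lineshapes** — absorption spectra of the
  free↔bound system, the largest k_off compatible with a bound on the
  free-peak displacement, k_on = k_off/K_D, and exchange-regime
  classification (`simulate_lineshape`, `max_koff_for_shift`,
  `kon_from_koff_kd`, `classify_regime`).
* **¹⁵N relaxation and hNOE** — mono-exponential R₁/R₂ fits at the
  reference delay schedules with duplicate-based Monte-Carlo errors, and
  noise-propagated heteronuclear NOE ratios (`fit_relaxation`,
  `rate_uncertainty_mc`, `heteronuclear_noe`).
* **PRE profiling** — paramagnetic/diamagnetic intensity ratios with
  propagated errors, bleached/attenuated/unaffected proximity classes, and
  signed apo-vs-bound comparisons (`pre_profile`, `compare_pre_states`).
* **ITC** — single-site calorimetric isotherm with stoichiometry fixed at
  n = 1 and an overflow-cell dilution model (`fit_itc`).
* **Ensemble geometry** — Cα-distance statistics over NMR structural
  ensembles and apo/bound ensemble comparisons (`read_pdb_ensemble`,
  `ensemble_distance`, `compare_ensembles`).
* **Synthetic data** — seeded generators for every stage
  (`gen_titration`, `gen_relaxation`, `gen_pre`, `gen_ensemble`,
  `gen_itc`), each with a known generating truth, so the whole chain is
  testable without any external data.

Peak tables, manifests, ITC heats and spectral grids travel as small
tab-separated text files; structures as standard PDB. `inst/scripts/sbdnmr-cli.R`
is a thin command-line front-end over the exported run functions
(`run_fit_kd`, `run_koff_bound`, `run_fit_relax`, `run_pre`,
`run_ens_dist`, `run_itc_fit`, `run_lineshape`).

## Worked example

```r
library(sbdnmr)

## a synthetic titration at the reference conditions: 7 peptide points
## (0.075-6 mM) into 0.3 mM protein, 28 residues, 3% intensity noise,
## generating K_D = 1.3 mM
sim <- gen_titration(kd_true = 1.3, seed = 7, noise_frac = 0.03)
fit <- fit_kd(sim$series, mc_replicates = 500, seed = 8)
fit
#> Global single-site K_D fit (ligand-depletion isotherm)
#>   K_D: 1.356 mM +/- 0.03 mM (Monte Carlo)
#>   residues: 28, titration points: 7, RSS: 0.2149

## kinetic bound: largest k_off keeping the free-peak displacement below
## 5 Hz at dnu = 58 Hz, R2 = 21 s^-1, 0.3 mM protein + 3.0 mM peptide
res <- run_koff_bound(58, 21, 0.3, 3.0, 1.3, 5, out_dir = tempdir())
res$max_koff   # 33.95  (s^-1)
res$kon        # 26115  (M^-1 s^-1)
res$regime     # "slow"
```

The fitted K_D recovers the generating 1.3 mM within its Monte-Carlo
uncertainty; the kinetic bound says that any dissociation rate above
~34 s⁻¹ would displace the free-state ¹H line by more than 5 Hz at these
populations, and the derived association rate ~2.6 × 10⁴ M⁻¹ s⁻¹ places
the system firmly in the slow-exchange regime (k_ex ≈ 107 s⁻¹ against
2πΔν ≈ 364 rad s⁻¹).

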