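# bindassay

Models and fitters for the quantitative side of a multi-assay biophysical
characterisation of an EF-hand calcium sensor (NCS-1) and its partner, the
Gα chaperone/GEF Ric-8A — and, more generally, for any system studied with
the same toolbox: multi-site calcium titrations by ITC, monovalent-cation
fluorescence titrations, biolayer-interferometry (BLI) sensograms,
GTPγS-binding nucleotide-exchange kinetics, nano-DSF thermal-shift melts,
and protein–peptide interface analysis from crystallographic coordinates.

## What it computes

**Sequential three-site binding equilibrium.** A macromolecule M binds
ligand L in ordered stoichiometric steps,

    M + L ⇌ ML₁ + L ⇌ ML₂ + L ⇌ ML₃ ,

step *i* governed by the stepwise dissociation constant *K*ᵢ and enthalpy
ΔHᵢ. The solver inverts the ligand mass balance exactly (bisection on the
binding polynomial), yielding free ligand, the species fractions *f*₀…*f*₃,
and per-class site availabilities Θᵢ = Σ_{j<i} *f*ⱼ. Free energies use
ΔGᵢ = −RT ln(1/*K*ᵢ) with R = 1.986 cal/mol/K.

**ITC.** A VP-ITC forward model (discrete perfusion dilution, heat-content
differences with a mean-heat displacement correction) and a six-parameter
Levenberg–Marquardt fitter (*K*₁–₃ in log space, ΔH₁–₃ linear) that
reproduces the sequential-model analysis of calcium isotherms.

**1:1 models.** Fluorescence saturation titrations
(y = y_max·L/(K_d+L), with a linear alternative and AICc model selection);
BLI sensograms (Langmuir association/dissociation, global fit with shared
k_off, K_d = k_off/k_on, with weak-identifiability flagging); exchange
progress curves (single/double exponential) feeding the one-site activation
hyperbola v = v₀ + v_max[Ca²⁺]/(K_a+[Ca²⁺]).

**Thermal shift.** Two-state van 't Hoff melt curves of the 350/330 nm
fluorescence ratio and first-derivative inflection-temperature (Ti)
detection with Savitzky–Golay smoothing.

**Interface analysis.** Contact census at a distance cutoff (default
4.2 Å), donor–acceptor hydrogen-bond detection (direct and water-mediated),
per-residue contact shares, and buried surface area by Shrake–Rupley
quadrature, from PDB coordinates.

Every assay has a synthetic-data generator with known ground truth and
deterministic seeding, so each fitting stage is testable offline.

## Worked example

Simulate a calcium ITC isotherm under the sodium-buffer ladder
(K_d = 265/758/379 nM, ΔH = −7.7/+3.0/−9.1 kcal/mol), then fit it from
3-fold-perturbed starting values:

```r
library(bindassay)

truth <- seq_binding_model(kd = c(265e-9, 758e-9, 379e-9),
                           dh = c(-7.7, 3.0, -9.1))
iso <- simulate_isotherm(truth)   # default VP-ITC protocol
fit <- fit_sequential_itc(iso, seq_binding_model(truth$kd * 3, truth$dh * 3))
fit
#> Sequential ITC fit (converged, rss = 6.782e-21)
#>   step 1: Kd = 2.65e-07 M, dH = -7.7 kcal/mol
#>   step 2: Kd = 7.58e-07 M, dH = 3 kcal/mol
#>   step 3: Kd = 3.79e-07 M, dH = -9.1 kcal/mol
```

All six generating parameters are recovered to better than 1 ppm: on
noiseless data the simulate-and-fit round trip is exact to optimiser
tolerance. The same pattern holds for the other assays:

```r
fit_saturation_1to1(gen_titration(123.4e-3, noise_sd = 0))
#> 1:1 saturation fit: Kd_app = 0.1234 M (SE 2.2e-17), ymax = 1, rss = 1.93e-32

detect_ti(two_state_ratio_curve(tm = 53.5, dh_vh = 100))
#> Detected Ti: 53.5 degC
```

The first call recovers the 123.4 mM apparent Na⁺ dissociation constant
from a noiseless 0–300 mM titration; the second detects the 53.5 °C
inflection temperature of a synthetic two-state melt as the peak of the
smoothed first derivative.

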