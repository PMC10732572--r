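---
title: "Binding, kinetics and stability models in bindassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding, kinetics and stability models in bindassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindassay)
```

bindassay implements the quantitative models behind a multi-assay
characterisation of a calcium-regulated protein–protein interaction: an
EF-hand sensor whose calcium loading state gates recognition of a partner
peptide. This vignette is the package's own account of those models — the
assumptions they make, the parameters that matter, the numerical choices,
and what the synthetic-data tests do and do not demonstrate.

## The sequential binding equilibrium

The core model is the stoichiometric sequential ladder

$$\mathrm{M} + \mathrm{L} \rightleftharpoons \mathrm{ML}_1 + \mathrm{L}
  \rightleftharpoons \mathrm{ML}_2 + \mathrm{L} \rightleftharpoons \mathrm{ML}_3,$$

parameterised by stepwise dissociation constants $K_i$ (molar) and per-step
enthalpies $\Delta H_i$ (kcal/mol). *Stepwise* means the constant for adding
the $i$-th ligand to $\mathrm{ML}_{i-1}$ regardless of which physical site
binds: the model deliberately does not resolve microscopic (site-specific)
constants, which would require additional information (e.g. NMR or
site-directed mutants). For a sensor with three functional EF-hands this is
the natural ITC-level description.

With overall association constants $\beta_i = \prod_{k \le i} 1/K_k$, the
fraction of macromolecule carrying exactly $i$ ligands at free-ligand
concentration $l$ is $f_i = \beta_i l^i / \sum_k \beta_k l^k$
($\beta_0 = 1$). The only nontrivial computation is inverting the ligand
mass balance

$$ l + M_\mathrm{tot} \, \langle n \rangle(l) = L_\mathrm{tot}, \qquad
   \langle n \rangle(l) = \frac{\sum_i i\,\beta_i l^i}{\sum_i \beta_i l^i}. $$

The left side is strictly increasing in $l$ on $[0, L_\mathrm{tot}]$, so we
solve by bisection to a relative tolerance of $10^{-12}$ — slower than
Newton but unconditionally convergent, which matters inside a least-squares
loop that may visit extreme parameter values. Polynomial terms are built by
the cascade $t_i = t_{i-1}\,l/K_i$ so intermediates stay within double
range even for nanomolar constants.

**Site availability.** For titration displays we report
$\Theta_i = \sum_{j<i} f_j$: the probability that binding step $i$ has not
yet occurred. This is a *stoichiometric-step* availability. A site-specific
alternative (availability of a particular EF-hand) is not computable from
stepwise constants at all, which is why the definition is recorded in the
returned object's metadata rather than left implicit.

**Free energies** use $\Delta G_i = -RT\ln(1/K_i)$ with
$R = 1.986$ cal/mol/K — the convention of the calorimetric analysis being
reproduced, kept verbatim rather than replaced by the CODATA value so that
derived numbers match published tables digit for digit. 25 °C maps to
298.15 K.

## The ITC forward model and fitter

A VP-ITC perfusion cell of volume $V_0$ (default 1.4619 ml) holds
macromolecule at $M_0$ (default 110 µM) and is titrated with syringe ligand
at $c_s$ (default 1.5 mM). Each injection of volume $v_j$ displaces cell
liquid, so after $j$ injections

$$ M_j = M_0 \prod_{k\le j}\Big(1 - \frac{v_k}{V_0}\Big), \qquad
   L_j = c_s \Big(1 - \prod_{k\le j}\Big(1 - \frac{v_k}{V_0}\Big)\Big). $$

The cell's binding heat content is
$H_j = V_0 M_j \sum_i \big(\sum_{k \le i}\Delta H_k\big) f_{i,j}$ and the
measured heat of injection $j$ is

$$ q_j = H_j - H_{j-1} + \frac{v_j}{V_0}\,\frac{H_j + H_{j-1}}{2}, $$

normalised per mole of injectant, $q_j/(c_s v_j)$. The second term corrects
for enthalpy content carried out in the displaced volume, using the mean of
the adjacent heat contents; commercial packages use closely related but
unpublished corrections, so this convention is an explicit, documented
approximation. Dilution heats are treated as negligible (they were measured
separately and found so in the experiments this reproduces). With one
active step the model collapses to the closed-form single-site (Wiseman)
isotherm, which the tests verify to $10^{-6}$ relative.

The injection schedule is not part of published tables; the default is the
standard VP-ITC practice of a small 2 µl pre-injection (simulated but
excluded from fitting) followed by 28 × 10 µl injections, fully
configurable via `itc_protocol()`.

**Fitting.** `fit_sequential_itc()` minimises
$\sum_j (q_j^{obs} - q_j^{model})^2$ by Levenberg–Marquardt with $K_i$ in
$\log_{10}$ space (positivity, scale-invariance) and $\Delta H_i$ linear.
If the first start fails, a multistart over $K_i \times \{0.1, 10\}$ is
tried. Standard errors come from the linearised Jacobian at the optimum; no
bootstrap by default. An all-zero isotherm is returned with
$\Delta H \approx 0$ and an explicit unidentifiability flag rather than a
spurious fit.

**Identifiability at realistic noise.** Noiseless round trips recover all
six parameters to optimiser tolerance ($<10^{-6}$ relative). At 2% noise
(relative to the largest per-mole heat) the picture changes: the linearised
information bound at the sodium-ladder parameters under the default
schedule puts the best achievable relative errors near 40–60% for the three
$K_i$ and 3/45/17% for $\Delta H_{1-3}$. This is a property of the
experiment design (28 heats, six strongly correlated parameters), not of
the optimiser, and the test suite asserts that the fitter's scatter stays
within ~2× that bound rather than pretending tighter recovery is possible.
Practically: single-isotherm stepwise constants at this noise level carry
large uncertainties, which is worth remembering when comparing published
tables fitted from single titrations.

## 1:1 models: fluorescence, BLI

**Fluorescence titrations** of tryptophan emission against cation
concentration are fitted as $y = y_\mathrm{max}\,L/(K_d + L)$ with free ≈
total ligand — justified because the cation (mM range) exceeds protein
(10 µM) by ≥10³. Signals are normalised intensity changes; the package fits
the magnitude $|I - I_0|/I_0$ and records the raw sign in metadata, since
published conventions mix "enhancement" language with $(I_0 - I)/I_0$
normalisation and the fitted $K_d$ is invariant to that sign. A linear
model is fitted alongside and `select_binding_model()` chooses by corrected
AIC, with ties going to the line (parsimony): this formalises the
saturating-sodium vs linear-potassium contrast as a reproducible decision
rather than a visual one. A fitted $K_d$ more than 50× beyond the titrated
range is flagged unidentifiable — the curvature needed to pin it simply is
not in the data.

**BLI sensograms** follow the 1:1 Langmuir model: association
$R(t) = R_{eq}(1 - e^{-k_{obs}t})$ with $k_{obs} = k_{on}C + k_{off}$ and
$R_{eq} = R_\mathrm{max} C/(C + K_d)$; dissociation
$R(t) = R(t_a)e^{-k_{off}t}$. The global fit shares $k_{off}$ across both
phases with equal weighting (vendor software objectives are proprietary;
equal weighting is the neutral choice) and reports
$K_d = k_{off}/k_{on}$ exactly. Two failure modes are flagged rather than
silently reported: a response far from saturation ($R_{eq}/R_\mathrm{max}$
outside [0.05, 0.995]), where $k_{on}$ and $R_\mathrm{max}$ trade off
freely, and kinetics faster than the sampling interval
($k_{obs}\,\Delta t > 1$), where the trace degenerates to a step and the
rate constants are not determined by the data. The second is exactly what
happens for a mM-range affinity probed at 50 µM analyte: the package
reports the fit but marks it weakly identifiable, mirroring how such
values should be read — order-of-magnitude estimates, not precise
constants. An independent cross-check, `kobs_linear_analysis()`, fits
single exponentials at several concentrations and regresses
$k_{obs}$ on $C$ (slope $k_{on}$, intercept $k_{off}$); the tests require
the two routes to agree within 1%.

## Exchange kinetics and calcium activation

GTPγS-binding progress curves are fitted as
$F(t) = F_0 + \sum_i a_i(1 - e^{-k_i t})$ with one or two phases; starting
rates come from the log-linearised approach to plateau. For biphasic
curves the rates are sorted and the *slow* rate taken as the
catalysed-exchange estimate — a fixed convention from the underlying
assays, where the fast phase reflects GTPγS binding to a pre-formed
intermediary complex, not re-derived per dataset. `choose_exponential_model()`
compares orders by corrected AIC with ties to the single exponential.

Rates across a CaCl₂ series are corrected by subtracting the intrinsic
(uncatalysed) rate *matched exactly on concentration* — a missing match is
an error, never an interpolation — and fitted to the one-site activation
hyperbola

$$ v = v_0 + v_\mathrm{max}\,\frac{[\mathrm{Ca}^{2+}]}{K_a + [\mathrm{Ca}^{2+}]}. $$

The assay concentration sets (0, 1, 10, 25, 50, 500 µM, optionally with
sub-micromolar points) anchor $v_0$ at zero calcium and bracket typical
$K_a$ values well; the tests verify that the recovered $K_a$ is invariant
to the arbitrary $v_0$ and $v_\mathrm{max}$ over a 3×3 grid, so the
activation constant can be compared across conditions with different
absolute rates.

## Thermal shift

Nano-DSF melt curves are modelled as a two-state transition of the 350/330
fluorescence ratio with linear baselines:

$$ \mathrm{ratio}(T) = B_F(T) + (B_U(T) - B_F(T))\,\theta_U(T), \quad
   \theta_U = \frac{1}{1 + \exp[(\Delta H_{vH}/R)(1/T - 1/T_m)]} $$

($T$ in kelvin). The instrument's internal model is unpublished; this
standard van 't Hoff form has the right qualitative behaviour (midpoint at
$T_m$, sharpness set by $\Delta H_{vH}$) and is the basis for synthetic
curves only — equality with instrument-reported values is only ever
asserted on curves *built from* those values. Detection mirrors the
instrument's described readout: smooth (local quadratic Savitzky–Golay,
default 1.5 °C window on the 0.1 °C grid), differentiate, and report peaks
of the derivative magnitude above a prominence threshold (default 5% of
the derivative range). A derivative that is essentially constant — pure
baseline — returns no transitions. Multiple transitions are supported, as
in a two-protein complex melt; resolvability of nearby midpoints (e.g.
~3 °C apart) depends on transition sharpness, which the two-transition
test makes explicit by generating with a large $\Delta H_{vH}$. Sloped
baselines bias a raw derivative peak; the detector reports the raw-peak
position by default, matching the instrument-style readout.

## Interface analysis

Contacts between two chain selections are all heavy-atom pairs within a
cutoff (default 4.2 Å), waters and ions excluded; every convention is a
toggle because published interface censuses rarely state theirs, so
deposited-structure numbers can be bracketed rather than asserted.
Hydrogen bonds use donor/acceptor typing over N/O (and S) atoms of the
standard residues with a 3.5 Å distance criterion; the angular test is
applied only when explicit hydrogens exist, which crystal structures at
typical resolution lack. Water bridges (one water within range of a polar
atom on each side) are available behind a flag. Buried area is
$(\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB})/2$ with SASA by
Shrake–Rupley quadrature over a deterministic golden-spiral point set
(default 960 points/atom, converging to <0.5% on doubling) and Bondi vdW
radii. The tests pin the census to an $O(n^2)$ brute-force oracle, rigid-
motion invariance, and the analytic two-sphere spherical-cap formula.

## Synthetic data and what passing tests mean

Every generator emits the exact model curve at `noise_sd = 0` and additive
Gaussian noise otherwise, with per-dataset seeds derived from
(master seed, assay, replicate) so studies are reproducible and
parallelizable. Ground truth travels as an attribute of the returned
object — metadata a fitter never reads. Default noise levels (ITC 2% of
the largest heat; titration/BLI 2% of amplitude; exchange 3%; melt 0.5% of
the ratio range) are chosen to resemble published trace scatter and are
arbitrary in that sense.

The generators emulate the *study conditions*: the published cell/syringe
concentrations and injection schedule, 0–300 mM titration grids, 300 s
association/dissociation at 50 µM analyte, the printed CaCl₂ series, and
35–95 °C melts on a 0.1 °C grid. They do not emulate instrument raw
signals (power compensation traces, interference spectra), slow drifts,
correlated noise, active-concentration errors, mass-transport limitation,
or aggregation during melting. A passing round trip therefore shows that
the estimation chain is correct and well-conditioned under its own model —
it does not certify accuracy on real data where those un-modelled effects
live. The identifiability flags (BLI weak-identifiability, ITC zero-signal,
fluorescence no-curvature, activation no-amplitude) are the package's way
of keeping that boundary visible at run time.

Problem sizes used by the test suite — 10⁴ random draws for the
equilibrium invariants, 12 noisy ITC replicates, 200 fluorescence
replicates, 100 exponential-fit replicates, 100 random toy complexes — are
the package's own balance of coverage against run time; all are plain
constants in the tests and scale up trivially.

## Known limitations

- Stepwise constants only; no microscopic site assignment, no Mg²⁺
  competition, no Hill-type cooperativity.
- The ITC displacement correction is a stated convention, not the
  (unpublished) vendor formula; concentrations are taken at nominal values
  with no active-fraction ("site") correction.
- BLI: no mass-transport or heterogeneous-ligand models; single-analyte
  traces only.
- Thermal shift: no unfolding thermodynamics beyond the van 't Hoff shape;
  no scan-rate correction.
- Interface: no symmetry-mate generation, no interface-significance
  scoring, no electrostatics.
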