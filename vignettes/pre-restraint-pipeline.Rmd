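---
title: "From paramagnetic relaxation enhancements to docking restraints"
author: "premap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paramagnetic relaxation enhancements to docking restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premap)
```

# The problem

Transient protein–protein complexes — such as the interaction between a
peptidyl carrier protein (PCP) domain and the condensation domain of a
nonribosomal peptide synthetase — are often too weak and too dynamic for
conventional NOE-based structure determination. Two NMR observables carry
long-range and interface information even in this regime:

* **Paramagnetic relaxation enhancements (PREs).** A nitroxide spin label
  coupled to an engineered surface cysteine broadens nearby nuclear
  resonances. The extra transverse relaxation rate $\Gamma_2^H$ scales as
  $r^{-6}$ in the electron–nucleus distance and is measurable out to
  roughly 15–35 Å, making it ideal for positioning a partner domain.
* **Chemical shift perturbations (CSPs).** Titration of a binding partner
  shifts the resonances of interface residues, mapping the binding surface
  without long-range geometric content.

`premap` implements the full analysis chain from peak intensities to
docking restraints: PRE quantification under three measurement protocols,
conversion to distances with the Solomon–Bloembergen model-free (SBMF)
formalism, CSP interface mapping with active/passive classification,
ambiguous interaction restraints (AIRs), and assembly, filtering and export
of distance-restraint sets — together with a synthetic-data generator that
provides ground truth for every stage.

# PRE quantification

## Measurement protocols

Three protocols are supported, matching how PREs are measured in practice
on a paramagnetic sample and its ascorbate-reduced diamagnetic reference:

1. **Two time points** (`pre_two_point()`): each sample is measured as a
   two-plane pseudo-3D relaxation experiment with delays $\tau_1$ and
   $\tau_2$ (defaults 0 and 10 ms), and
   $\Gamma_2^H = -\ln(I_\mathrm{ratio,para}/I_\mathrm{ratio,dia})/\Delta\tau$.
2. **Single time point, volumes** (`pre_volume_ratio()`): when peak
   volumes are reliable,
   $\Gamma_2^H = -\ln(V_\mathrm{para}/V_\mathrm{dia})/\Delta$, where
   $\Delta$ is the total fixed delay during which $^1$H magnetization is
   transverse (10.3 ms for the amide HSQC, 7.7 ms for the methyl HMQC
   defaults used here).
3. **Single time point, heights** (`forward_height_ratio()` /
   `invert_height_ratio()`): methyl HMQC peak heights depend on the PRE
   through both the fixed-delay attenuation and the line broadening in both
   dimensions,
   $$\frac{I_\mathrm{para}}{I_\mathrm{dia}} = e^{-\Gamma_2^H\Delta}
   \frac{(R_{2}^{MQ}+\pi LB_1)(R_2^H+\pi LB_2)}
   {(R_2^{MQ}+\pi LB_1+c\,\Gamma_2^H)(R_2^H+\pi LB_2+\Gamma_2^H)},$$
   where $c = 1+(\gamma_C/\gamma_H)^2 \approx 1.063$ accounts for the
   $^1$H/$^{13}$C multiple-quantum coherence of the indirect dimension.
   The factor $c$ is always computed from the bundled gyromagnetic ratios,
   never hard-coded.

The height model cannot be inverted in closed form, but it equals 1 at
$\Gamma_2^H=0$ and decreases strictly, so the numerical inverse is unique.
We bracket the root (geometric expansion starting at $10^3\,
\mathrm{s^{-1}}$), refine with Brent's method (`stats::uniroot`) and polish
with Newton steps on the log-ratio until the residual on the ratio is below
$10^{-12}$. Round trips are exact to better than $10^{-6}$ relative over
$\Gamma_2 \in [0.1, 500]\ \mathrm{s^{-1}}$.

Edge-case policy: apparent ratios marginally above 1 are pure noise and are
clamped to $\Gamma_2=0$ with status `no_pre`; peaks absent from the
paramagnetic spectrum are flagged `bleached` and excluded from restraint
building (they indicate proximity, but without a quantifiable rate).
Probes split into free/bound peaks are combined by summing component
intensities (`merge_split_peaks()`) before the ratio is formed.

Diamagnetic reference rates come from exponential fits to relaxation decay
series (`fit_exponential_decay()`; nonlinear least squares with log-linear
starting values) recorded on the standard 8-delay schedule
(0, 2, 5, 10, 15, 20, 30, 40 ms).

## Uncertainties

`monte_carlo_pre_uncertainty()` propagates the standard errors of
$I_\mathrm{para}$, $I_\mathrm{dia}$, $R_{2,\mathrm{dia}}^H$ and
$R_{2,\mathrm{dia}}^{MQ}$ by Gaussian resampling and re-inversion of each
replicate; the reported uncertainty is the $n-1$ standard deviation of the
replicate $\Gamma_2$ values. Replicates with non-positive intensities are
redrawn (truncation by redraw) and counted. The seed is a mandatory
argument: identical seeds give byte-identical results. The noise magnitude
itself is an input — whether it comes from the spectral noise floor or from
line-shape fit residuals is a choice the user must make, so it is not
defaulted.

# The Solomon–Bloembergen model-free conversion

For a nitroxide ($S = 1/2$) the transverse PRE is
$$\Gamma_2^H = \frac{\kappa_H}{r_{eN}^6}\left[4 J_\mathrm{SBMF}(0) +
3 J_\mathrm{SBMF}(\omega_H)\right], \qquad
J_\mathrm{SBMF}(\omega) = \frac{S^2\tau_1}{1+\omega^2\tau_1^2} +
\frac{(1-S^2)\tau_t}{1+\omega^2\tau_t^2},$$
with $1/\tau_1 = 1/\tau_m + 1/T_{1e}$ combining rotational diffusion and
electronic relaxation and $1/\tau_t = 1/\tau_1 + 1/\tau_i$ adding internal
tag motion. When internal motion is fast and $S^2 > 0.5$ the second
spectral-density term is negligible and the working expression becomes
$$\Gamma_2^H = \frac{\kappa_H}{r_{eN}^6} S^2 \tau_1
\left(4 + \frac{3}{1+\omega_H^2\tau_1^2}\right),$$
which `gamma2_from_distance()` and `distance_from_gamma2()` implement as
an exact inverse pair (the full two-term form is available via
`full = TRUE`).

**The prefactor.** $\kappa_H = (\gamma_H g_e \beta)^2 (\mu_0/4\pi)^2
S(S+1)/15$. The default constant bundle uses CODATA 2018 values for
$\gamma_H$, $\gamma_C$, $\beta$ and $\mu_0/4\pi$, and $g_e = 2.0$ for the
electron g-factor — the convention behind the numerical value universally
quoted in the PRE literature, $1.2311\times 10^{16}\ \mathring{A}^6
\mathrm{s}^{-2}$ (equivalently $1.23\times10^{-32}\ \mathrm{cm^6 s^{-2}}$).
The CODATA free-electron value $g_e = 2.002319\ldots$ is bundled as
`codata_electron_g()` and raises $\kappa_H$ by 0.23%; the corresponding
distance change is below 0.04% ($r \propto \kappa^{1/6}$), far inside the
6 Å restraint padding, so the choice is numerically immaterial for
restraints but matters for reproducing the printed constant.

```{r kappa}
signif(kappa_h(), 5)
round(mq_pre_factor(), 3)
```

**Defaults.** Restraint conversion uses $S^2 = 1.0$ and $\tau_1 = 20$ ns —
deliberately conservative: overestimating $S^2\tau_1$ overestimates the
distance, which is safe for upper-bound-only restraints.

## Tag ensembles and correlation-time fitting

A flexible spin label samples many conformations, and the PRE averages
$r^{-6}$ (not $r$) over them. `back_calculate_pre_profile()` therefore
computes $\langle r^{-6}\rangle$ from a conformer cloud
(`tag_site()`). The default cloud (`default_tag_conformers()`) places 10
points uniformly on a sphere of radius 7 Å centred 7 Å outward from the
attachment C$\beta$ along the C$\alpha\to$C$\beta$ direction — a
desk-scale stand-in for molecular-dynamics tag-ensemble optimization that
preserves the objective's shape (a 1-D profile in $\tau_1$ over fixed
geometry).

`fit_correlation_time()` minimizes the weighted squared difference between
measured and back-calculated PREs over $\tau_1 \in [5, 40]$ ns (the
physically sensible window for a system of this size). The optimization is
performed in nanoseconds so that the optimizer's absolute tolerance is
well-scaled, and the uncertainty comes from a seeded nonparametric
bootstrap over probes (default 500 resamples). On noiseless synthetic data
the generating $\tau_1 = 20$ ns is recovered to better than 0.1 ns; with
10% Gaussian noise on 50 probes the median error across seeds stays below
2 ns.

# CSP interface mapping and AIRs

CSPs combine the two amide channels as
$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (0.15\,\Delta\delta_N)^2}$.
Classification (`classify_residues()`) uses the mean and $n-1$ SD over all
scored residues (assigned, non-proline; unassigned residues are excluded,
never imputed):

* **active**: CSP ≥ mean + 1.5 SD *and* relative solvent accessibility
  above 15% (computed against Gly-X-Gly theoretical maxima);
* **passive**: CSP ≥ mean + 1 SD (not active), or intensity lost on
  binding while within the contiguity radius of an active residue.

Two rules required operationalization because "forms a continuous surface"
has no standard formal definition: an active residue must have another
classified residue with any atom within the contiguity radius (default
8 Å, about two residue diameters), otherwise it is demoted to passive; the
same radius defines "close to active" for intensity-loss residues. With
zero CSP dispersion the thresholds are unreachable and nothing is
classified (degenerate-input policy).

`build_airs()` emits one AIR per active residue, targeting the partner's
active ∪ passive set with an $r^{-6}$ effective distance
(`effective_distance()`, $(\sum d^{-6})^{-1/6}$) bounded above by 2.0 Å —
i.e. *some* atom of the active residue must contact the partner interface.

# Restraint assembly and filtering

`build_pre_restraints()` converts quantified PREs with intensity ratio
below 0.8 into proxy-atom restraints: amide N (or methyl C) of the
observed residue to C$\beta$ of the spin-label site. Ratios ≥ 0.8 carry
too little attenuation to yield a reliable distance and are marked
`filtered_ratio`. The derived distance plus an empirical 6 Å padding —
covering tag length and quantification error — becomes the upper bound;
the lower bound is 0 because sub-stoichiometric saturation always makes
the apparent PRE distance an overestimate.

`filter_encounter_satisfiable()` removes restraints that an
encounter-complex ensemble can already explain: a restraint satisfied in
*any* ensemble member is eliminated. The any-member rule is the
conservative anti-contamination choice — the final-complex restraint list
keeps only effects the encounter state cannot produce.

`add_connectivity_restraints()` supplies the three geometric restraints
used alongside the PREs: the inter-domain linker (C$\alpha$–C$\alpha$,
upper 59.5 Å), the phosphopantetheine-arm unfurling restraint (thiol S to
phosphate P, 14.0–16.5 Å) and the active-site reach restraint (thiol S to
the catalytic histidine C$\epsilon1$, upper 8.0 Å).

Export (`write_restraints()`) uses the CNS/Xplor assign-statement dialect
with the upper-bound-only encoding `d = upper`, `dminus = upper − lower`,
`dplus = 0`, which round-trips exactly through the bundled reader; a JSON
dialect retains full provenance.

# Solvent accessibility

No NACCESS-style program is assumed. `shrake_rupley_sasa()` implements
Shrake–Rupley sphere-point sampling with a deterministic golden-spiral
point set (960 points and a 1.4 Å probe by default; hydrogens ignored,
Bondi radii, all overridable). A single atom reproduces the analytic
sphere within 1%, well-separated atoms are exactly additive, and doubling
the point count changes totals by < 0.5%. Because the reference program's
exact parameters are unknown, classifications of residues *near* the 15%
relative-accessibility threshold may legitimately differ between SASA
engines; the threshold itself is a configuration value.

# The synthetic-data generator

`make_toy_complex()` builds two ideal poly-alanine helices (N, C$\alpha$,
C$\beta$ per residue; 100°/residue, 1.5 Å rise), places the second at a
chosen pose offset (default 25 Å, putting the interface in the PRE-informative
15–35 Å window), attaches tag conformer clouds to chain-B residues and
records per-probe ground truth ($\langle r^{-6}\rangle^{-1/6}$ distances
and PREs at $\tau_1 = 20$ ns, $S^2 = 1$, 850 MHz). The generator's tag
clouds use a compact geometry (shell radius 2.5 Å, offset 3.5 Å from
C$\beta$) so that the worst-case discrepancy between the true
electron–nucleus distance and the proxy C$\beta$ distance stays within the
6 Å padding — the same consistency the padding is meant to guarantee for a
real tag — which makes the zero-noise end-to-end run provably
violation-free against the generating pose.

`simulate_pre_dataset()` pushes the true PREs through the height forward
model, draws diamagnetic intensities around a nominal value and applies
*multiplicative* Gaussian noise (peak-height errors scale with intensity).
`simulate_csp_dataset()` plants an exponentially decaying CSP field
($|\Delta\delta| = A e^{-d/\lambda}$, defaults $A = 0.2$ ppm,
$\lambda = 5$ Å — typical amide-CSP magnitudes for a mid-affinity
interface) split in quadrature between the two channels with seeded random
signs. `simulate_decay_series()` provides exponential decay fixtures. All
randomness flows from explicit integer seeds; identical seeds give
byte-identical tables.

What the generator does *not* emulate: peak overlap and line shapes,
exchange broadening, incomplete saturation, NUS reconstruction artifacts,
side-chain packing and realistic SASA variation. Passing tests therefore
demonstrate the correctness of the quantification/conversion/filter
arithmetic and its statistical calibration — not robustness to
spectral pathologies of real data.

# The pipeline

`run_pipeline()` chains generate → simulate → extract → convert → filter →
validate from one schema-validated configuration (R list or YAML), writes
every artifact (peak table, extracted PREs, `.tbl` and JSON restraints,
true-pose PDB, machine-readable summary, resolved configuration) and
enforces count conservation at each stage
(`quantified + no_pre + bleached = probes`). Reruns with the same seed are
byte-identical. A thin command-line wrapper lives at
`inst/cli/pre2restraints.R`; the exported functions are the primary
interface.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 17), out_dir = tempfile())
res$summary
```

# Problem sizes and numerical choices

The bundled tests and the acceptance script run entirely on synthetic
problems sized for interactive use: 20–50 residue pseudo-domains, 3 tag
sites, 10-conformer clouds, 100-setting round-trip sweeps, 20-seed
recovery experiments and Monte Carlo runs of $10^2$–$2\times10^4$
replicates. These sizes were chosen so that each property being tested
(exact inversion, unbiased recovery, MC calibration within 25%) is already
stable; larger problems change nothing qualitatively.

Other numerical policies collected in one place: root-finding residual
tolerance $10^{-12}$ on the ratio; $\tau_1$ optimization in ns units with
tolerance $10^{-6}$ ns; sample statistics use $n-1$ throughout; ties in
altloc occupancy resolve to the first conformer in file order; restraint
sets preserve input order; the two distinct symbols named $\tau_1$ in the
field's notation (a relaxation *delay* in the two-point protocol, a
correlation *time* in the spectral density) live in different containers
(`acquisition_settings` vs `sbmf_parameters`) precisely to avoid
confusion.

# Known limitations

* Only the nitroxide dipolar PRE mechanism is modelled — no Curie-spin or
  cross-correlated contributions, no $^{15}$N PREs.
* The tag ensemble is a fixed geometric cloud; no co-optimization of
  conformers with $\tau_1$ against the data.
* CSP analysis is endpoint-based; exchange-regime modelling and $K_d$
  fitting are out of scope.
* Docking itself (and scoring/clustering of poses) is out of scope: the
  package produces and validates restraints.
* PDB input only (no mmCIF); SASA for proteins only.
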