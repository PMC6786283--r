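---
title: "Quantitative models behind the isoform biophysics workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative models behind the isoform biophysics workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isophys)
```

`isophys` implements the analysis chain used to differentiate two protein
isoforms that share all but their N-terminal domain — the MeCP2 E1/E2 pair
being the motivating case: equilibrium stability from thermal melts, DNA
binding thermodynamics from calorimetric titrations, turnover and mobility
from chase and FRAP kinetics, an exact nonparametric group comparison for
densitometry, and the peptide-evidence filter for co-immunoprecipitation
interactor lists. A seeded generator produces synthetic instrument-level
data with exactly the statistical structure each fit assumes, so every
estimator can be validated by parameter recovery.

## Two-state thermal unfolding

A melt curve is modelled as a folded/unfolded equilibrium read out through
an optical signal with linear baselines. The unfolding free energy follows
the Gibbs–Helmholtz form

$$\Delta G_U(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right) -
  \Delta C_{p,U}\left[(T_m - T) + T\ln\frac{T}{T_m}\right],$$

so the unfolded fraction $f_U = K_U/(1+K_U)$ with
$K_U = e^{-\Delta G_U/RT}$ is exactly one half at $T_m$. `fit_two_state()`
estimates $(T_m, \Delta H_m)$ and four baseline coefficients by
Levenberg–Marquardt least squares. $\Delta C_{p,U}$ is fixed at zero by
default: over the ~15 K transition window of a typical melt its curvature
contribution is not identifiable, and the study-style readout reports only
$T_m$ and the van't Hoff $\Delta H_m$. A free-$\Delta C_p$ mode exists for
wide scans.

Starting values are deterministic and data-driven: $T_m$ from the extremum
of a smoothed signal derivative (a curve whose extremum sits at the grid
edge is rejected as having no detectable transition), baselines from the
outer 15% of points at each end, and $\Delta H_m$ from the transition
slope via $df_U/dT|_{T_m} = \Delta H_m/(4RT_m^2)$. Fits are unweighted —
single-channel fluorimeters have effectively constant noise across the
scan. Temperatures are kelvin internally; files use Celsius with the exact
273.15 offset, and fitting a curve read from a Celsius file is identical
to fitting the in-memory kelvin object.

## Single-site calorimetric titrations

The titrant (a DNA duplex) is injected into the protein-containing cell of
an overflow calorimeter. With $\Delta V_i$ the cumulative injected volume
after injection $i$ and $V_0$ the cell volume, the standard
instrument-convention dilution gives cell concentrations

$$M_i = M_0\,\frac{1-\Delta V_i/2V_0}{1+\Delta V_i/2V_0},\qquad
  X_i = X_0\,\frac{\Delta V_i/V_0}{1+\Delta V_i/2V_0},$$

the bound complex is the stable root of the 1:1 quadratic mass balance,
and the heat of injection $i$ is

$$q_i = V_0\,\Delta H\,\big([MX]_i - [MX]_{i-1}(1 - v_i/V_0)\big) +
  q_{dil}\, n_{inj,i}.$$

The quadratic root is evaluated in the rationalized form
$2nM_iX_i/(b+\sqrt{b^2-4nM_iX_i})$, which is immune to the catastrophic
cancellation the textbook $(b-\sqrt{\cdot})/2$ form suffers far from
saturation; the forward model agrees with an independent iterative
mass-balance solver to better than $10^{-10}$ relative.

`fit_single_site()` estimates $(n, K_d, \Delta H, q_{dil})$ on normalized
heats, with $K_d$ parameterized on the log scale and a deterministic grid
of log-$K_d$ starts; the first injection is discarded by default
(syringe-diffusion convention). The heat of dilution is fitted as a free
offset in kcal per mol of injectant rather than subtracted from a blank
titration; under the study schedule (2 µL of 50 µM titrant, i.e.
$10^{-10}$ mol per injection) the default truth of 0.5 kcal/mol equals
0.05 µcal per injection. Sign conventions: exothermic $\Delta H < 0$;
$n_H < 0$ means protons are released to the buffer, so "releases more
protons" reads as a more negative $n_H$.

The Wiseman parameter $c = n M_0 / K_d$ governs identifiability and the
fit flags $c < 1$ or $c > 1000$. For the weak isoform at the study
concentrations $c \approx 5$, where stoichiometry, enthalpy and $K_d$ are
nearly collinear; the workflow follows the established low-$c$ practice of
pinning $n$ at the known 1:1 value (`fix_n = 1`) and titrating to molar
ratio ≈ 4 (35 × 2 µL injections) so the isotherm tail constrains
$q_{dil}$.

Derived quantities obey the identities $\Delta G = RT\ln K_d$ ($K_d$ in
molar) and $\Delta G = \Delta H + (-T\Delta S)$ exactly — they are
computed, never fitted independently.

### Linkage and heat-capacity decomposition

When complex formation exchanges protons with the buffer, the apparent
enthalpy is linear in the buffer ionization enthalpy,
$\Delta H_{app} = \Delta H_0 + n_H\,\Delta H_{ion}$, and the binding heat
capacity is the slope of $\Delta H_{app}$ against temperature. Both are
ordinary least-squares lines (`linkage_regression()`,
`heat_capacity_regression()`). When the per-titration enthalpy standard
errors are supplied, the line is fitted by weighted least squares and the
reported parameter uncertainties combine, in quadrature, the
known-variance propagation with the residual-scatter estimate. This is
deliberately conservative: linkage series are short (3–4 buffers), where a
purely residual-based standard error has so few degrees of freedom that
nominal 2-SE intervals undercover badly; the combined estimate restores
honest coverage at the cost of mild width. The simulated study protocol
runs duplicate titrations per condition, as a laboratory would.

## Turnover and FRAP kinetics

Chase series are fitted as $A e^{-kt}$ on the linear scale (log-linear
fitting biases the small late values; a log-linear mode exists for
diagnostics), with $A$ free by default so the fit is invariant to overall
intensity rescaling. $k \ge 0$ is enforced; a non-decaying series returns
a flagged boundary fit with infinite half-life rather than an error.
`t_half * k == log(2)` holds exactly in every result.

FRAP traces are double-normalized by the pre-bleach mean, with $t = 0$ at
the first post-bleach frame, then fitted as
$F(t) = F_0 + (F_\infty - F_0)(1 - e^{-kt})$. The mobile fraction is
$(F_\infty - F_0)/(1 - F_0)$, clamped to $[0,1]$. The single-exponential
model parameterizes exactly the two quantities the experiment reports —
half-maximal recovery time and mobile fraction; it is not a
diffusion-reaction model and estimates no diffusion coefficient.

## Densitometry and the exact Mann–Whitney test

Band intensities are divided by their loading control — when both
β-actin and histone H3 are given, by their geometric mean, so neither
channel dominates — and scaled so the reference group's mean ratio is 1.

The two-group comparison is the two-tailed Mann–Whitney U test. For
$\min(n_1,n_2) \le 10$ and tie-free data the null distribution of U is
built by full enumeration of all $\binom{n_1+n_2}{n_1}$ labelings
(memoized per size pair) and
$p = \min\{1,\, 2\min(P(U\le u), P(U\ge u))\}$. Ties force the normal
approximation with midranks, tie-corrected variance and a continuity
correction applied toward the mean — so data identical across groups
report $p = 1$ rather than a spurious sub-unity value. The exact branch is
property-tested against an independent enumeration oracle over every size
pair with $n_1+n_2 \le 12$, and its type-I error at the study's $n = 7$
vs 8 stays in the nominal band.

## Co-IP interactor filter

A protein is a putative interactor when it has at least 2 significantly
matching peptides in the immunoprecipitate and zero peptides in **both**
negative controls (blocked-antibody and IgG) — the strictest reading of
"absent from the negative controls". Multiple IP replicates aggregate by
maximum count by default (summation is available, and matters only for
proteins with 1 peptide per replicate). Output ordering is deterministic:
descending IP evidence, then protein id.

## The synthetic generator and what passing tests mean

Each generator emits exactly its fit's assumed model plus i.i.d. Gaussian
noise: two-state melts with linear baselines, 1:1 isotherms with the
overflow dilution and a constant heat-of-dilution offset, first-order
decays (value 1 at $t=0$), single-exponential FRAP recoveries, and peptide
tables with planted true interactors (≥ 2 IP peptides, clean controls),
background proteins (0–1 IP peptides) and contaminants (≥ 1 control
peptide). A global seed expands into per-call child seeds through a fixed
counter map, so appending an experiment to a design list never perturbs
the earlier streams.

Noise magnitudes are package conventions — the study reports none:

* melts: sd = 1% of the signal range;
* titrations: sd = 0.02 µcal per injection, derived from the instrument
  class's baseline noise (≈ 0.2 ncal/s integrated over an injection
  window). Under the study schedule this is 0.2 kcal/mol of injectant —
  large enough to matter against the small-enthalpy isoform's ≈ 3
  kcal/mol signal, as in the real experiment;
* chase: sd = 0.05 on normalized intensity; FRAP: sd = 0.01.

Real instrument data differ in ways the generator deliberately omits:
baseline drift and non-Gaussian, heteroscedastic noise; three-state or
aggregation-coupled melts; injection-to-injection volume error; FRAP
acquisition bleaching and diffusive (non-exponential) early recovery;
densitometry saturation; and peptide-count overdispersion between
replicates. Passing recovery tests therefore demonstrates estimator
correctness under the stated models, not robustness to instrument
pathology.

Problem sizes in the validation suites — 50-seed titration pairs for the
affinity-fold recoveries, 100-seed melt/kinetics/linkage recoveries,
$10^4$ null datasets for test calibration — were chosen to pin medians and
rates to the precision the comparisons need.

## Known limitations

* One transition, one binding site: no three-state melts, no multi-site or
  competitive titration models.
* $K_d$ is reported per buffer; correcting $K_d$ itself for proton linkage
  across buffers is out of scope, and $\Delta G$ is treated as
  buffer-independent at fixed pH.
* Exact Mann–Whitney with ties (mid-rank enumeration) is not implemented;
  ties always use the corrected approximation.
* The peptide filter consumes identification-level counts; spectral
  matching, FDR control and protein inference belong upstream.
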