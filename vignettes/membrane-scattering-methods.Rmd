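---
title: "Models and methods for saponin-modified membrane scattering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for saponin-modified membrane scattering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscatter)
```

# Scope

`memscatter` analyses the structural response of DMPC small unilamellar
vesicles (SUVs) to the saponin aescin and to cholesterol, as seen by four
techniques: small-angle neutron and X-ray scattering (SANS, SAXS), wide-angle
X-ray scattering (WAXS), and differential scanning calorimetry (DSC). The
package covers the model side of such a study — scattering length densities,
intensity models and their fitting, chain-packing and endotherm analysis,
model-independent inversion — together with a seeded synthetic-data generator
so that the whole pipeline can be exercised, tested and benchmarked without
beamline data.

# Scattering length densities

The neutron SLD of a molecular species is the sum of coherent bound
scattering lengths over the molecular volume,
$\mathrm{NSLD}(T) = \sum_i b_i / V(T)$; the X-ray SLD replaces $\sum b_i$ by
$Z e$ in units of the classical electron radius,
$\mathrm{XSLD}(T) = Z\,r_e/V(T)$ with $r_e = 2.818\times10^{-5}$ Å. Volumes
are piecewise linear between tabulated anchors (linear extrapolation outside),
which is how the temperature correction enters: heavy water drops from
$6.37\times10^{-6}$ Å$^{-2}$ at 10 °C to $6.34\times10^{-6}$ Å$^{-2}$ at
40 °C, DMPC from $0.297$ to $0.278\times10^{-6}$ Å$^{-2}$ as the gel-phase
molecular volume (1041 Å$^3$) expands towards the fluid phase.

Choices worth recording:

* **Solvent volumes** come from tabulated mass densities of D$_2$O and H$_2$O.
* **DMPC volumes** use the dilatometric gel (1041 Å$^3$, 10 °C) and fluid
  (1101 Å$^3$, 30 °C) anchors; the 40 °C anchor (1114 Å$^3$) is chosen
  consistent with fluid-phase thermal expansivity and the fluid-phase NSLD
  above.
* **Aescin (C$_{55}$H$_{86}$O$_{24}$) and cholesterol (C$_{27}$H$_{46}$O)
  volumes** are back-computed from their literature NSLDs
  ($1.42$ and $0.22 \times 10^{-6}$ Å$^{-2}$) and treated as
  temperature-independent; the species table labels them as back-computed
  rather than measured.
* **Mixing rule**: mole-fraction-weighted total scattering length over
  mole-fraction-weighted volume (equivalent to volume-fraction averaging of
  SLDs) — the physically standard ideal-mixing rule.
* The two composition fractions deliberately use *different denominators*:
  $x(\mathrm{aescin}) = n_a/(n_a+n_D+n_c)$ but
  $x(\mathrm{chol}) = n_c/(n_D+n_c)$, matching how such samples are commonly
  declared.

# Intensity models

## Unilamellar vesicle

A spherical solvent core of radius $R_{core}$ inside a homogeneous shell of
thickness $t$:

$$I_{ves}(q) = \frac{C}{V_{shell}}\left[
  3V_{core}(\rho_{solv}-\rho_{sh})\frac{f_1(qR_{core})}{qR_{core}}
+ 3V_{tot}(\rho_{sh}-\rho_{solv})\frac{f_1(qR_{tot})}{qR_{tot}}
\right]^2 + bkg$$

with $f_1(x) = (\sin x - x\cos x)/x^2$. Below $x=10^{-2}$ a 5-term Taylor
series replaces the direct formula to avoid catastrophic cancellation; the
switch point is tested for branch consistency. With SLDs in Å$^{-2}$,
lengths in Å and $C$ a volume fraction, multiplying the Å-native expression
by $10^8$ yields absolute intensities in cm$^{-1}$; that conversion is
applied in all models.

## Core–multi-shell (CMS) sphere

The X-ray contrast of a bilayer is not a box: the electron-rich headgroups
bracket an electron-poor hydrocarbon core. The CMS model therefore stacks
three shells — head, tail, head — around a solvent core of radius $R_{C,X}$,
with both headgroup shells sharing thickness $d_h$ and SLD (the default
$d_h = 7$ Å is a typical X-ray headgroup thickness for such mixed bilayers).
The total membrane thickness is $d_{X,M} = d_{tail} + 2d_h$. The amplitude is
the concentric-spheres sum over the four interfaces, verified in the tests
against an independently coded oracle.

## Paracrystal lamellar stack

Aggregated vesicles stack bilayers with mean period $D$ and Gaussian spacing
disorder. The intensity is

$$I_{LS}(q) = 2\pi(\Delta\rho)^2\,\phi\,\frac{P_{bil}(q)}{q^2} Z_N(q),
\qquad P_{bil} = \left(\frac{\sin(qt/2)}{qt/2}\right)^2$$

with the finite-stack interference factor $Z_N(q)$ written in the standard
closed form in $w$, $x_N S_N + (1-x_N)S_{N+1}$, so that a non-integer mean
stack number $N_L = x_N N + (1-x_N)(N+1)$ is a linear mixture of stacks of
$N$ and $N+1$ layers. The distortion factor is not uniquely pinned down by
the quantities usually quoted with this model; we take the standard
paracrystal choice
$$w(q) = \exp(-q^2 \sigma_D^2/2), \qquad \sigma_D = (\sigma_D/D)\cdot D,$$
which is the only way the quoted relative spacing deviation
($\sigma_D/D \approx 0.2$) enters. Before freezing the implementation the
closed form was checked to equal the direct ideal-paracrystal pair sum
$1 + (2/N)\sum_k (N-k)w^k\cos(kqD)$ to machine precision; that check is kept
as a test oracle. Note that $Z_N$ peaks slightly *below* $2\pi/D$ because
$w(q)$ decays across the peak; the effect is a fraction of a typical q bin.

## Combined model

Measured SANS curves mix a vesicle population and stacked aggregates:

$$I(q) = N\,[\,a\,I_{ves}(q) + b\,I_{LS}(q)\,] + bkg, \qquad a+b=1 .$$

The constraint is enforced at construction; component backgrounds are zeroed
so a single global background applies. The bilayer thickness $t$ is shared
between the vesicle shell and the stack, as the same bilayer forms both.

## Polydispersity

Core radii take a Schulz (gamma) distribution — extrusion truncates the
upper tail, making a right-skewed shape appropriate — with
$z = 1/\sigma_{rel}^2 - 1$; the hydrophobic thickness takes a Gaussian
(width capped at 0.1 relative, where the ±3σ truncation loses under 0.3% of
mass). Averaging is number-weighted over the *intensity* (shells riding
rigidly on the radius; radii fixed while the thickness varies), the
convention of the established fitting programs this mirrors.

Numerically, the averages use Gauss–Legendre nodes against the analytic
density. Two deliberate choices:

* The Schulz integral runs over $[0, \mu + 8\sigma]$. A 5σ cut looks
  generous but leaves a renormalization bias of order $10^{-4}$ in the mean
  at 30% width, which would dominate the quadrature error; 8σ brings the
  recovered mean within $10^{-6}$ relative of the input, which the tests
  assert.
* The node count scales with $q_{max}$ times the integration range
  (minimum 35, cap 600). At high $q$ the form factor oscillates in the size
  variable with period $\pi/q$; a fixed 35-node rule aliases these
  oscillations badly (errors of order 100% at $q = 0.3$ Å$^{-1}$ for 30%
  width), while the scaled rule keeps the doubling-the-nodes change below
  0.1%, the convergence criterion used in the tests.

## Resolution smearing

A Gaussian kernel of width $\sigma_q = (\Delta\lambda/\lambda)\,q/2.355$
(10% wavelength spread expressed as FWHM) applied by trapezoid quadrature on
the measured grid, renormalized on the available support. Smearing is off by
default in the generator: the recovery studies probe the models, not the
instrument, and adding it is a one-argument change.

# Fitting

Weighted least squares, $\chi^2 = \sum[(I_{mod}-I_{obs})/\sigma]^2$, by
bounded Levenberg–Marquardt. Design points:

* **Parameter normalization.** Radii (hundreds of Å), SLDs ($10^{-6}$) and
  fractions (≤1) differ by nine orders of magnitude; every free parameter is
  scaled by its start magnitude before optimization.
* **Multi-start.** Form-factor oscillations alias: a start radius half an
  oscillation off can converge to a secondary minimum (observed as rare
  $\chi^2_\nu \approx 10$ outliers in seeded recovery ensembles). `fit_sas()`
  optionally repeats the fit from a fixed, deterministic pattern of perturbed
  starts and keeps the lowest $\chi^2_\nu$; the recovery harness uses three
  restarts by default. Fits remain bit-reproducible for identical inputs.
* **Integer stack count.** $N$ is fitted by a discrete scan over 1–10 with
  the continuous $x_N$ free inside each, mirroring how a non-integer mean
  layer number is reported.
* **Uncertainties** come from the covariance at the optimum scaled by
  $\sqrt{\chi^2_\nu}$ — the usual small-angle practice, documented as
  approximate. Seeded ensembles in the tests check that the reported σ and
  the empirical scatter agree within a factor well inside 5.
* **No silent defaults.** Start values must be supplied in full; named
  presets encode the studied sample regimes explicitly.
* A q-range sanity check rejects grids extending beyond 2 Å$^{-1}$, the
  signature of nm$^{-1}$ data fed in unconverted.

# WAXS chain packing

The acyl-chain correlation peak position gives $d_{WAXS} = 2\pi n/q_{peak}$,
and in the gel phase (hexagonal chain packing, taken at 10 °C) the area per
lipid $A_L = 16\pi^2/(\sqrt{3}\,q_{peak}^2) = 4d^2/\sqrt{3}$. Peak location
subtracts a linear background through the window endpoints (the diffuse
scattering slopes visibly under these peaks) and refines the discrete
maximum with a least-squares parabola over the contiguous points above 70%
of the peak height. A plain 3-point parabola transmits single-bin noise
directly into the vertex; using the full peak top keeps the refinement
lineshape-agnostic while reaching the few-times-$10^{-3}$ Å$^{-1}$
reproducibility the melting analysis needs. The melting point comes from
the inflection of
$d(T) = d_{low} + (d_{high}-d_{low})/(1+e^{(T_m-T)/k})$ with $k>0$ (spacing
grows on melting); series with no resolvable inflection inside the measured
range, or a transition broader than half of it, are returned flagged rather
than silently fitted.

# DSC endotherms

After subtracting a straight baseline anchored in the flat pre- and
post-transition regions, endotherms are decomposed into 1–4 Lorentzians
$A\gamma^2/((T-T_0)^2+\gamma^2)$, whose maximum is analytically at $T_0$.
The component count is user-specified — assigning peaks to saponin-poor,
saponin-rich and steroid-broadened environments is interpretive — and a
possible overfit is *flagged* (any amplitude under 3× the residual-derived
noise) instead of auto-pruned. Start centres come from a greedy
find-maximum-and-subtract pass over the smoothed signal with half-widths
estimated from half-height crossings; plain local-maximum picking fails once
components overlap within ~1.5 half-widths, which these systems do.

# Indirect Fourier transformation

$I(q) = 4\pi\int_0^{D_{max}} p(r)\,\mathrm{sinc}(qr)\,dr$ is discretized on a
uniform r grid (default 101 points) with $p(0)=p(D_{max})=0$ and solved as a
ridge problem with a second-difference smoothness penalty. The weight
$\alpha$ is chosen by an L-curve scan — the solution farthest from the chord
through the extremes of the (log residual, log roughness) curve — and can be
overridden. Negativity of $p(r)$ is *not* forbidden: X-ray bilayer contrast
legitimately produces negative lobes. Partial-range analysis (`q_window`)
supports curves whose high-q part carries structure-factor peaks. The radius
of gyration follows from the moments,
$R_G^2 = \int p\,r^2 dr \,/\, 2\!\int p\,dr$; for an ideal thin shell this
gives $R_G = R$, for a solid sphere $\sqrt{3/5}\,R$, both used as analytic
anchors in the tests. Power-law exponents $m$ in $I \sim q^{-m}$ are read
from log-log fits per window (1 cylinders, 2 lamellae, 3 fractal-like,
4 sharp interfaces), and the Porod constant is the median of $q^4I$ over the
highest window — the median because residual form-factor oscillations make a
mean unstable. On a fixed-thickness vesicle the bilayer oscillation never
damps and a windowed slope is genuinely ill-defined; the Porod property test
therefore uses a thickness-dispersed vesicle, which is also the physically
realistic case.

# Synthetic data: what it emulates and what it does not

The generator produces every input the pipeline reads, sharing the exact
model code paths so that zero noise reproduces the model bit-for-bit:

* **SANS presets** follow the studied sample regimes: shared near-fixed
  constants (overall scale 0.019, background 0.15 cm$^{-1}$, $D = 72$ Å,
  $\sigma_D/D = 0.2$, $t = 40/35$ Å at 10/40 °C, solvent NSLD 6.37/6.34
  $\times 10^{-6}$ Å$^{-2}$) with per-regime core radii (186–445 Å), Schulz
  widths (27–45%), shell NSLDs and stack fractions ($b$ = 0–0.71, $N_L$ =
  1–8). Where published fractions round to $a+b \ne 1$, $b$ is kept and
  $a = 1-b$. The q grid is log-spaced over $7.6\times10^{-4}$–0.4 Å$^{-1}$
  (120 points by default).
* **SAXS presets** are CMS vesicles ($R_{C,X}$ = 300/350 Å, $d_h$ = 7 Å,
  $d_{tail}$ = 30 Å) on a 1.5×10$^{-3}$–0.6 Å$^{-1}$ grid.
* **WAXS series** place one Gaussian chain peak at $2\pi/d(T)$ with $d(T)$
  following the melting sigmoid (gel 4.20 Å → fluid 4.55 Å around 23.6 °C,
  width 1.5 °C — a DMPC-like transition) on a sloping diffuse background,
  on 10–50 °C in 5 °C steps.
* **DSC thermograms** are Lorentzian sums on a linear baseline over 7–40 °C
  at 0.02 °C sampling (a 0.5 °C/min scan); the pure-DMPC preset is a single
  peak at 23.6 °C with $\gamma$ = 0.4 °C.
* **Noise** is seeded Gaussian, relative (default 3% for reduced small-angle
  data, 1% elsewhere) plus an optional absolute floor, and the σ column
  reports exactly the noise model.

Not emulated: counting (Poisson) statistics, instrument-specific smearing
kernels and detector artifacts, multilamellar-vesicle (onion) form factors,
inter-vesicle structure factors beyond the lamellar stack, chemical
backgrounds, or the low-q upturns seen in aggregating real samples. Passing
the recovery suites therefore demonstrates that the estimators are unbiased
and well-calibrated *under the stated models and noise*, not that every
systematic of beamline data is handled.

# Problem sizes and numerical budget

The test and acceptance runs use 120-point SANS grids, 1651-point
thermograms, 9-temperature WAXS series, 101-point r grids, 20-seed recovery
ensembles and $10^5$-sample Monte-Carlo oracles — sizes at which every
individual fit completes in well under a minute on one core while leaving
the statistical checks meaningful.

# Known limitations

* The stack model has no Caillé-type fluctuation structure factor; strong
  thermal undulations are outside its validity.
* Uncertainties are curvature-based; strongly correlated parameters (e.g.
  overall scale against $b$) are reported with their covariance but no
  profile likelihood.
* The IFT is the plain dilute-regime transform; no concentration
  (structure-factor) correction is applied.
* Resolution smearing enters model curves on request but is not
  deconvolved from data.
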