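# memscatter

Scattering and calorimetry analysis of saponin-modified lipid model membranes.

## The problem

The saponin aescin lyses red blood cells by complexing membrane cholesterol.
To study that interaction structurally, aescin and cholesterol are embedded at
low mole fractions in DMPC small unilamellar vesicles (SUVs) and the samples
are probed by SANS, SAXS, WAXS and DSC across the lipid's gel–fluid
transition. `memscatter` implements the quantitative machinery such a study
needs, for scattering/biophysics practitioners who work with reduced 1D
curves and thermograms:

* neutron and X-ray **scattering length densities** with temperature-dependent
  molecular volumes and mole-fraction mixing (`nsld()`, `xsld()`,
  `mix_sld()`, `composition_fractions()`);
* **intensity models** — unilamellar vesicle, core–multi-shell (CMS) bilayer,
  paracrystal lamellar stack, and their weighted combination — with Schulz /
  Gaussian polydispersity and optional resolution smearing;
* bounded weighted **least-squares fitting** with multi-start protection and
  a recovery harness (`fit_sas()`, `fix_and_scan()`, `recover_from_table()`);
* **WAXS chain packing**: peak position, `d_WAXS = 2πn/q_peak`, hexagonal
  area per lipid `A_L = 16π²/(√3 q²)`, and the melting point from a sigmoid
  fit of `d(T)`;
* **DSC decomposition** of endotherms into Lorentzian components with
  composition-trend tabulation;
* model-independent **IFT** to the pair-distance distribution `p(r)`, radius
  of gyration `R_G² = ∫p r² dr / (2∫p dr)`, power-law slopes and the Porod
  constant;
* a seeded **synthetic-data generator** for every input format the pipeline
  reads, with presets mirroring the studied sample regimes.

## The core model

Measured SANS curves of these samples superpose a vesicle form factor and a
finite lamellar stack from vesicle–vesicle aggregation:

```
I(q) = N [ a · I_ves(q) + b · I_LS(q) ] + bkg ,   a + b = 1
I_ves(q) = C/V_shell [ 3V_c Δρ f₁(qR_c)/(qR_c) − 3V_t Δρ f₁(qR_t)/(qR_t) ]² ,
I_LS(q)  = 2π Δρ² φ · P_bil(q)/q² · Z_N(q) ,   P_bil = (sin(qt/2)/(qt/2))²
```

with `f₁(x) = (sin x − x cos x)/x²` and `Z_N(q)` the paracrystal interference
factor of `N_L = x_N·N + (1−x_N)(N+1)` stacked bilayers with Gaussian spacing
disorder `w(q) = exp(−q²σ_D²/2)`. The stack fraction `b` tracks how strongly
vesicles aggregate as aescin and cholesterol contents grow.

## Worked example

```r
library(memscatter)

nsld("D2O", 10)    # solvent contrast at 10 degC
#> neutron SLD: 6.367 x 1e-6/A^2 (T = 10 degC)
nsld("DMPC", 10)
#> neutron SLD: 0.2974 x 1e-6/A^2 (T = 10 degC)

# synthetic SANS curve of the aggregated high-aescin regime, 3% noise,
# then refit with radius, thickness, spacing and stack fraction free
fit <- recover_from_table("a1.0_c5_10C", noise_rel = 0.03, seed = 42,
                          free = c("scale", "R_core", "t", "D", "b"))
fit
#> <sas_fit> model 'combined', 120 points in q = [0.00076, 0.4], chi2_red = 1.09
#>   scale           0.0190752 +/- 0.000257
#>   R_core            387.593 +/- 2.25
#>   t                 39.9091 +/- 0.252
#>   D                  72.292 +/- 1.9
#>   b                0.710805 +/- 0.00452
#>   fixed: poly_R=0.28, rho_shell=3.04e-07, rho_solvent=6.37e-06, sigma_rel=0.2, N=6, x_N=1, background=0.15

# DSC: pure-DMPC endotherm, baseline-corrected, one Lorentzian
tg  <- generate_dsc("DMPC_pure", noise = noise_spec(rel = 0.01, seed = 42))
dec <- decompose_thermogram(baseline_correct(tg, c(10, 38)), n_peaks = 1)
dec
#> <dsc_decomposition> 1 peak(s), residual RMS 0.05177
#>         T0     gamma amplitude    T_max
#> 1 23.60039 0.4053405  4.982971 23.60039
```

The fit recovers the generating truth (core radius 385 Å, bilayer thickness
40 Å, lamellar spacing 72 Å, stack fraction 0.71) within its reported
uncertainties at a reduced chi-square near one; the DSC decomposition returns
the DMPC main transition at 23.6 °C.

A thin command-line front end over the same functions ships in
`inst/cli/memscatter.R` (subcommands `sld`, `simulate`, `fit-sans`, `waxs`,
`dsc`, `ift`).

## Layout

```
R/                  implementation (SLDs, models, fitting, WAXS, DSC, IFT,
                    synthetic data, I/O)
inst/extdata/       species table (formulas, volume anchors, provenance)
inst/cli/           command-line front end
tests/testthat/     unit, property and end-to-end recovery tests
scripts/            acceptance script
vignettes/          methods vignette (models, assumptions, design choices)
```
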