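Package: memscatter
Title: Scattering and Calorimetry Analysis of Saponin-Modified Lipid Model Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for small-angle scattering and calorimetry of
    phospholipid model membranes (DMPC vesicles) doped with the saponin aescin
    and cholesterol. Provides neutron and X-ray scattering length density
    calculation with temperature-dependent molecular volumes, unilamellar
    vesicle and core-multi-shell form factors, a paracrystal lamellar-stack
    structure factor and their weighted combination, Schulz and Gaussian
    polydispersity averaging, resolution smearing, bounded weighted
    least-squares model fitting, WAXS acyl-chain packing analysis (chain
    correlation distance, area per lipid, sigmoidal transition temperature),
    DSC endotherm decomposition into Lorentzian components, regularized
    indirect Fourier transformation to the pair-distance distribution function
    with radius of gyration and Porod/power-law analysis, and a seeded
    synthetic-data generator covering every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
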