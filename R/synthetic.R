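# Seeded synthetic-data generation for every input the pipeline consumes:
# SANS/SAXS curves from the intensity models, WAXS temperature series, and
# DSC thermograms. Noise-free generation shares the exact model code paths.

#' Noise specification
#'
#' Relative Gaussian noise plus an absolute floor:
#' `sigma = sqrt((rel * I)^2 + floor^2)`, seeded.
#'
#' @param rel fractional noise on the intensity (default 0.03, typical of
#'   reduced small-angle data).
#' @param floor absolute noise floor.
#' @param seed integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(rel = 0.03, floor = 0, seed = 1L) {
  stopifnot(rel >= 0, floor >= 0)
  structure(list(rel = rel, floor = floor, seed = as.integer(seed)),
            class = "noise_spec")
}

.apply_noise <- function(I0, noise) {
  sigma <- sqrt((noise$rel * I0)^2 + noise$floor^2)
  if (all(sigma == 0)) return(list(I = I0, sigma = NULL))
  set.seed(noise$seed)
  list(I = I0 + rnorm(length(I0), 0, sigma), sigma = sigma)
}

#' SANS sample presets from the tabulated fit regimes
#'
#' Combined vesicle + lamellar-stack parameter sets named
#' `a<x_aescin>_c<mol% cholesterol>_<T>C`. Shared near-fixed constants:
#' overall scale 0.019, background 0.15 1/cm, layer spacing D = 72 A with
#' relative spacing disorder 0.2, bilayer thickness 40 A at 10 degC and 35 A
#' at 40 degC, heavy-water solvent NSLD 6.37e-6 (10 degC) / 6.34e-6 (40 degC)
#' 1/A^2. Per-sample values (core radius, its Schulz width, shell NSLD, stack
#' count, fraction b) follow the tabulated regimes; where the printed a and b
#' round to a sum slightly off 1, b is kept and a = 1 - b.
#'
#' @return named list of [combined_params()] objects.
#' @export
sans_presets <- function() {
  row <- function(R, polyR, shell, b, NL, T10 = TRUE) {
    t <- if (T10) 40 else 35
    solv <- if (T10) 6.37e-6 else 6.34e-6
    combined_params(
      scale = 0.019, b = b,
      vesicle = vesicle_params(R_core = R, t = t, rho_shell = shell,
                               rho_solvent = solv, scale = 1, background = 0,
                               poly_R = polyR),
      stack = lamellar_params(t = t, D = 72, sigma_rel = 0.2, N = NL, x_N = 1,
                              delta_rho = shell - solv, scale = 1,
                              background = 0),
      background = 0.15)
  }
  list(
    a0.0_c1_10C = row(186, 0.38, 0.296e-6, b = 0.00, NL = 1),
    a0.0_c5_10C = row(225, 0.45, 0.293e-6, b = 0.09, NL = 1),
    a0.4_c5_10C = row(356, 0.30, 0.298e-6, b = 0.56, NL = 4),
    a1.0_c5_10C = row(385, 0.28, 0.304e-6, b = 0.71, NL = 6),
    a0.0_c1_40C = row(208, 0.38, 0.277e-6, b = 0.00, NL = 1, T10 = FALSE),
    a1.0_c5_40C = row(445, 0.27, 0.287e-6, b = 0.71, NL = 8, T10 = FALSE)
  )
}

#' Core-multi-shell SAXS presets
#'
#' Extruded-SUV regimes with headgroup thickness 7 A, hydrophobic thickness
#' 30 A, lipid-like headgroup/tail X-ray SLDs and light-water solvent.
#'
#' @return named list of [cms_params()] objects.
#' @export
saxs_presets <- function() {
  mk <- function(R) cms_params(
    R_CX = R, d_tail = 30, d_h = 7, xsld_head = 14.0e-6, xsld_tail = 8.3e-6,
    xsld_core = 9.42e-6, xsld_solvent = 9.42e-6, poly_R = 0.15,
    poly_dtail = 0.05, scale = 0.01, background = 0.02)
  list(saxs_R300_10C = mk(300), saxs_R350_10C = mk(350))
}

#' DSC thermogram presets
#'
#' `DMPC_pure`: the single main-transition endotherm of pure DMPC SUVs at
#' 23.6 degC (Lorentzian half-width 0.4 degC) on a gently sloping baseline.
#' `aescin3_chol0`: three overlapping components emulating an
#' intermediate-aescin endotherm.
#'
#' @return named list with `peaks` (data frame T0, gamma, amplitude) and
#'   `baseline` (intercept, slope).
#' @export
dsc_presets <- function() {
  list(
    DMPC_pure = list(
      peaks = data.frame(T0 = 23.6, gamma = 0.4, amplitude = 5),
      baseline = c(intercept = 0.1, slope = 0.01)),
    aescin3_chol0 = list(
      peaks = data.frame(T0 = c(20.8, 22.6, 23.5), gamma = c(0.9, 0.6, 0.35),
                         amplitude = c(1.5, 2.5, 4)),
      baseline = c(intercept = 0.1, slope = 0.01))
  )
}

.default_sans_q <- function(n = 120) exp(seq(log(7.6e-4), log(0.4), length.out = n))
.default_saxs_q <- function(n = 140) exp(seq(log(1.5e-3), log(0.6), length.out = n))

.as_combined <- function(params) {
  if (is.character(params)) {
    pr <- sans_presets()
    if (!params %in% names(pr)) {
      stop("unknown preset '", params, "'; available: ",
           paste(names(pr), collapse = ", "))
    }
    return(pr[[params]])
  }
  if (inherits(params, "combined_params")) return(params)
  if (is.numeric(params) && !is.null(names(params))) {
    return(.flat_models$combined$build(params))
  }
  stop("params must be a preset name, combined_params, or flat named vector")
}

#' Generate a synthetic SANS curve
#'
#' Evaluates the combined vesicle + lamellar-stack model on a log-spaced
#' SANS q grid (7.6e-4 to 0.4 1/A), optionally applies Gaussian resolution
#' smearing, and adds seeded Gaussian noise. With zero noise the curve is the
#' exact model evaluation (identical code path).
#'
#' @param params preset name, [combined_params()] object, or flat named
#'   parameter vector (see [model_eval()]).
#' @param q optional q grid, 1/A.
#' @param noise a [noise_spec()].
#' @param dq_over_q relative resolution smearing (0 = none; the measurement
#'   wavelength spread was 10%).
#' @param temperature metadata, degC.
#' @return a [scattering_curve()] whose sigma column is the noise model.
#' @export
generate_sans <- function(params, q = NULL, noise = noise_spec(),
                          dq_over_q = 0, temperature = NA_real_) {
  p <- .as_combined(params)
  if (is.null(q)) q <- .default_sans_q()
  I0 <- combined_intensity(q, p)
  if (dq_over_q > 0) I0 <- smear_resolution(q, I0, dq_over_q)
  nz <- .apply_noise(I0, noise)
  scattering_curve(q, nz$I, nz$sigma, radiation = "neutron",
                   temperature = temperature, absolute_scale = TRUE)
}

#' Generate a synthetic SAXS curve
#'
#' Core-multi-shell model on a log-spaced SAXS q grid (1.5e-3 to 0.6 1/A)
#' plus seeded noise.
#'
#' @param params preset name from [saxs_presets()] or a [cms_params()] object.
#' @inheritParams generate_sans
#' @return a [scattering_curve()].
#' @export
generate_saxs <- function(params, q = NULL, noise = noise_spec(),
                          temperature = NA_real_) {
  if (is.character(params)) params <- saxs_presets()[[params]]
  stopifnot(inherits(params, "cms_params"))
  if (is.null(q)) q <- .default_saxs_q()
  I0 <- cms_intensity(q, params)
  nz <- .apply_noise(I0, noise)
  scattering_curve(q, nz$I, nz$sigma, radiation = "xray",
                   temperature = temperature, absolute_scale = TRUE)
}

#' Generate a synthetic WAXS temperature series
#'
#' One Gaussian chain-correlation peak per temperature, centred at
#' `q(T) = 2 pi / d(T)` with `d(T)` following the melting sigmoid
#' `d_low + (d_high - d_low)/(1 + exp((T_m - T)/width))`, on a linear diffuse
#' background, with seeded noise proportional to the peak amplitude.
#'
#' @param T_grid temperatures, degC (default 10 to 50 step 5).
#' @param d_low,d_high gel and fluid chain spacings, A (`d_low < d_high`).
#' @param T_m transition midpoint, degC.
#' @param width sigmoid width, degC.
#' @param peak_width_q Gaussian peak SD in q, 1/A.
#' @param amplitude peak amplitude.
#' @param background `c(intercept, slope)` of the diffuse background in q.
#' @param q q grid, 1/A (linear, 0.6-4 by default).
#' @param noise a [noise_spec()]; `rel` is relative to `amplitude`.
#' @return list of [waxs_pattern()] objects.
#' @export
generate_waxs_series <- function(T_grid = seq(10, 50, 5), d_low = 4.20,
                                 d_high = 4.55, T_m = 23.6, width = 1.5,
                                 peak_width_q = 0.06, amplitude = 1,
                                 background = c(0.8, -0.15),
                                 q = seq(0.6, 4, by = 0.005),
                                 noise = noise_spec(rel = 0.01)) {
  stopifnot(d_low < d_high, width > 0)
  set.seed(noise$seed)
  lapply(T_grid, function(Temp) {
    d <- d_low + (d_high - d_low) / (1 + exp((T_m - Temp) / width))
    q0 <- 2 * pi / d
    I0 <- amplitude * exp(-(q - q0)^2 / (2 * peak_width_q^2)) +
      background[1] + background[2] * q
    sd <- sqrt((noise$rel * amplitude)^2 + noise$floor^2)
    I <- if (sd > 0) I0 + rnorm(length(q), 0, sd) else I0
    waxs_pattern(q, I, temperature = Temp)
  })
}

#' Generate a synthetic DSC thermogram
#'
#' Sum of Lorentzian endotherm components on a linear baseline, with seeded
#' Gaussian noise whose `rel` component is taken relative to the tallest
#' peak amplitude.
#'
#' @param peaks data frame with columns `T0`, `gamma`, `amplitude`, or a
#'   preset name from [dsc_presets()].
#' @param baseline `c(intercept, slope)`.
#' @param T_grid temperatures, degC (default 7 to 40 step 0.02, matching a
#'   0.5 degC/min scan).
#' @param noise a [noise_spec()].
#' @param composition optional [membrane_composition()].
#' @return a [thermogram()].
#' @export
generate_dsc <- function(peaks, baseline = c(0, 0),
                         T_grid = seq(7, 40, by = 0.02),
                         noise = noise_spec(rel = 0.01),
                         composition = NULL) {
  if (is.character(peaks)) {
    preset <- dsc_presets()[[peaks]]
    baseline <- preset$baseline
    peaks <- preset$peaks
  }
  if (nrow(peaks)) {
    stopifnot(all(peaks$T0 > min(T_grid)), all(peaks$T0 < max(T_grid)),
              all(peaks$gamma > 0), all(peaks$amplitude > 0))
  }
  y <- baseline[1] + baseline[2] * T_grid
  for (j in seq_len(nrow(peaks))) {
    y <- y + lorentzian(T_grid, peaks$T0[j], peaks$gamma[j], peaks$amplitude[j])
  }
  amp <- if (nrow(peaks)) max(peaks$amplitude) else 0
  sd <- sqrt((noise$rel * amp)^2 + noise$floor^2)
  if (sd > 0) {
    set.seed(noise$seed)
    y <- y + rnorm(length(T_grid), 0, sd)
  }
  thermogram(T_grid, y, composition = composition)
}
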