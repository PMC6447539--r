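# Intensity models: unilamellar vesicle, core-multi-shell sphere, paracrystal
# lamellar stack, and their weighted combination.
#
# Conventions: q in 1/A, strictly positive; lengths in A; SLDs in 1/A^2.
# With the scale factors interpreted as volume fractions the returned
# intensities are in 1/cm (conversion factor 1e8 = 1/A -> 1/cm).

.check_q <- function(q) {
  if (!is.numeric(q) || !all(is.finite(q)) || any(q <= 0)) {
    stop("q must be finite and strictly positive (1/A)")
  }
  invisible(q)
}

#' First-order spherical Bessel amplitude
#'
#' f1(x) = (sin x - x cos x) / x^2, the radial amplitude kernel of a uniform
#' sphere. Evaluated by a 5-term Taylor series below x = 1e-2 to avoid
#' catastrophic cancellation; f1(0) = 0 with limiting slope 1/3.
#'
#' @param x non-negative numeric vector.
#' @return numeric vector, same length as `x`.
#' @examples
#' spherical_bessel_amp(pi)  # 1/pi
#' @export
spherical_bessel_amp <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-2
  if (any(small)) {
    xs <- x[small]
    x2 <- xs * xs
    out[small] <- xs * (1 / 3 + x2 * (-1 / 30 + x2 * (1 / 840 +
      x2 * (-1 / 45360 + x2 / 3991680))))
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- (sin(xl) - xl * cos(xl)) / xl^2
  }
  out
}

# scattering amplitude of a uniform sphere of radius R at unit contrast:
# F(q,R) = 3 V f1(qR)/(qR), F -> V as q -> 0
.sphere_amp <- function(q, R) {
  x <- q * R
  3 * (4 / 3 * pi * R^3) * spherical_bessel_amp(x) / x
}

# ---- parameter containers ---------------------------------------------------

#' Unilamellar vesicle model parameters
#'
#' @param R_core core (lumen) radius, A.
#' @param t shell (bilayer) thickness, A.
#' @param rho_shell,rho_solvent scattering length densities, 1/A^2
#'   ([sld_value()] or bare numeric).
#' @param scale scale factor C (volume fraction on absolute scale).
#' @param background flat background, same units as the intensity.
#' @param poly_R relative Schulz width of the core-radius distribution, in
#'   `[0, 0.6]`; 0 means monodisperse.
#' @return object of class `vesicle_params`.
#' @export
vesicle_params <- function(R_core, t, rho_shell, rho_solvent,
                           scale = 1, background = 0, poly_R = 0) {
  stopifnot(R_core > 0, t > 0, scale >= 0, background >= 0,
            poly_R >= 0, poly_R <= 0.6)
  structure(list(R_core = R_core, t = t, rho_shell = as_sld(rho_shell),
                 rho_solvent = as_sld(rho_solvent), scale = scale,
                 background = background, poly_R = poly_R),
            class = "vesicle_params")
}

#' Core-multi-shell (CMS) model parameters
#'
#' Concentric spheres: solvent core of radius `R_CX`, inner headgroup shell of
#' thickness `d_h`, hydrophobic shell `d_tail`, outer headgroup shell `d_h`,
#' embedded in solvent. The total membrane thickness is
#' `d_XM = d_tail + 2 d_h`. Both headgroup shells share thickness and SLD.
#'
#' @param R_CX inner core radius, A.
#' @param d_h headgroup shell thickness, A (default 7).
#' @param d_tail hydrophobic shell thickness, A.
#' @param xsld_head,xsld_tail,xsld_core,xsld_solvent X-ray SLDs, 1/A^2.
#' @param poly_R relative Schulz width on `R_CX` (shells ride rigidly).
#' @param poly_dtail relative Gaussian width on `d_tail`, in `[0, 0.1]`.
#' @inheritParams vesicle_params
#' @return object of class `cms_params`.
#' @export
cms_params <- function(R_CX, d_tail, d_h = 7, xsld_head, xsld_tail,
                       xsld_core, xsld_solvent, poly_R = 0, poly_dtail = 0,
                       scale = 1, background = 0) {
  stopifnot(R_CX > 0, d_h > 0, d_tail > 0, scale >= 0, background >= 0,
            poly_R >= 0, poly_R <= 0.6, poly_dtail >= 0, poly_dtail <= 0.1)
  structure(list(R_CX = R_CX, d_h = d_h, d_tail = d_tail,
                 xsld_head = as_sld(xsld_head), xsld_tail = as_sld(xsld_tail),
                 xsld_core = as_sld(xsld_core),
                 xsld_solvent = as_sld(xsld_solvent),
                 poly_R = poly_R, poly_dtail = poly_dtail,
                 scale = scale, background = background),
            class = "cms_params")
}

#' Paracrystal lamellar stack parameters
#'
#' A finite stack of `N_L` bilayers of thickness `t` with mean spacing `D` and
#' Gaussian spacing disorder of relative width `sigma_rel`. Non-integer stack
#' counts are a linear mixture: `N_L = x_N * N + (1 - x_N) * (N + 1)`.
#'
#' @param t bilayer thickness, A (must be < D).
#' @param D mean layer spacing, A.
#' @param sigma_rel relative standard deviation of the spacing distribution.
#' @param N integer lower stack count, >= 1.
#' @param x_N mixing fraction in `[0, 1]` between stacks of N and N+1 layers.
#' @param delta_rho bilayer/solvent SLD contrast, 1/A^2.
#' @param scale volume fraction of material in the bilayers.
#' @inheritParams vesicle_params
#' @return object of class `lamellar_params`.
#' @export
lamellar_params <- function(t, D, sigma_rel, N, x_N = 1, delta_rho,
                            scale = 1, background = 0) {
  stopifnot(t > 0, D > 0, t < D, sigma_rel >= 0, N >= 1, N == round(N),
            x_N >= 0, x_N <= 1, scale >= 0, background >= 0)
  structure(list(t = t, D = D, sigma_rel = sigma_rel, N = as.integer(N),
                 x_N = x_N, delta_rho = as_sld(delta_rho), scale = scale,
                 background = background),
            class = "lamellar_params")
}

#' Combined vesicle + lamellar-stack model parameters
#'
#' The measured SANS intensity is modelled as
#' `I(q) = scale * (a * I_ves(q) + b * I_LS(q)) + background` with `a + b = 1`.
#' Component backgrounds are zeroed; only the single global background applies.
#' The bilayer thickness `t` is shared between the vesicle shell and the stack.
#'
#' @param scale overall adjustable scale factor.
#' @param a,b vesicle and stack fractions; give either or both (must sum to 1).
#' @param vesicle a [vesicle_params()] object.
#' @param stack a [lamellar_params()] object.
#' @param background global flat background.
#' @return object of class `combined_params`.
#' @export
combined_params <- function(scale, a = NULL, b = NULL, vesicle, stack,
                            background = 0) {
  if (is.null(a) && is.null(b)) stop("give at least one of a, b")
  if (is.null(a)) a <- 1 - b
  if (is.null(b)) b <- 1 - a
  if (abs(a + b - 1) > 1e-9) stop("fractions must satisfy a + b = 1")
  stopifnot(a >= 0, a <= 1, scale >= 0, background >= 0,
            inherits(vesicle, "vesicle_params"),
            inherits(stack, "lamellar_params"))
  structure(list(scale = scale, a = a, b = b, vesicle = vesicle,
                 stack = stack, background = background),
            class = "combined_params")
}

# ---- polydispersity quadrature ----------------------------------------------

#' Quadrature nodes and weights for a size distribution
#'
#' Gauss-Legendre nodes against a Schulz (gamma, shape `1/rel_width^2`) or
#' Gaussian density. Schulz integrates over `[0, mean + 8 sd]`, Gaussian over
#' `mean +/- 3 sd` truncated at zero; weights are renormalized to unit mass.
#'
#' @param type "schulz" or "gaussian".
#' @param mean distribution mean.
#' @param rel_width relative standard deviation sd/mean (Schulz requires < 1).
#' @param n number of nodes (default 35).
#' @return list with `x` (nodes) and `w` (weights summing to 1).
#' @export
polydispersity_nodes <- function(type = c("schulz", "gaussian"), mean,
                                 rel_width, n = 35) {
  type <- match.arg(type)
  stopifnot(mean > 0, rel_width > 0, n >= 5)
  sd <- rel_width * mean
  if (type == "schulz") {
    if (rel_width >= 1) stop("Schulz relative width must be < 1 (z > 0)")
    shape <- 1 / rel_width^2           # = z + 1
    gl <- pracma::gaussLegendre(n, 0, mean + 8 * sd)
    w <- gl$w * dgamma(gl$x, shape = shape, scale = mean / shape)
  } else {
    gl <- pracma::gaussLegendre(n, max(0, mean - 3 * sd), mean + 3 * sd)
    w <- gl$w * dnorm(gl$x, mean, sd)
  }
  list(x = gl$x, w = w / sum(w))
}

# size averages at high q oscillate in the size variable with period ~ pi/q;
# the node count must track the number of oscillation cycles across the
# integration interval or the quadrature aliases
.poly_nodes_needed <- function(qmax, range_len) {
  max(35L, min(600L, ceiling(4 * qmax * range_len / pi)))
}

#' Average a model over a Schulz size distribution
#'
#' Number-weighted quadrature average of the intensity returned by
#' `evaluator(q, x)` over a Schulz distribution of the size `x`.
#'
#' @param evaluator function of `(q, x)` returning an intensity vector.
#' @param mean distribution mean, A.
#' @param rel_width relative width sd/mean; 0 returns the monodisperse curve.
#' @param q momentum-transfer grid, 1/A.
#' @param n number of quadrature nodes; the default `NULL` scales the count
#'   with `max(q)` times the integration range so that size oscillations of
#'   the form factor stay resolved (minimum 35).
#' @return intensity vector on `q`.
#' @export
schulz_average <- function(evaluator, mean, rel_width, q, n = NULL) {
  stopifnot(rel_width >= 0)
  if (rel_width == 0) return(evaluator(q, mean))
  if (is.null(n)) n <- .poly_nodes_needed(max(q), mean * (1 + 8 * rel_width))
  nodes <- polydispersity_nodes("schulz", mean, rel_width, n)
  out <- 0
  for (i in seq_along(nodes$x)) out <- out + nodes$w[i] * evaluator(q, nodes$x[i])
  out
}

#' Average a model over a Gaussian size distribution
#'
#' As [schulz_average()] but with a Gaussian density truncated at
#' `max(0, mean - 3 sd)` and renormalized.
#'
#' @inheritParams schulz_average
#' @export
gaussian_average <- function(evaluator, mean, rel_width, q, n = NULL) {
  stopifnot(rel_width >= 0)
  if (rel_width == 0) return(evaluator(q, mean))
  if (is.null(n)) n <- .poly_nodes_needed(max(q), 6 * rel_width * mean)
  nodes <- polydispersity_nodes("gaussian", mean, rel_width, n)
  out <- 0
  for (i in seq_along(nodes$x)) out <- out + nodes$w[i] * evaluator(q, nodes$x[i])
  out
}

# ---- model evaluators -------------------------------------------------------

.vesicle_mono <- function(q, R_core, t, rho_shell, rho_solvent, scale) {
  R_tot <- R_core + t
  A <- (rho_solvent - rho_shell) * .sphere_amp(q, R_core) +
       (rho_shell - rho_solvent) * .sphere_amp(q, R_tot)
  V_shell <- 4 / 3 * pi * (R_tot^3 - R_core^3)
  .kI * scale / V_shell * A^2
}

#' Unilamellar vesicle intensity
#'
#' Spherical core-shell form factor of a vesicle: solvent lumen of radius
#' `R_core`, bilayer shell of thickness `t`. With `poly_R > 0` the curve is a
#' number-weighted Schulz average over the core radius at fixed `t`.
#' As q -> 0 the monodisperse intensity tends to
#' `1e8 * scale * (rho_shell - rho_solvent)^2 * V_shell + background`.
#'
#' @param q momentum-transfer grid, 1/A, strictly positive.
#' @param p a [vesicle_params()] object.
#' @return intensity vector (1/cm on absolute scale).
#' @export
vesicle_intensity <- function(q, p) {
  stopifnot(inherits(p, "vesicle_params"))
  .check_q(q)
  ev <- function(q, R) .vesicle_mono(q, R, p$t, p$rho_shell, p$rho_solvent, p$scale)
  schulz_average(ev, p$R_core, p$poly_R, q) + p$background
}

.cms_mono <- function(q, R_CX, d_h, d_tail, rhos, scale) {
  # rhos: c(core, head, tail, head, solvent); interfaces at R1..R4
  R <- c(R_CX, R_CX + d_h, R_CX + d_h + d_tail, R_CX + 2 * d_h + d_tail)
  A <- 0
  for (j in 1:4) A <- A + (rhos[j] - rhos[j + 1]) * .sphere_amp(q, R[j])
  V_shell <- 4 / 3 * pi * (R[4]^3 - R[1]^3)
  .kI * scale / V_shell * A^2
}

#' Core-multi-shell (CMS) intensity
#'
#' Concentric-sphere amplitude sum over the four interfaces
#' core|head, head|tail, tail|head, head|solvent. Schulz polydispersity acts
#' on `R_CX` with the shells riding rigidly; Gaussian polydispersity acts on
#' `d_tail` at fixed `R_CX`. With both set, the product quadrature is used.
#'
#' @param q momentum-transfer grid, 1/A, strictly positive.
#' @param p a [cms_params()] object.
#' @return intensity vector.
#' @export
cms_intensity <- function(q, p) {
  stopifnot(inherits(p, "cms_params"))
  .check_q(q)
  rhos <- c(p$xsld_core, p$xsld_head, p$xsld_tail, p$xsld_head, p$xsld_solvent)
  ev_R <- function(q, R) {
    ev_d <- function(q, d) .cms_mono(q, R, p$d_h, d, rhos, p$scale)
    gaussian_average(ev_d, p$d_tail, p$poly_dtail, q)
  }
  schulz_average(ev_R, p$R_CX, p$poly_R, q) + p$background
}

#' Bilayer cross-section form factor
#'
#' `P_bil(q, t) = (sin(qt/2) / (qt/2))^2`, in `[0, 1]`, with limit 1 as q -> 0
#' and zeros at q = 2 pi n / t.
#'
#' @param q momentum transfer, 1/A (non-negative).
#' @param t bilayer thickness, A.
#' @return numeric vector.
#' @export
p_bilayer <- function(q, t) {
  stopifnot(t > 0, all(q >= 0))
  x <- q * t / 2
  s <- ifelse(x < 1e-8, 1, sin(x) / x)
  s^2
}

#' Paracrystal stack interference function
#'
#' Finite-stack interference factor Z_N(q) for N bilayers with Gaussian
#' spacing disorder, evaluated from the closed form
#' `Z_N = (1 - w^2)/(1 + w^2 - 2 w cos(qD)) + x_N S_N + (1 - x_N) S_{N+1}`
#' with the distortion factor `w(q) = exp(-q^2 sigma_D^2 / 2)`,
#' `sigma_D = sigma_rel * D`. Equals 1 identically when w = 0 and equals the
#' direct pair sum `1 + (2/N) sum_k (N-k) w^k cos(kqD)` for integer stacks.
#'
#' @param q momentum-transfer grid, 1/A.
#' @param p a [lamellar_params()] object.
#' @param w optional distortion factor override (scalar or vector), mainly for
#'   testing limits; default computed from `sigma_rel`.
#' @return dimensionless vector.
#' @export
z_interference <- function(q, p, w = NULL) {
  stopifnot(inherits(p, "lamellar_params"))
  if (is.null(w)) {
    sigma_D <- p$sigma_rel * p$D
    w <- exp(-q^2 * sigma_D^2 / 2)
  }
  cqd <- cos(q * p$D)
  den <- 1 + w^2 - 2 * w * cqd
  SN <- function(N) {
    aN <- 4 * w^2 - 2 * (w^3 + w) * cqd -
      4 * w^(N + 2) * cos(N * q * p$D) +
      2 * w^(N + 3) * cos((N - 1) * q * p$D) +
      2 * w^(N + 1) * cos((N + 1) * q * p$D)
    aN / (N * den^2)
  }
  out <- (1 - w^2) / den + p$x_N * SN(p$N) + (1 - p$x_N) * SN(p$N + 1)
  # the exact Z_N is non-negative; clip roundoff
  pmax(out, 0)
}

#' Paracrystal lamellar stack intensity
#'
#' `I_LS(q) = 1e8 * 2 pi delta_rho^2 * scale * P_bil(q, t) / q^2 * Z_N(q)
#'  + background`, the scale factor playing the role of the volume fraction of
#' bilayer material.
#'
#' @param q momentum-transfer grid, 1/A, strictly positive (1/q^2 diverges
#'   at 0).
#' @param p a [lamellar_params()] object.
#' @return intensity vector.
#' @export
lamellar_intensity <- function(q, p) {
  stopifnot(inherits(p, "lamellar_params"))
  .check_q(q)
  .kI * 2 * pi * p$delta_rho^2 * p$scale * p_bilayer(q, p$t) / q^2 *
    z_interference(q, p) + p$background
}

#' Combined vesicle + lamellar stack intensity
#'
#' `I(q) = scale * (a * I_ves(q) + b * I_LS(q)) + background`, the two
#' component models evaluated with zero background.
#'
#' @param q momentum-transfer grid, 1/A, strictly positive.
#' @param p a [combined_params()] object.
#' @return intensity vector.
#' @export
combined_intensity <- function(q, p) {
  stopifnot(inherits(p, "combined_params"))
  .check_q(q)
  ves <- p$vesicle; ves$background <- 0
  st <- p$stack; st$background <- 0
  p$scale * (p$a * vesicle_intensity(q, ves) + p$b * lamellar_intensity(q, st)) +
    p$background
}

#' Gaussian resolution smearing
#'
#' Convolves a discrete curve with a q-dependent Gaussian kernel of width
#' `sigma_q = dq_over_q * q / 2.355` (FWHM given as a relative wavelength
#' spread), by trapezoid quadrature over the measured grid with the kernel
#' renormalized on the available support.
#'
#' @param q momentum-transfer grid, ascending.
#' @param I intensity on `q`.
#' @param dq_over_q relative resolution (e.g. 0.10); 0 is the identity.
#' @return smeared intensity vector.
#' @export
smear_resolution <- function(q, I, dq_over_q) {
  stopifnot(length(q) == length(I), dq_over_q >= 0)
  if (dq_over_q == 0) return(I)
  .check_q(q)
  n <- length(q)
  dq <- diff(q)
  wtrap <- c(dq[1] / 2, (dq[-1] + dq[-(n - 1)]) / 2, dq[n - 1] / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- dq_over_q * q[i] / 2.355
    k <- dnorm(q, q[i], s) * wtrap
    k[abs(q - q[i]) > 4 * s] <- 0
    out[i] <- sum(k * I) / sum(k)
  }
  out
}
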