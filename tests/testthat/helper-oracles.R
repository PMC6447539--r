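# Shared independent oracles and small utilities for the test suite.

# direct (no series branch) uniform-sphere amplitude, unit contrast
oracle_sphere_amp <- function(q, R) {
  x <- q * R
  3 * (4 / 3 * pi * R^3) * (sin(x) - x * cos(x)) / x^3
}

# concentric-spheres intensity by direct summation over interfaces
oracle_multishell <- function(q, radii, rhos, scale, background = 0) {
  A <- 0
  for (j in seq_along(radii)) {
    A <- A + (rhos[j] - rhos[j + 1]) * oracle_sphere_amp(q, radii[j])
  }
  V_shell <- 4 / 3 * pi * (max(radii)^3 - min(radii)^3)
  1e8 * scale / V_shell * A^2 + background
}

# ideal finite-paracrystal interference by direct pair summation
oracle_paracrystal_z <- function(q, D, w, N) {
  out <- rep(1, length(q))
  for (k in seq_len(N - 1)) out <- out + (2 / N) * (N - k) * w^k * cos(k * q * D)
  out
}

# closed-form pair-distance distribution of a solid sphere of radius R
oracle_sphere_pddf <- function(r, R) {
  x <- r / R
  ifelse(r <= 2 * R, r^2 * (1 - 0.75 * x + x^3 / 16), 0)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

default_sans_q <- function(n = 120) exp(seq(log(7.6e-4), log(0.4), length.out = n))
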