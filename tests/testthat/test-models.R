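test_that("spherical Bessel amplitude: closed values and branch consistency", {
  expect_equal(spherical_bessel_amp(pi), 1 / pi, tolerance = 1e-12)
  expect_equal(spherical_bessel_amp(0), 0)
  # limiting slope 1/3 near zero
  expect_equal(spherical_bessel_amp(1e-6) / 1e-6, 1 / 3, tolerance = 1e-9)
  # series branch (just below the 1e-2 switch) agrees with the direct formula
  x <- 0.0099999
  direct <- (sin(x) - x * cos(x)) / x^2
  expect_lt(abs(spherical_bessel_amp(x) - direct), 1e-12)
  # direct branch just above the switch agrees with its own formula too
  x2 <- 0.0100001
  expect_equal(spherical_bessel_amp(x2), (sin(x2) - x2 * cos(x2)) / x2^2)
})

test_that("vesicle model: zero contrast, q->0 limit, degenerate distribution", {
  q <- default_sans_q(60)
  flat <- vesicle_params(200, 40, 3e-6, 3e-6, scale = 0.5, background = 0.25)
  expect_equal(vesicle_intensity(q, flat), rep(0.25, length(q)))

  p <- vesicle_params(200, 40, 0.3e-6, 6.37e-6, scale = 0.5, background = 0.1)
  V_shell <- 4 / 3 * pi * (240^3 - 200^3)
  lim <- 1e8 * 0.5 * (0.3e-6 - 6.37e-6)^2 * V_shell + 0.1
  expect_equal(vesicle_intensity(1e-7, p), lim, tolerance = 1e-8)

  p0 <- p; p0$poly_R <- 0
  expect_identical(vesicle_intensity(q, p0), vesicle_intensity(q, p))
  expect_error(vesicle_intensity(c(0, q), p), "positive")
})

test_that("vesicle and CMS match the concentric-spheres oracle", {
  q <- exp(seq(log(2e-3), log(0.3), length.out = 70))
  set.seed(42)
  for (i in 1:5) {
    R <- runif(1, 100, 400); t <- runif(1, 20, 60)
    rs <- runif(1, 0, 1e-6); rsol <- runif(1, 5e-6, 7e-6)
    sc <- runif(1, 0.001, 0.1)
    p <- vesicle_params(R, t, rs, rsol, scale = sc)
    expect_equal(vesicle_intensity(q, p),
                 oracle_multishell(q, c(R, R + t), c(rsol, rs, rsol), sc),
                 tolerance = 1e-10)
    dh <- runif(1, 4, 10); dt <- runif(1, 20, 40)
    rh <- runif(1, 1e-5, 1.6e-5); rt <- runif(1, 7e-6, 9e-6)
    rc <- runif(1, 9e-6, 1e-5)
    cp <- cms_params(R_CX = R, d_tail = dt, d_h = dh, xsld_head = rh,
                     xsld_tail = rt, xsld_core = rc, xsld_solvent = rc,
                     scale = sc)
    expect_equal(
      cms_intensity(q, cp),
      oracle_multishell(q, c(R, R + dh, R + dh + dt, R + 2 * dh + dt),
                        c(rc, rh, rt, rh, rc), sc),
      tolerance = 1e-10)
  }
})

test_that("CMS reduces to the vesicle model at uniform shell SLD", {
  q <- exp(seq(log(1e-3), log(0.4), length.out = 80))
  cp <- cms_params(R_CX = 300, d_tail = 26, d_h = 7, xsld_head = 0.3e-6,
                   xsld_tail = 0.3e-6, xsld_core = 6.37e-6,
                   xsld_solvent = 6.37e-6, scale = 0.5)
  vp <- vesicle_params(300, 26 + 2 * 7, 0.3e-6, 6.37e-6, scale = 0.5)
  expect_equal(cms_intensity(q, cp), vesicle_intensity(q, vp),
               tolerance = 1e-10)
  # all SLDs equal to solvent: flat background
  cpz <- cms_params(R_CX = 300, d_tail = 26, d_h = 7, xsld_head = 9.4e-6,
                    xsld_tail = 9.4e-6, xsld_core = 9.4e-6,
                    xsld_solvent = 9.4e-6, background = 0.02)
  expect_equal(cms_intensity(q, cpz), rep(0.02, length(q)))
})

test_that("CMS first form-factor minimum moves to lower q as the core grows", {
  qf <- seq(0.005, 0.03, by = 5e-5)
  first_min <- function(R) {
    p <- cms_params(R_CX = R, d_tail = 30, d_h = 7, xsld_head = 14e-6,
                    xsld_tail = 8.3e-6, xsld_core = 9.42e-6,
                    xsld_solvent = 9.42e-6)
    I <- cms_intensity(qf, p)
    qf[which(diff(sign(diff(I))) == 2)[1] + 1]
  }
  expect_lt(first_min(310), first_min(250))
})

test_that("Schulz and Gaussian quadrature agree with Monte-Carlo sampling", {
  ves_R <- function(q, R) memscatter:::.vesicle_mono(q, R, 40, 0.3e-6, 6.37e-6, 1)
  qs <- exp(seq(log(0.002), log(0.03), length.out = 30))
  # Schulz, 30% relative width
  Iq <- schulz_average(ves_R, 300, 0.3, qs)
  set.seed(7)
  Rs <- rgamma(1e5, shape = 1 / 0.3^2, scale = 300 * 0.3^2)
  Imc <- vapply(qs, function(qq) mean(ves_R(qq, Rs)), 0)
  expect_lt(sqrt(mean((Iq / Imc - 1)^2)), 0.005)
  # Gaussian on the shell thickness, sampled on the same +-3 sd support
  ves_t <- function(q, t) memscatter:::.vesicle_mono(q, 300, t, 0.3e-6, 6.37e-6, 1)
  Ig <- gaussian_average(ves_t, 40, 0.08, qs)
  set.seed(8)
  ts <- rnorm(3e5, 40, 3.2)
  ts <- ts[abs(ts - 40) <= 3 * 3.2][1:1e5]
  Igmc <- vapply(qs, function(qq) mean(ves_t(qq, ts)), 0)
  expect_lt(sqrt(mean((Ig / Igmc - 1)^2)), 0.005)
})

test_that("polydispersity quadrature recovers moments and converges", {
  nd <- polydispersity_nodes("schulz", 300, 0.3)
  expect_equal(sum(nd$w), 1, tolerance = 1e-12)
  expect_lt(abs(sum(nd$x * nd$w) / 300 - 1), 1e-6)
  ng <- polydispersity_nodes("gaussian", 40, 0.08)
  expect_lt(abs(sum(ng$x * ng$w) / 40 - 1), 1e-6)
  # Gaussian truncation at +-3 sd loses < 0.3% of mass before renormalization
  gl <- pracma::gaussLegendre(200, 40 - 3 * 3.2, 40 + 3 * 3.2)
  expect_lt(1 - sum(gl$w * dnorm(gl$x, 40, 3.2)), 0.003)
  # doubling the automatic node count changes curves by < 0.1%
  ves_R <- function(q, R) memscatter:::.vesicle_mono(q, R, 40, 0.3e-6, 6.37e-6, 1)
  qs <- exp(seq(log(0.002), log(0.3), length.out = 50))
  n_auto <- memscatter:::.poly_nodes_needed(max(qs), 300 * (1 + 8 * 0.3))
  I1 <- schulz_average(ves_R, 300, 0.3, qs)
  I2 <- schulz_average(ves_R, 300, 0.3, qs, n = 2 * n_auto)
  expect_lt(max(abs(I1 / I2 - 1)), 0.001)
  # zero width falls back to the monodisperse curve; width >= 1 is an error
  expect_identical(schulz_average(ves_R, 300, 0, qs), ves_R(qs, 300))
  expect_identical(gaussian_average(ves_R, 300, 0, qs), ves_R(qs, 300))
  expect_error(schulz_average(ves_R, 300, 1, qs), "Schulz")
})

test_that("bilayer cross-section factor hits its closed-form values", {
  t <- 40
  expect_equal(p_bilayer(1e-9, t), 1)
  expect_equal(p_bilayer(2 * pi / t, t), 0, tolerance = 1e-12)
  expect_equal(p_bilayer(pi / t, t), 4 / pi^2, tolerance = 1e-12)
  q <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(p_bilayer(q, t) >= 0 & p_bilayer(q, t) <= 1))
})

test_that("stack interference: w = 0 limit, direct-sum oracle, peak position", {
  q <- seq(0.01, 0.4, length.out = 80)
  for (N in c(1, 3, 6)) for (xN in c(0, 0.4, 1)) {
    p <- lamellar_params(t = 40, D = 72, sigma_rel = 0.2, N = N, x_N = xN,
                         delta_rho = 6e-6)
    expect_equal(z_interference(q, p, w = 0), rep(1, length(q)))
  }
  # closed form equals the brute-force ideal-paracrystal pair sum
  for (N in c(2, 6)) {
    p <- lamellar_params(t = 40, D = 72, sigma_rel = 0.2, N = N, x_N = 1,
                         delta_rho = 6e-6)
    w <- exp(-q^2 * (0.2 * 72)^2 / 2)
    expect_equal(z_interference(q, p), oracle_paracrystal_z(q, 72, w, N),
                 tolerance = 1e-8)
  }
  # principal maximum at 2 pi / D within one grid step
  qg <- seq(0.05, 0.12, by = 5e-4)
  p6 <- lamellar_params(t = 40, D = 72, sigma_rel = 0.1, N = 6, x_N = 1,
                        delta_rho = 6e-6)
  qpk <- qg[which.max(z_interference(qg, p6))]
  expect_lt(abs(qpk - 2 * pi / 72), 5e-4 + 1e-12)
})

test_that("lamellar intensity scales with contrast squared and peaks near 2pi/D", {
  q <- seq(0.05, 0.15, by = 2e-4)
  p1 <- lamellar_params(t = 40, D = 72, sigma_rel = 0.2, N = 6, x_N = 1,
                        delta_rho = 3e-6, scale = 1, background = 0.15)
  p2 <- p1; p2$delta_rho <- 6e-6
  expect_equal(lamellar_intensity(q, p2) - 0.15,
               4 * (lamellar_intensity(q, p1) - 0.15), tolerance = 1e-12)
  expect_lt(abs(q[which.max(lamellar_intensity(q, p1))] - 2 * pi / 72), 0.01)
})

test_that("combined model is the stated linear mixture of its components", {
  q <- default_sans_q(60)
  pre <- sans_presets()$a1.0_c5_10C
  ves <- pre$vesicle; st <- pre$stack
  Iv <- vesicle_intensity(q, ves)
  Il <- lamellar_intensity(q, st)
  mk <- function(b) combined_params(scale = 2, b = b, vesicle = ves,
                                    stack = st, background = 0.15)
  expect_equal(combined_intensity(q, mk(0)), 2 * Iv + 0.15, tolerance = 1e-12)
  expect_equal(combined_intensity(q, mk(1)), 2 * Il + 0.15, tolerance = 1e-12)
  expect_equal(combined_intensity(q, mk(0.5)), 2 * (Iv + Il) / 2 + 0.15,
               tolerance = 1e-12)
  expect_error(combined_params(scale = 1, a = 0.6, b = 0.6, vesicle = ves,
                               stack = st), "a \\+ b")
})

test_that("all model intensities stay at or above the background", {
  q <- default_sans_q(80)
  set.seed(5)
  for (i in 1:5) {
    p <- vesicle_params(runif(1, 100, 400), runif(1, 20, 60), runif(1, 0, 1e-6),
                        6.37e-6, scale = runif(1, 0.01, 1),
                        background = runif(1, 0, 0.5),
                        poly_R = runif(1, 0, 0.4))
    expect_true(all(vesicle_intensity(q, p) >= p$background - 1e-12))
    pl <- lamellar_params(t = runif(1, 20, 50), D = 72,
                          sigma_rel = runif(1, 0.05, 0.4),
                          N = sample(1:8, 1), x_N = runif(1),
                          delta_rho = 6e-6, scale = runif(1, 0.001, 1),
                          background = runif(1, 0, 0.5))
    expect_true(all(lamellar_intensity(q, pl) >= pl$background - 1e-12))
  }
})

test_that("resolution smearing is identity at zero width, fills minima, conserves flux", {
  p <- vesicle_params(300, 40, 0.3e-6, 6.37e-6, scale = 0.019)
  q <- exp(seq(log(2e-3), log(0.1), length.out = 300))
  I0 <- vesicle_intensity(q, p)
  expect_identical(smear_resolution(q, I0, 0), I0)
  Is <- smear_resolution(q, I0, 0.1)
  mid <- q > 0.005 & q < 0.05
  expect_gt(min(Is[mid]), min(I0[mid]))
  inner <- q > 0.005 & q < 0.08
  expect_lt(abs(trapz(q[inner], Is[inner]) / trapz(q[inner], I0[inner]) - 1),
            0.01)
})
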