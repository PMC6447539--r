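truth_pure <- sans_presets()$a0.0_c1_10C
truth_agg <- sans_presets()$a1.0_c5_10C

test_that("noise-free self-consistency: truth starts give back truth, chi2 ~ 0", {
  crv <- generate_sans(truth_pure, noise = noise_spec(rel = 0))
  st <- flatten_combined(truth_pure)
  fit <- fit_sas(crv, "combined", st, free = c("scale", "R_core", "t"))
  expect_true(fit$converged)
  expect_equal(fit$params[["R_core"]], 186, tolerance = 1e-8)
  expect_equal(fit$params[["t"]], 40, tolerance = 1e-8)
  expect_lt(fit$chi2_reduced, 1e-10)
})

test_that("noise-free identifiability: 20% start perturbation recovers truth", {
  crv <- generate_sans(truth_pure, noise = noise_spec(rel = 0))
  st <- flatten_combined(truth_pure)
  st[c("R_core", "t", "scale")] <- st[c("R_core", "t", "scale")] * c(1.2, 0.8, 1.2)
  fit <- fit_sas(crv, "combined", st, free = c("scale", "R_core", "t"))
  expect_lt(abs(fit$params[["R_core"]] / 186 - 1), 1e-3)
  expect_lt(abs(fit$params[["t"]] / 40 - 1), 1e-3)
})

test_that("fits are deterministic given identical starts", {
  crv <- generate_sans(truth_agg, noise = noise_spec(rel = 0.03, seed = 4))
  st <- flatten_combined(truth_agg)
  st[["R_core"]] <- 370
  f1 <- fit_sas(crv, "combined", st, free = c("scale", "R_core", "b"))
  f2 <- fit_sas(crv, "combined", st, free = c("scale", "R_core", "b"))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$chi2_reduced, f2$chi2_reduced)
})

test_that("mixed-unit and malformed inputs are rejected up front", {
  # nm^-1-looking grid: q_max far beyond any A^-1 small-angle range
  crv <- scattering_curve(seq(0.05, 4, length.out = 100),
                          rep(1, 100))
  st <- flatten_combined(truth_pure)
  expect_error(fit_sas(crv, "combined", st, free = "scale"), "units")
  # start values outside bounds
  crv2 <- generate_sans(truth_pure, noise = noise_spec(rel = 0))
  st2 <- st; st2[["poly_R"]] <- 0.9
  expect_error(fit_sas(crv2, "combined", st2, free = "scale"), "bounds")
  # too few points for the number of free parameters
  crv3 <- scattering_curve(crv2$q[1:6], crv2$I[1:6])
  expect_error(fit_sas(crv3, "combined", st, free = c("scale", "R_core")),
               "data points")
})

test_that("aggregated-regime recovery: fraction b within 0.1 at 3% noise", {
  fit <- recover_from_table("a1.0_c5_10C", noise_rel = 0.03, seed = 12,
                            free = c("scale", "R_core", "t", "D", "b"))
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["b"]] - 0.71), 0.1)
  expect_lt(abs(fit$params[["R_core"]] - 385), 3 * fit$se[["R_core"]] + 5)
})

test_that("repeated seeded fits: 3-sigma coverage and honest uncertainties", {
  res <- t(vapply(1:20, function(s) {
    f <- recover_from_table("a0.0_c1_10C", noise_rel = 0.03, seed = 100 + s,
                            free = c("scale", "R_core", "t", "background"))
    c(R = f$params[["R_core"]], se = f$se[["R_core"]],
      chi2 = f$chi2_reduced, conv = as.numeric(f$converged))
  }, numeric(4)))
  expect_true(all(res[, "conv"] == 1))
  coverage <- mean(abs(res[, "R"] - 186) <= 3 * res[, "se"])
  expect_gte(coverage, 0.9)
  # empirical scatter of the estimate comparable to the reported uncertainty
  ratio <- sd(res[, "R"]) / mean(res[, "se"])
  expect_lt(ratio, 5)
  expect_gt(ratio, 1 / 5)
  # correctly specified noise: reduced chi-square near one
  expect_lt(abs(median(res[, "chi2"]) - 1), 0.5)
})

test_that("zero noise and zero jitter give zero recovery deltas", {
  fit <- recover_from_table(truth_pure, noise_rel = 0, seed = 5,
                            start_jitter = 0,
                            free = c("scale", "R_core", "t"))
  expect_true(all(abs(fit$delta) < 1e-6))
})

test_that("frozen-parameter scan localises the generating headgroup thickness", {
  cp <- saxs_presets()$saxs_R300_10C
  cp$poly_R <- 0.1; cp$poly_dtail <- 0
  crv <- generate_saxs(cp, noise = noise_spec(rel = 0.02, seed = 5))
  st <- c(R_CX = 290, d_h = 7, d_tail = 28, xsld_head = 14e-6,
          xsld_tail = 8.3e-6, xsld_core = 9.42e-6, xsld_solvent = 9.42e-6,
          poly_R = 0.1, poly_dtail = 0, scale = 0.012, background = 0.02)
  sc <- fix_and_scan(crv, "cms", st,
                     free = c("R_CX", "d_tail", "scale", "background"),
                     param = "d_h", values = 5:9, restarts = 4)
  prof <- attr(sc, "scan")
  expect_equal(prof$value[which.min(prof$chi2_reduced)], 7)
  # chi2 near one at the generating value
  expect_lt(abs(prof$chi2_reduced[prof$value == 7] - 1), 0.5)
  # empty scan yields an empty result list
  empty <- fix_and_scan(crv, "cms", st, free = "scale", param = "d_h",
                        values = numeric(0))
  expect_length(empty, 0)
})

test_that("noise-free scan over a frozen thickness minimises at the truth", {
  crv <- generate_sans(truth_agg, noise = noise_spec(rel = 0))
  st <- flatten_combined(truth_agg)
  sc <- fix_and_scan(crv, "combined", st, free = c("scale", "b"),
                     param = "t", values = c(36, 40, 44))
  prof <- attr(sc, "scan")
  expect_equal(prof$value[which.min(prof$chi2_reduced)], 40)
})
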