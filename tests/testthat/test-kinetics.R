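test_that("mean bond number follows the closed form and its limits", {
  dens <- assay_densities()
  par <- kinetic_params(3.03e-7, 7.75)

  expect_identical(mean_bond_number(0, dens, par), 0)
  # saturation limit mr*ml*AcKa
  expect_equal(mean_bond_number(1e6, dens, par), 1500 * 1500 * 3.03e-7,
               tolerance = 1e-12)
  expect_equal(mean_bond_number(1e6, dens, par), 0.681750, tolerance = 1e-6)
  # frozen scalar evaluation at tc = 0.1 s
  expect_equal(mean_bond_number(0.1, dens, par), 0.3676652, tolerance = 1e-6)
  expect_error(mean_bond_number(-0.1, dens, par), "non-negative")
})

test_that("adhesion probability is a proper monotone probability", {
  dens <- assay_densities()
  par <- kinetic_params(3.03e-7, 7.75)

  expect_identical(adhesion_probability(0, dens, par), 0)
  expect_equal(adhesion_probability(2, dens, par), 0.4942687, tolerance = 1e-6)
  # AcKa -> 0 kills adhesion
  expect_lt(adhesion_probability(5, dens, kinetic_params(1e-15, 7.75)), 1e-8)

  # bounds and monotonicity over a grid (finite differences)
  tc <- seq(0, 20, by = 0.05)
  pa <- adhesion_probability(tc, dens, par)
  expect_true(all(pa >= 0 & pa < 1))
  expect_true(all(diff(pa) >= 0))
  # monotone in AcKa and densities too
  pa2 <- adhesion_probability(2, dens, kinetic_params(6e-7, 7.75))
  expect_gt(pa2, adhesion_probability(2, dens, par))

  # plateau identity at tc = 100 / koff
  plateau <- 1 - exp(-dens$mr * dens$ml * par$AcKa)
  expect_lt(abs(adhesion_probability(100 / par$koff, dens, par) - plateau), 1e-6)
})

test_that("on-rate derivation is the exact product AcKa * koff", {
  expect_identical(derive_on_rate(kinetic_params(1, 1)), 1)
  expect_equal(derive_on_rate(kinetic_params(3.03e-7, 7.75)), 2.34825e-6,
               tolerance = 1e-12)
  expect_equal(derive_on_rate(kinetic_params(0.80e-7, 7.62)), 6.096e-7,
               tolerance = 1e-12)
  p <- kinetic_params(2.43e-7, 8.90)
  expect_equal(p$Ackon - p$AcKa * p$koff, 0, tolerance = 1e-12 * p$Ackon)
  # ND propagates
  expect_true(is.na(derive_on_rate(list(AcKa = NA_real_, koff = NA_real_))))
})

test_that("noiseless curves are inverted to high precision by both objectives", {
  for (par in published_params()[c(1, 4)]) {
    cur <- noiseless_curve(par)
    for (method in c("wls", "mle")) {
      fit <- fit_adhesion(cur, method = method)
      expect_true(fit$converged)
      expect_false(fit$nd)
      est <- coef(fit)
      expect_lt(abs(est["AcKa"] - par$AcKa) / par$AcKa, 1e-4)
      expect_lt(abs(est["koff"] - par$koff) / par$koff, 1e-4)
      expect_equal(unname(est["Ackon"]), est[["AcKa"]] * est[["koff"]],
                   tolerance = 1e-12)
    }
  }
})

test_that("all-zero adhesion takes the not-detectable path", {
  dens <- assay_densities()
  obs <- data.frame(cell_pair_id = paste0("p", 1:6),
                    tc = c(0.1, 0.2, 0.5, 1, 2, 5),
                    n_cycles = 50, n_adhesions = 0)
  fit <- fit_adhesion(adhesion_curve(obs, dens))
  expect_true(fit$nd)
  expect_true(is.na(coef(fit)["AcKa"]))
  expect_true(detection_limit_check(fit))
  expect_error(predict(fit), "ND")
})

test_that("detection-limit verdict follows the fitted affinity", {
  fit <- fit_adhesion(noiseless_curve(kinetic_params(3.03e-7, 7.75)))
  expect_false(detection_limit_check(fit))
  weak <- fit_adhesion(noiseless_curve(kinetic_params(5e-9, 7.75),
                                       density_pair(3e4, 3e4)))
  expect_true(detection_limit_check(weak))
})

test_that("fitting requires at least two distinct contact times", {
  dens <- assay_densities()
  obs <- data.frame(cell_pair_id = c("a", "b"), tc = c(1, 1),
                    n_cycles = 50, n_adhesions = c(10, 12))
  expect_error(fit_adhesion(adhesion_curve(obs, dens)), "2 distinct")
})

test_that("stochastic curves at assay scale recover the generating parameters", {
  # mean over 25 seeded replicates: AcKa within 10%, koff within 20%
  dens <- assay_densities()
  par <- kinetic_params(3.03e-7, 7.75)
  est <- vapply(1:25, function(i) {
    coef(fit_adhesion(simulate_adhesion_cycles(par, dens, seed = 300 + i)))[1:2]
  }, numeric(2))
  m <- rowMeans(est)
  expect_lt(abs(m["AcKa"] - par$AcKa) / par$AcKa, 0.10)
  expect_lt(abs(m["koff"] - par$koff) / par$koff, 0.20)
})

test_that("wls and mle agree within the sampling noise on synthetic data", {
  cur <- simulate_adhesion_cycles(kinetic_params(3.03e-7, 7.75),
                                  assay_densities(), seed = 17)
  a <- coef(fit_adhesion(cur, method = "wls"))
  b <- coef(fit_adhesion(cur, method = "mle"))
  # both estimators target the same curve; they should agree well within
  # the ~4% bootstrap SE on AcKa at this design
  expect_lt(abs(a["AcKa"] - b["AcKa"]) / a["AcKa"], 0.05)
  expect_lt(abs(a["koff"] - b["koff"]) / a["koff"], 0.15)
})

test_that("bootstrap errors are deterministic, near zero without noise, and calibrated", {
  par <- kinetic_params(3.03e-7, 7.75)
  # noiseless: resampling identical observations gives identical refits
  se0 <- bootstrap_errors(noiseless_curve(par), n_boot = 100, seed = 1)
  expect_lt(se0["AcKa"] / par$AcKa, 1e-6)
  # determinism
  cur <- simulate_adhesion_cycles(par, assay_densities(), seed = 42)
  se1 <- bootstrap_errors(cur, n_boot = 100, seed = 9)
  se2 <- bootstrap_errors(cur, n_boot = 100, seed = 9)
  expect_identical(se1, se2)
  # relative SE of AcKa in the Monte-Carlo-established 2-15% band
  expect_gt(se1["AcKa"] / coef(fit_adhesion(cur))["AcKa"], 0.02)
  expect_lt(se1["AcKa"] / coef(fit_adhesion(cur))["AcKa"], 0.15)
})

test_that("fit comparison reports fold changes and log-scale z tests", {
  fits <- lapply(published_params(), function(p) fit_adhesion(noiseless_curve(p)))

  same <- compare_fits(fits[[1]], fits[[1]])
  expect_equal(same$fold, rep(1, 3), tolerance = 1e-8)

  ab <- compare_fits(fits[[1]], fits[[2]])
  expect_equal(ab$fold[ab$param == "AcKa"], 3.03 / 0.80, tolerance = 1e-3)
  cd <- compare_fits(fits[[3]], fits[[4]])
  expect_equal(cd$fold[cd$param == "AcKa"], 7.74 / 2.43, tolerance = 1e-3)

  nd <- fit_adhesion(adhesion_curve(
    data.frame(cell_pair_id = c("a", "b"), tc = c(1, 2), n_cycles = 50,
               n_adhesions = 0), assay_densities()))
  expect_error(compare_fits(fits[[1]], nd), "detection_limit_check")
})

test_that("fit methods (predict, residuals, simulate, plot) are coherent", {
  par <- kinetic_params(3.03e-7, 7.75)
  cur <- simulate_adhesion_cycles(par, assay_densities(), seed = 3)
  fit <- fit_adhesion(cur)
  expect_equal(unname(residuals(fit)), fit$pool$Pa - predict(fit),
               tolerance = 1e-12)
  expect_equal(predict(fit, 0), 0)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "adhesion_curve")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  expect_output(print(fit), "AcKa")
  expect_output(summary(fit), "Per-contact-time")
})

test_that("optional constant background is estimated when present", {
  dens <- assay_densities()
  par <- kinetic_params(3.03e-7, 7.75)
  tc <- c(0.1, 0.2, 0.5, 1, 2, 5)
  b <- 0.15
  pa <- 1 - exp(-(mean_bond_number(tc, dens, par) + b))
  cur <- adhesion_curve(
    data.frame(cell_pair_id = paste0("p", seq_along(tc)), tc = tc,
               n_cycles = 1e6, n_adhesions = pa * 1e6), dens)
  fit <- fit_adhesion(cur, background = TRUE)
  expect_equal(fit$background, b, tolerance = 1e-2)
  expect_lt(abs(coef(fit)["AcKa"] - par$AcKa) / par$AcKa, 1e-2)
})
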