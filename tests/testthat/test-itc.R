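default_protocol <- itc_protocol() # 200 ul cell, 0.4 + 18 x 2 ul, 15 C

test_that("perfusion-cell concentrations follow the dilution correction", {
  conc <- itc_concentrations(default_protocol)
  expect_equal(nrow(conc), 19)
  # hand arithmetic: after all injections dV = 36.4, dV/2V0 = 0.091
  expect_equal(conc$cumulative_volume[19], 36.4)
  expect_equal(conc$Mt[19], 90 * (1 - 0.091) / (1 + 0.091))
  # no-injection limit: a tiny first injection leaves Mt ~ M0, Xt ~ 0
  tiny <- itc_protocol(injection_volumes = c(1e-9, 2))
  c0 <- itc_concentrations(tiny)
  expect_equal(c0$Mt[1], 90, tolerance = 1e-9)
  expect_equal(c0$Xt[1], 0, tolerance = 1e-6)
  # monotonicity
  expect_true(all(diff(conc$Mt) < 0))
  expect_true(all(diff(conc$Xt) > 0))
  expect_true(all(diff(conc$molar_ratio) > 0))
  # cumulative volume is all that matters
  split2 <- itc_concentrations(itc_protocol(injection_volumes = c(1, 1, 2)))
  whole <- itc_concentrations(itc_protocol(injection_volumes = c(2, 2)))
  expect_equal(split2$Mt[2:3], whole$Mt)
  expect_equal(split2$Xt[2:3], whole$Xt)
  # validity limit
  expect_error(
    itc_concentrations(itc_protocol(injection_volumes = rep(100, 5))),
    "dilution model"
  )
})

test_that("bound fraction from the quadratic matches a bisection oracle", {
  withr::with_seed(7, {
    for (k in 1:12) {
      Xt <- runif(1, 1, 400)
      Mt <- runif(1, 10, 150)
      N <- runif(1, 0.5, 2)
      kd <- 10^runif(1, -1, 2.5)
      theta <- xlinkquant:::one_site_theta(Xt, Mt, N, kd)
      expect_equal(theta, oracle_theta_bisect(Xt, Mt, N, kd),
                   tolerance = 1e-8,
                   info = sprintf("Xt=%.1f Mt=%.1f N=%.2f kd=%.2f", Xt, Mt, N, kd))
    }
  })
})

test_that("simulated isotherms respect null-enthalpy and saturation limits", {
  # dH = 0, offset = 0: all heats exactly 0
  iso0 <- simulate_isotherm(one_site_params(N = 1, kd = 10, dH = 0))
  expect_true(all(iso0$raw_heat == 0))
  expect_true(all(iso0$molar_heat == 0))
  expect_true(iso0$discard[1] && !any(iso0$discard[-1]))

  # tight binding: molar heat ~ dH before saturation, ~ 0 after
  iso_tight <- simulate_isotherm(one_site_params(N = 1, kd = 1e-6, dH = -10))
  early <- iso_tight$molar_heat[!iso_tight$discard & iso_tight$molar_ratio < 0.8]
  late <- iso_tight$molar_heat[iso_tight$molar_ratio > 1.5]
  expect_equal(early, rep(-10, length(early)), tolerance = 1e-3)
  expect_equal(late, rep(0, length(late)), tolerance = 1e-2)

  # cumulative heat is monotone in Xt for fixed-sign dH
  iso <- simulate_isotherm(one_site_params(N = 1, kd = 25, dH = -8))
  conc <- itc_concentrations(default_protocol)
  Q <- cumsum(iso$raw_heat) # close to cell heat content; decreasing
  expect_true(all(diff(Q) < 0))

  # determinism given a seed, without touching the global RNG stream
  a <- simulate_isotherm(one_site_params(kd = 25, dH = -8), noise_sd = 0.5,
                         seed = 42)
  b <- simulate_isotherm(one_site_params(kd = 25, dH = -8), noise_sd = 0.5,
                         seed = 42)
  expect_identical(a, b)
})

test_that("larger Kd flattens the transition monotonically", {
  steepness <- vapply(c(1, 5, 25, 100, 400), function(kd) {
    iso <- simulate_isotherm(one_site_params(N = 1, kd = kd, dH = -8))
    keep <- !iso$discard
    max(abs(diff(iso$molar_heat[keep]) / diff(iso$molar_ratio[keep])))
  }, numeric(1))
  expect_true(all(diff(steepness) < 0))
})

test_that("noise-free simulate-then-fit round trips from perturbed inits", {
  withr::with_seed(5, {
    for (k in 1:4) {
      truth <- one_site_params(
        N = runif(1, 0.5, 2),
        kd = c(2, 20, 80, 400)[k],
        dH = runif(1, -15, -2)
      )
      iso <- simulate_isotherm(truth, default_protocol)
      init <- one_site_params(
        N = truth$N * runif(1, 0.7, 1.3),
        kd = truth$kd * runif(1, 0.7, 1.3),
        dH = truth$dH * runif(1, 0.7, 1.3)
      )
      fit <- fit_one_site(iso, init = init)
      expect_true(fit$converged)
      expect_equal(fit$params$N, truth$N, tolerance = 1e-3)
      expect_equal(fit$params$kd, truth$kd, tolerance = 1e-3)
      expect_equal(fit$params$dH, truth$dH, tolerance = 1e-3)
    }
  })
})

test_that("the fit ignores the discarded first injection", {
  iso <- simulate_isotherm(one_site_params(kd = 25, dH = -8), noise_sd = 0.3,
                           seed = 8)
  fit1 <- fit_one_site(iso)
  iso$raw_heat[1] <- iso$raw_heat[1] + 500
  iso$molar_heat[1] <- iso$molar_heat[1] + 500
  fit2 <- fit_one_site(iso)
  expect_equal(unlist(fit2$params), unlist(fit1$params))
  expect_equal(fit2$sse, fit1$sse)
})

test_that("flat isotherms are refused; self-init fits without a guess", {
  flat <- simulate_isotherm(one_site_params(kd = 25, dH = 0))
  expect_error(fit_one_site(flat), "flat isotherm")

  iso <- simulate_isotherm(one_site_params(N = 1.2, kd = 40, dH = -9))
  fit <- fit_one_site(iso) # no init
  expect_true(fit$converged)
  expect_equal(fit$params$kd, 40, tolerance = 1e-4)
  expect_equal(fit$params$N, 1.2, tolerance = 1e-4)
})

test_that("thermodynamics identities hold and the reference state is 1 M", {
  # Kd = 1 M (1e6 uM) gives dG = 0
  th <- itc_thermodynamics(kd = 1e6, dH = -8, temperature = 288.15)
  expect_equal(th$dG, 0)
  # dG = dH + (-TdS) by definition
  th2 <- itc_thermodynamics(kd = 24.6, dH = -11.3, temperature = 288.15)
  expect_equal(th2$dG, -11.3 + th2$minus_TdS, tolerance = 1e-12)
  expect_equal(th2$dG, 1.9872e-3 * 288.15 * log(24.6e-6))
  # fit results satisfy the identity too
  fit <- fit_one_site(simulate_isotherm(one_site_params(kd = 25, dH = -8)))
  expect_equal(fit$dG, fit$params$dH + fit$minus_TdS, tolerance = 1e-9)
})

test_that("stderr intervals from the fit cover the truth at moderate noise", {
  withr::with_seed(31, seeds <- sample(1e6, 25))
  truth <- one_site_params(N = 1, kd = 25, dH = -8)
  covered <- vapply(seeds, function(s) {
    iso <- simulate_isotherm(truth, noise_sd = 0.5, seed = s)
    fit <- fit_one_site(iso)
    ci_lo <- fit$params$kd - 2 * fit$stderr[["kd"]]
    ci_hi <- fit$params$kd + 2 * fit$stderr[["kd"]]
    ci_lo <= truth$kd && truth$kd <= ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("isotherm CSV round trips through read/write", {
  iso <- simulate_isotherm(one_site_params(kd = 25, dH = -8), noise_sd = 0.5,
                           seed = 12)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_isotherm(iso, tmp)
  back <- read_isotherm(tmp, default_protocol)
  expect_equal(back$raw_heat, iso$raw_heat)
  expect_equal(back$molar_heat, iso$molar_heat)
  expect_equal(back$discard, iso$discard)
})
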