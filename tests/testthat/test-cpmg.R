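test_that("R2,eff inverts the exponential intensity decay", {
  expect_equal(r2eff_from_intensity(0.7, 0.7, 0.039), 0)
  expect_equal(r2eff_from_intensity(exp(-0.78), 1, 0.039), 20)
  expect_equal(r2eff_from_intensity(exp(-1.95), 1, 0.039), 50)
  expect_error(r2eff_from_intensity(-0.1, 1, 0.039), "intensity")
})

test_that("dispersion profiles are flat without exchange or shift difference", {
  nu <- nu_grid_default()
  flat1 <- simulate_dispersion(exchange_params(0, 500, 2, 12), nu, 600)
  expect_equal(flat1, rep(12, length(nu)), tolerance = 1e-8)
  flat2 <- simulate_dispersion(exchange_params(0.05, 800, 0, 9, 9), nu, 600)
  expect_equal(flat2, rep(9, length(nu)), tolerance = 1e-8)
})

test_that("fast-exchange limit reproduces Rex = pA pB dw^2 / kex", {
  p <- exchange_params(p_b = 0.03, k_ex = 8000, dw_ppm = 1, r2_a = 10)
  nu <- nu_grid_default()
  r2 <- simulate_dispersion(p, nu, 600)
  dw_rad <- 2 * pi * 1e-6 * 600e6 * 0.10136767 * p$dw_ppm
  rex_expect <- (1 - p$p_b) * p$p_b * dw_rad^2 / p$k_ex
  rex_sim <- r2[which.min(nu)] - r2[which.max(nu)]
  # the high-nu tail has not fully refocused, so compare the low-nu plateau
  # against r2_a + closed-form Rex
  expect_lt(abs((r2[which.min(nu)] - p$r2_a) - rex_expect) / rex_expect, 0.05)
  expect_gt(rex_sim, 0)
})

test_that("profiles decrease monotonically with pulsing frequency", {
  nu <- nu_grid_default()
  ord <- order(nu)
  for (kex in c(300, 1000, 3000)) {
    for (pb in c(0.01, 0.05)) {
      for (dw in c(0.5, 1, 2)) {
        r2 <- simulate_dispersion(exchange_params(pb, kex, dw, 10), nu, 600)
        if (kex >= 0.5 * slimbind:::dw_rad_per_s(dw, 600)) {
          expect_true(all(diff(r2[ord]) <= 1e-8))
        } else {
          # slow exchange: echo-parity ripple at low nu stays tiny
          expect_lt(max(diff(r2[ord])), 0.05)
        }
      }
    }
  }
})

test_that("matrix propagation matches the Carver-Richard oracle", {
  # the closed form tracks the propagation to 1% where the minor population
  # is small and exchange is not slower than the shift difference; in the
  # slow-exchange corner it is a documented approximation (here bounded 12%)
  nu <- nu_grid_default()
  for (kex in c(200, 1000, 5000)) {
    for (pb in c(0.01, 0.05, 0.1)) {
      for (dw in c(0.5, 2, 4)) {
        p <- exchange_params(pb, kex, dw, 11)
        sim <- simulate_dispersion(p, nu, 600)
        ora <- carver_richard(p, nu, 600)
        rel <- max(abs(sim - ora) / pmax(sim, 1))
        tol <- if (pb <= 0.05 &&
                   kex >= 1.5 * slimbind:::dw_rad_per_s(dw, 600)) 0.01 else 0.12
        expect_lt(rel, tol, label = sprintf("kex=%g pb=%g dw=%g", kex, pb, dw))
      }
    }
  }
  expect_equal(carver_richard(exchange_params(0, 700, 2, 13), 100, 600), 13)
})

test_that("exchange broadening scales up with the static field", {
  p <- exchange_params(0.02, 3000, 2, 10)  # fast regime
  nu <- nu_grid_default()
  rex_500 <- {
    r <- simulate_dispersion(p, nu, 500); r[which.min(nu)] - r[which.max(nu)]
  }
  rex_600 <- {
    r <- simulate_dispersion(p, nu, 600); r[which.min(nu)] - r[which.max(nu)]
  }
  expect_gt(rex_600, rex_500)
  # angular shift difference is linear in the field
  expect_equal(slimbind:::dw_rad_per_s(2, 600) / slimbind:::dw_rad_per_s(2, 500),
               1.2, tolerance = 1e-12)
})

test_that("non-integer echo counts are rejected with the offending nu", {
  p <- exchange_params(0.02, 800, 2, 10)
  expect_error(simulate_dispersion(p, 17.3, 600), "17.3")
})

test_that("Rex amplitude is the low-minus-high frequency difference", {
  expect_equal(rex_amplitude(data.frame(nu_cpmg = c(25, 100, 400),
                                        r2eff = c(8, 8, 8))), 0)
  p <- exchange_params(0.02, 1000, 2, 10)
  nu <- nu_grid_default()
  r2 <- simulate_dispersion(p, nu, 600)
  rex <- rex_amplitude(data.frame(nu_cpmg = nu, r2eff = r2))
  expect_gt(rex, 0)
  expect_equal(rex, r2[which.min(nu)] - r2[which.max(nu)])
  # duplicates averaged before differencing
  expect_equal(rex_amplitude(data.frame(nu_cpmg = c(25, 25, 400),
                                        r2eff = c(10, 12, 8))), 3)
  expect_error(rex_amplitude(data.frame(nu_cpmg = 25, r2eff = 3)), "distinct")
})

test_that("apo-like datasets show near-zero Rex for every residue", {
  pars <- setNames(lapply(1:4, function(i) exchange_params(0, 700, 2, 10)),
                   paste0("A", 1:4))
  ds <- gen_cpmg(pars, seed = 6)
  for (r in unique(ds$residue)) {
    d <- ds[ds$residue == r & ds$field_mhz == 600, ]
    expect_lt(abs(rex_amplitude(d)), 1.5)
  }
})

test_that("zero-noise generation round-trips through the forward model", {
  pars <- cpmg_param_set(0.03, 900, n = 3)
  ds <- gen_cpmg(pars, intensity_noise_sd = 0, seed = 8)
  for (r in names(pars)) {
    for (f in c(500, 600)) {
      d <- ds[ds$residue == r & ds$field_mhz == f, ]
      sim <- simulate_dispersion(pars[[r]], d$nu_cpmg, f)
      expect_equal(d$r2eff, sim, tolerance = 1e-10)
    }
  }
})

test_that("duplicate-derived sigma estimates the injected noise within x3", {
  pars <- cpmg_param_set(0.02, 800, n = 3)
  ratios <- vapply(1:100, function(s) {
    ds <- gen_cpmg(pars, intensity_noise_sd = 0.007, seed = s)
    # truth: sigma(R2) at plateau ~ noise_sd / (I * t)
    d <- ds[ds$residue == names(pars)[1] & ds$field_mhz == 600, ]
    i_pl <- exp(-max(d$r2eff) * 0.039)
    sig_true <- 0.007 / (i_pl * 0.039)
    median(d$sigma) / sig_true
  }, numeric(1))
  expect_gt(mean(ratios > 1 / 3 & ratios < 3), 0.95)
})

test_that("noiseless global fit recovers the planted parameters exactly", {
  pars <- cpmg_param_set(0.024, 800, n = 4)
  ds <- gen_cpmg(pars, intensity_noise_sd = 0, seed = 5)
  fit <- fit_dispersion_global(ds, mode = "naive")
  expect_lt(fit$reduced_chi2, 1e-6)
  expect_equal(fit$p_b, 0.024, tolerance = 1e-3)
  expect_equal(fit$k_ex, 800, tolerance = 1e-2)
  dw_true <- vapply(pars, `[[`, numeric(1), "dw_ppm")
  expect_equal(unname(fit$dw_ppm[names(pars)]), unname(dw_true),
               tolerance = 1e-3)
})

test_that("constrained and naive fits agree on |dw| when dR2 > 0 is planted", {
  set.seed(5)
  dw <- runif(8, 1, 3)
  pars <- setNames(lapply(1:8, function(i)
    exchange_params(p_b = 0.049, k_ex = 700, dw_ppm = dw[i],
                    r2_a = 12, r2_b = 40)), paste0("R", 1:8))
  ds <- gen_cpmg(pars, seed = 21)
  fn <- fit_dispersion_global(ds, mode = "naive")
  fc <- fit_dispersion_global(ds, mode = "constrained", fixed_p_b = 0.049)
  expect_lt(sqrt(mean((fn$dw_ppm - fc$dw_ppm)^2)), 0.4)
  # constrained mode recovers the planted excited-state broadening
  expect_equal(mean(fc$r2_b - fc$r2_a), 28, tolerance = 0.15)
  expect_equal(fc$k_ex, 700, tolerance = 0.1)
})

test_that("exchange parameters convert to rate constants per mass balance", {
  r <- rates_from_exchange(0.02, 1000, 80, 1500)
  expect_equal(r$l_free, 50)
  expect_equal(r$k_off, 980)
  expect_equal(r$k_on, 0.4)          # /uM/s, i.e. 4.0e5 /M/s
  expect_equal(r$kd, 2450)           # uM
  expect_equal(r$kd * r$k_on, r$k_off)
  # koff -> kex as the population vanishes
  expect_equal(rates_from_exchange(1e-6, 750, 100, 10)$k_off, 750,
               tolerance = 1e-5)
  expect_error(rates_from_exchange(0.2, 1000, 80, 1500), "Lfree")
})

test_that("rate uncertainties propagate to first order", {
  r <- rates_from_exchange(0.02, 1000, 80, 1500, p_b_sd = 0.002, k_ex_sd = 50)
  num <- sqrt((0.002 * 1000)^2 + ((1 - 0.02) * 50)^2)
  expect_equal(r$k_off_sd, num, tolerance = 1e-10)
  expect_true(all(c(r$k_on_sd, r$kd_sd) > 0))
})
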