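test_that("active fraction follows first-order irreversible kinetics", {
  expect_equal(active_fraction(0.5, 0), 0)
  expect_equal(active_fraction(0.017, 60), 1 - exp(-1.02))
  expect_equal(active_fraction(1e9, 1), 1, tolerance = 1e-12)
  expect_error(active_fraction(-1, 10))
  expect_error(active_fraction(1, -10))
  tt <- seq(0, 2000, by = 50)
  f <- active_fraction(3e-3, tt)
  expect_true(all(diff(f) >= 0) && all(f >= 0 & f <= 1))
})

test_that("memory fraction reproduces the slow-conversion timescale", {
  expect_equal(memory_fraction(0.8e-3, 1680), 0.7392, tolerance = 1e-4)
  expect_equal(memory_fraction(0.8e-3, 1200), 0.6171, tolerance = 1e-4)
  expect_equal(memory_fraction(0.8e-3, 0), 0)
  # Nup98 depletion + hormone withdrawn: instant reversion
  expect_equal(memory_fraction(0.8e-3, 1680, nup98_depleted = TRUE), 0)
  expect_gt(memory_fraction(0.8e-3, 1680, nup98_depleted = TRUE,
                            hormone_present = TRUE), 0)
  tt <- seq(0, 5000, by = 100)
  f <- memory_fraction(0.8e-3, tt)
  expect_true(all(diff(f) >= 0) && all(f >= 0 & f <= 1))
})

test_that("effective loading rate saturates at the packing cap v/s", {
  expect_equal(effective_loading_rate(0, 150, 1500), 0)
  expect_equal(effective_loading_rate(Inf, 150, 1500), 10)
  expect_equal(effective_loading_rate(5, 150, 1500), 5 / 1.5)
  lam <- 10^seq(-3, 3, length.out = 50)
  r <- effective_loading_rate(lam, 150, 1500)
  expect_true(all(diff(r) > 0))
  expect_true(all(r <= 10))
  expect_equal(effective_loading_rate(1e-4, 150, 1500), 1e-4,
               tolerance = 1e-4)
})

test_that("effective loading rate matches long-run footprint-gated simulation", {
  # stochastic oracle: forced-active single locus, attempt rate 5/min,
  # footprint 150 nt; completed mRNAs per minute ~ 3.33
  p <- kinetic_params(k_A = 1000, k_pol = 5, footprint_nt = 150)
  tr <- simulate_locus(promoter_model_spec("two_state_model1"), p,
                       default_gene(), one_induction(8000),
                       sample_times = c(100, 8000), seed = 99)
  rate <- diff(tr$completed_mrna_count) / 7900
  expect_equal(rate, effective_loading_rate(5, 150, 1500), tolerance = 0.06)
})

test_that("mean production rate covers all three model variants", {
  params <- kinetic_params()
  m1 <- promoter_model_spec("two_state_model1")
  m2 <- promoter_model_spec("two_state_model2")
  ms <- promoter_model_spec("memory_switch")

  expect_equal(mean_production_rate(m1, params, 0), 0)
  # converted population at re-induction: 0.74*4.5 + 0.26*0.3
  fast <- kinetic_params(k_A = 1000)
  expect_equal(mean_production_rate(ms, fast, 1, f_M0 = 0.74), 3.408,
               tolerance = 2e-3)
  # Model 2 linear regime
  expect_equal(mean_production_rate(m2, params, 1), params$alpha * 1,
               tolerance = 2e-3)
  expect_error(mean_production_rate(m1, params, -1))
})

test_that("memory switch degenerates to Model 1 when loading rates coincide", {
  base <- kinetic_params(k_polL = 2, k_polH = 2, k_polB = 0, k_pol = 2)
  m1 <- promoter_model_spec("two_state_model1")
  ms <- promoter_model_spec("memory_switch")
  tt <- seq(0, 240, by = 10)
  expect_equal(mean_production_rate(ms, base, tt),
               mean_production_rate(m1, base, tt), tolerance = 1e-12)
})

test_that("protocols validate their segments", {
  p <- standard_protocol()
  expect_equal(p$total_min, 1920)
  expect_equal(p$segments$hormone, c(TRUE, FALSE, TRUE))
  expect_error(induction_protocol(data.frame(duration_min = -1,
                                             hormone = TRUE,
                                             nup98_depleted = FALSE,
                                             inhibitor = "none")))
  expect_error(induction_protocol(data.frame(duration_min = 10,
                                             hormone = TRUE,
                                             nup98_depleted = FALSE,
                                             inhibitor = "DRB")))
  expect_error(induction_protocol(data.frame(duration_min = 10)),
               "missing column")
})

test_that("params and protocols round-trip through config files", {
  p <- kinetic_params(k_A = 0.02, k_C = 1e-3, footprint_nt = 120)
  path <- tempfile(fileext = ".json")
  write_params(p, path)
  expect_equal(read_params(path), p)

  proto <- standard_protocol(inhibitor_first = "FP")
  path2 <- tempfile(fileext = ".json")
  write_protocol(proto, path2)
  expect_equal(read_protocol(path2), proto)

  if (requireNamespace("yaml", quietly = TRUE)) {
    path3 <- tempfile(fileext = ".yaml")
    write_params(p, path3)
    expect_equal(read_params(path3), p)
  }
})
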