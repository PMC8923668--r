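test_that("constant-production closed form matches its ODE", {
  expect_equal(mean_constant_production(5, 200, 42, 0), 42)
  expect_equal(mean_constant_production(12, 100, 0, 1e7), 1200)
  expect_equal(mean_constant_production(12, 100, 0, 100),
               1200 * (1 - exp(-1)))
  # numeric ODE oracle
  tt <- seq(0, 400, by = 20)
  ode <- deSolve::ode(c(m = 3), tt, function(t, y, p) list(12 - y / 100),
                      NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(mean_constant_production(12, 100, 3, tt),
               unname(ode[, "m"]), tolerance = 1e-7)
})

test_that("linear-production closed form matches its ODE and limits", {
  expect_equal(mean_linear_production(0, 150, 80, 300), 80 * exp(-2))
  # early-time Taylor limit: m ~ a t^2 / 2
  expect_equal(mean_linear_production(0.02, 600, 0, 1),
               0.02 / 2, tolerance = 1e-3)
  expect_equal(mean_linear_production(0.06, 600, 0, 240),
               36 * (240 - 600 * (1 - exp(-0.4))))
  tt <- seq(0, 240, by = 10)
  ode <- deSolve::ode(c(m = 0), tt, function(t, y, p) list(0.06 * t - y / 600),
                      NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(mean_linear_production(0.06, 600, 0, tt),
               unname(ode[, "m"]), tolerance = 1e-7)
})

test_that("model mean curves integrate correctly and scale with locus count", {
  params <- kinetic_params(k_A = 5.1e-3, k_pol = 2)
  m1 <- promoter_model_spec("two_state_model1")
  tt <- seq(0, 240, by = 30)
  # closed-form oracle for Model 1: double-exponential solution of the ODE
  closed <- function(t, kA, kpol, n, tau) {
    P <- n * kpol
    P * tau * (1 - exp(-t / tau)) -
      P * (exp(-kA * t) - exp(-t / tau)) / (1 / tau - kA)
  }
  expect_equal(mean_model_curve(m1, params, tau = 600, n_loci = 6,
                                t_grid = tt),
               closed(tt, 5.1e-3, 2, 6, 600), tolerance = 1e-6)
  expect_equal(mean_model_curve(m1, params, 600, 6, tt),
               6 * mean_model_curve(m1, params, 600, 1, tt),
               tolerance = 1e-6)

  # memory switch without hormone-driven loading stays at pure decay
  ms <- promoter_model_spec("memory_switch")
  dead <- kinetic_params(k_polB = 0, k_polL = 0, k_polH = 0)
  expect_equal(mean_model_curve(ms, dead, 600, 6, tt, m0 = 100),
               100 * exp(-tt / 600), tolerance = 1e-6)

  # f_M = 0 memory switch equals Model 1 at k_pol = k_polL
  frozen <- kinetic_params(k_A = 5.1e-3, k_C = 0, k_polB = 0, k_polL = 2,
                           k_polH = 9)
  expect_equal(mean_model_curve(ms, frozen, 600, 6, tt),
               mean_model_curve(m1, params, 600, 6, tt), tolerance = 1e-6)
})

test_that("degradation fitting recovers lifetimes and flags bad input", {
  tt <- seq(0, 240, by = 30)
  clean <- data.frame(time_min = tt, mrna_per_cell = 500 * exp(-tt / 120))
  fit <- fit_degradation(clean)
  expect_equal(fit$lifetime_tau, 120, tolerance = 1e-6)
  expect_equal(fit$m0, 500, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
  expect_true(fit$ci95["tau", 1] <= 120 && 120 <= fit$ci95["tau", 2])

  flat <- data.frame(time_min = tt, mrna_per_cell = rep(100, length(tt)))
  expect_warning(ffit <- fit_degradation(flat), "does not decay")
  expect_equal(ffit$flag, "non_decaying")
  expect_equal(ffit$lifetime_tau, 1e6)

  expect_error(fit_degradation(clean[1:3, ]), "4 distinct time points")
})

test_that("accumulation fits recover production parameters", {
  tt <- seq(0, 240, by = 30)
  # noiseless constant production: exact recovery
  const <- data.frame(time_min = tt,
                      mrna_per_cell = mean_constant_production(12, 600, 0, tt))
  fit_c <- fit_accumulation("constant", const, tau = 600)
  expect_equal(unname(fit_c$params["P_cell"]), 12, tolerance = 1e-6)

  # noiseless Model 1: exact recovery of both parameters
  p <- kinetic_params(k_A = 5.1e-3, k_pol = 2)
  m1curve <- mean_model_curve(promoter_model_spec("two_state_model1"), p,
                              600, 6, tt)
  fit_m1 <- fit_accumulation("model1",
                             data.frame(time_min = tt,
                                        mrna_per_cell = m1curve),
                             tau = 600)
  expect_equal(unname(fit_m1$params["k_pol"]), 2, tolerance = 1e-3)
  expect_equal(unname(fit_m1$params["k_A"]), 5.1e-3, tolerance = 1e-3)
  expect_true(all(fit_m1$ci95[, "lower"] <= fit_m1$params &
                  fit_m1$params <= fit_m1$ci95[, "upper"]))
})

test_that("accumulation and per-locus transcription rates derive correctly", {
  tt <- seq(0, 240, by = 30)
  const <- data.frame(time_min = tt,
                      mrna_per_cell = mean_constant_production(12, 100, 0, tt))
  fit_c <- fit_accumulation("constant", const, tau = 100)
  r <- accumulation_rate(fit_c, c(0, 2000))
  expect_equal(r$accumulation_rate[2], 0, tolerance = 1e-4)
  expect_equal(r$transcription_rate_per_locus, rep(12 / 6, 2),
               tolerance = 1e-4)

  lin <- data.frame(time_min = tt,
                    mrna_per_cell = mean_linear_production(0.05, 600, 0, tt))
  fit_l <- fit_accumulation("linear", lin, tau = 600)
  rl <- accumulation_rate(fit_l, 240)
  # a_cell * t / n_loci: 0.05 * 240 / 6 = 2 mRNA/min per locus
  expect_equal(rl$transcription_rate_per_locus, 2, tolerance = 1e-3)
})
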