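test_that("no loading means no Pol IIs and no completed transcripts", {
  silent <- kinetic_params(k_polB = 0, k_polL = 0, k_polH = 0, k_pol = 0)
  tr <- simulate_locus(promoter_model_spec("memory_switch"), silent,
                       tiny_gene(), one_induction(120),
                       sample_times = c(30, 60, 120), seed = 1)
  expect_true(all(tr$nascent_cu == 0))
  expect_true(all(lengths(tr$polii_positions) == 0))
  expect_true(all(tr$completed_mrna_count == 0))
})

test_that("long-run Pol II occupancy obeys Little's law", {
  # forced-active locus, k_pol = 2/min, negligible footprint:
  # mean Pol II on gene = k_pol * L / v = 6
  p <- kinetic_params(k_A = 1000, k_pol = 2, footprint_nt = 1)
  tr <- simulate_locus(promoter_model_spec("two_state_model1"), p,
                       default_gene(), one_induction(10000),
                       sample_times = seq(50, 10000, by = 25), seed = 5)
  occ <- lengths(tr$polii_positions)
  # samples 25 min apart are effectively independent (residence time 3 min)
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - 6), 3 * se + 0.05)
})

test_that("footprint exclusion caps density and spacing", {
  p <- kinetic_params(k_A = 1000, k_pol = 50, footprint_nt = 150)
  tr <- simulate_locus(promoter_model_spec("two_state_model1"), p,
                       default_gene(), one_induction(120),
                       sample_times = seq(10, 120, by = 10), seed = 21)
  for (pos in tr$polii_positions) {
    expect_lte(length(pos), 30)  # packing bound L/s
    if (length(pos) > 1) {
      expect_gte(min(abs(diff(sort(pos)))), 150 - 1e-9)
    }
  }
})

test_that("populations mix 4- and 8-locus cells equally", {
  p <- kinetic_params()
  pop <- simulate_population(promoter_model_spec("memory_switch"), p,
                             tiny_gene(), one_induction(30), n_cells = 10,
                             sample_times = 30, seed = 2, return_loci = TRUE)
  cells <- pop$cells
  expect_equal(nrow(pop$loci), 60)
  expect_equal(sum(cells$n_loci == 4), 5)
  expect_equal(sum(cells$n_loci == 8), 5)
  expect_error(simulate_population(promoter_model_spec("memory_switch"), p,
                                   tiny_gene(), one_induction(30), 7, 30))
})

test_that("uninduced cells show no nascent signal and Poisson puncta", {
  p <- kinetic_params(k_polB = 0)
  pop <- simulate_population(promoter_model_spec("memory_switch"), p,
                             tiny_gene(), uninduced_protocol(60), 600,
                             sample_times = 60, seed = 3, tau = 1e5,
                             uninduced_mean_puncta = 2)
  expect_true(all(pop$nascent_cu == 0))
  # negligible decay at tau = 1e5: counts stay ~Poisson(2)
  expect_equal(mean(pop$mature_count), 2, tolerance = 0.15)
  expect_equal(var(pop$mature_count), 2, tolerance = 0.3)
})

test_that("population mean production tracks the analytic rate curve", {
  # negligible footprint; compare completions per locus over [120, 150] min
  p <- kinetic_params(footprint_nt = 1)
  spec <- promoter_model_spec("memory_switch")
  pop <- simulate_population(spec, p, default_gene(), one_induction(240),
                             1000, sample_times = c(120, 150), seed = 8,
                             return_loci = TRUE)
  loci <- pop$loci
  done <- tapply(loci$completed, loci$locus_id, function(x) diff(range(x)))
  rate <- done / 30
  # completions lag loading by L/v = 3 min
  expected <- mean(mean_production_rate(spec, p, seq(117, 147, by = 1)))
  se <- sd(rate) / sqrt(length(rate))
  expect_lt(abs(mean(rate) - expected), 3 * se)
})

test_that("the recovery shortcut reassigns memory analytically", {
  p <- kinetic_params()
  st <- list(active = rep(TRUE, 20000), memory = rep(FALSE, 20000),
             pool = rep(10L, 1000), elapsed_min = 240)
  set.seed(4)
  out <- apply_recovery_shortcut(st, p, recovery_min = 1440, tau = 600)
  expect_equal(mean(out$memory), memory_fraction(8e-4, 1680),
               tolerance = 0.015)
  expect_true(all(!out$active))
  expect_equal(mean(out$pool) / 10, exp(-1440 / 600), tolerance = 0.02)
  expect_equal(out$elapsed_min, 1680)

  out_nup <- apply_recovery_shortcut(st, p, 1440, nup98_depleted = TRUE)
  expect_true(all(!out_nup$memory))

  # shorter recovery converts fewer loci
  st2 <- list(active = logical(20000), memory = logical(20000),
              pool = integer(1000), elapsed_min = 60)
  set.seed(5)
  out6 <- apply_recovery_shortcut(st2, p, 360, tau = 600)
  expect_equal(mean(out6$memory), 1 - exp(-8e-4 * 420), tolerance = 0.015)
  expect_lt(mean(out6$memory), mean(out$memory))
})

test_that("seeded runs are reproducible and engines agree", {
  p <- kinetic_params()
  spec <- promoter_model_spec("memory_switch")
  a <- simulate_population(spec, p, default_gene(), one_induction(60), 100,
                           sample_times = 60, seed = 7)
  b <- simulate_population(spec, p, default_gene(), one_induction(60), 100,
                           sample_times = 60, seed = 7)
  expect_identical(a, b)
  c <- simulate_population(spec, p, default_gene(), one_induction(60), 100,
                           sample_times = 60, seed = 8)
  expect_false(isTRUE(all.equal(a$nascent_cu, c$nascent_cu)))

  ev <- simulate_population(spec, p, default_gene(), one_induction(60), 300,
                            sample_times = 60, seed = 9, engine = "event")
  fx <- simulate_population(spec, p, default_gene(), one_induction(60), 300,
                            sample_times = 60, seed = 9, engine = "fixed")
  expect_gt(suppressWarnings(
    ks.test(ev$nascent_cu, fx$nascent_cu)$p.value), 0.01)
})

test_that("transcription inhibitors silence loading but not conversion", {
  p <- kinetic_params(k_polB = 0)
  spec <- promoter_model_spec("memory_switch")
  prot <- one_induction(240, inhibitor = "FP")
  pop <- simulate_population(spec, p, default_gene(), prot, 100,
                             sample_times = c(60, 240), seed = 10,
                             return_loci = TRUE, uninduced_mean_puncta = 0)
  expect_true(all(pop$cells$nascent_cu == 0))
  # conversion proceeded regardless of the block: state bit 2 set for ~17%
  mem <- bitwAnd(pop$loci$state[pop$loci$time_min == 240], 2L) > 0
  expect_equal(mean(mem), memory_fraction(8e-4, 240), tolerance = 0.03)
})
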