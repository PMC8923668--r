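# build a cu_histogram with equal mass in the given bins of a shared domain
flat_hist <- function(edges, bins) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cu_histogram(rep(10^mids[bins], 100), edges)
}

test_that("activity histograms normalize with an underflow pseudo-bin", {
  edges <- seq(log10(0.5), 2, length.out = 31)
  h0 <- cu_histogram(rep(0, 50), edges)
  expect_equal(h0$underflow_mass, 1)
  expect_true(all(h0$density == 0))

  w <- diff(edges)[1]
  one_bin <- cu_histogram(rep(10^(edges[1] + w / 2), 30), edges)
  expect_equal(sum(one_bin$density > 0), 1)
  expect_equal(sum(one_bin$density) * w, 1)

  set.seed(1)
  v <- rlnorm(1000, 1, 1)
  h <- cu_histogram(v, edges)
  expect_equal(sum(h$density) * w + h$underflow_mass, 1, tolerance = 1e-12)

  expect_error(cu_histogram(v, c(0, 1, 3)), "identical width")
  expect_error(cu_histogram(c(-1, 2), edges), "non-negative")
})

test_that("Jaccard score is 1 on identical, 0 on disjoint, 1/3 on half overlap", {
  edges <- seq(0, 2, length.out = 21)
  a <- flat_hist(edges, 1:10)    # uniform over [0, 1]
  b <- flat_hist(edges, 11:20)   # uniform over [1, 2]
  half <- flat_hist(edges, 6:15) # uniform over [0.5, 1.5]
  expect_equal(jaccard_score(a, a), 1.0)
  expect_equal(jaccard_score(a, b), 0.0)
  expect_equal(jaccard_score(a, half), 1 / 3)
  # symmetry
  expect_equal(jaccard_score(half, a), jaccard_score(a, half))
  expect_error(jaccard_score(a, flat_hist(seq(0, 3, length.out = 21), 1:10)),
               "mismatched bin edges")
})

test_that("Jaccard score decreases monotonically with translation", {
  edges <- seq(0, 4, length.out = 41)
  ref <- flat_hist(edges, 1:10)
  scores <- vapply(0:30, function(s) {
    jaccard_score(ref, flat_hist(edges, (1:10) + s))
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_equal(scores[1], 1)
})

test_that("pooled score includes underflow and multiple time points", {
  edges <- seq(0, 2, length.out = 21)
  a <- cu_histogram(c(rep(0, 50), rep(10, 50)), edges)
  b <- cu_histogram(c(rep(0, 50), rep(10, 50)), edges)
  expect_equal(jaccard_score(list(a, a), list(b, b)), 1)
  d <- cu_histogram(rep(0, 100), edges)
  # intersection = underflow overlap 0.5; union = 1.5
  expect_equal(jaccard_score(a, d), 0.5 / 1.5)
})

test_that("grid search attains its maximum at the generating parameters", {
  spec <- promoter_model_spec("memory_switch")
  p <- kinetic_params()
  g <- default_gene()
  prot <- one_induction(240)
  obs <- simulate_population(spec, p, g, prot, 1200,
                             sample_times = c(60, 120, 240), seed = 31)
  # three-point grid bracketing the truth by 4x on either side
  sr <- grid_search(obs, spec, p, g, prot, free = "k_C",
                    ranges = list(k_C = c(8e-4 / 4, 8e-4 * 4)),
                    n_coarse = 3, n_refine = 0,
                    n_cells_coarse = 1200, seed = 17)
  expect_equal(unname(sr$best_params["k_C"]), 8e-4, tolerance = 1e-9)
  expect_true(all(sr$grid$score <= sr$best_score, na.rm = TRUE))
  expect_gt(sr$best_score, 0.8)
})

test_that("grid search surfaces are reproducible under a fixed seed", {
  spec <- promoter_model_spec("memory_switch")
  p <- kinetic_params()
  g <- tiny_gene()
  prot <- one_induction(60)
  obs <- simulate_population(spec, p, g, prot, 200, sample_times = 60,
                             seed = 12)
  s1 <- grid_search(obs, spec, p, g, prot, free = "k_A",
                    ranges = list(k_A = c(1e-3, 1e-1)), n_coarse = 3,
                    n_refine = 1, refine_points = 3, n_cells_coarse = 200,
                    n_cells_fine = 200, seed = 77)
  s2 <- grid_search(obs, spec, p, g, prot, free = "k_A",
                    ranges = list(k_A = c(1e-3, 1e-1)), n_coarse = 3,
                    n_refine = 1, refine_points = 3, n_cells_coarse = 200,
                    n_cells_fine = 200, seed = 77)
  expect_identical(s1$grid, s2$grid)
})

test_that("the mean-rate constraint can empty the feasible grid", {
  spec <- promoter_model_spec("memory_switch")
  p <- kinetic_params()
  g <- tiny_gene()
  prot <- one_induction(60)
  obs <- simulate_population(spec, p, g, prot, 200, sample_times = 60,
                             seed = 13)
  impossible <- function(ind, t) rep(1e6, length(t))
  expect_error(
    grid_search(obs, spec, p, g, prot, free = "k_A",
                ranges = list(k_A = c(1e-3, 1e-1)), n_coarse = 3,
                n_refine = 0, n_cells_coarse = 200,
                rate_target = impossible, rate_tol = 0.15, seed = 1),
    "empty feasible grid")
})

test_that("bootstrap intervals collapse on zero-variance data and cover truth", {
  spec <- promoter_model_spec("memory_switch")
  p <- kinetic_params()
  g <- tiny_gene()
  prot <- one_induction(60)

  flat <- data.frame(cell_id = 1:60, induction = 1, time_min = 60,
                     n_loci = 4, nascent_cu = 0, mature_count = 0)
  ci0 <- bootstrap_ci(flat, spec, p, g, prot, free = "k_A", n_boot = 3,
                      seed = 5, ranges = list(k_A = c(1e-3, 1e-1)),
                      n_coarse = 2, n_refine = 0, n_cells_coarse = 100)
  expect_equal(ci0$sd, 0)
  expect_equal(ci0$lower, ci0$upper)

  obs <- simulate_population(spec, p, g, prot, 400, sample_times = 60,
                             seed = 14)
  ci <- bootstrap_ci(obs, spec, p, g, prot, free = "k_A", n_boot = 6,
                     seed = 6, ranges = list(k_A = c(17e-3 / 3, 17e-3 * 3)),
                     n_coarse = 5, n_refine = 1, refine_points = 3,
                     n_cells_coarse = 400, n_cells_fine = 400)
  expect_true(ci$lower <= 17e-3 && 17e-3 <= ci$upper)
})
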