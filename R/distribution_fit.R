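#' Histogram of per-cell activity on the log(C.U.) axis
#'
#' Builds an area-normalized histogram of `log10` per-cell nascent activity
#' with identical-width bins. Cells whose activity falls below the log
#' domain (including zeros) are collected in an underflow pseudo-bin so that
#' total mass (bin area plus underflow) is exactly 1; values at or beyond
#' the last edge are counted in the last bin.
#'
#' @param values non-negative per-cell activities (C.U.).
#' @param edges strictly increasing, identical-width bin edges on the
#'   log10(C.U.) axis.
#' @return An object of class `cu_histogram` with fields `edges`, `density`,
#'   `underflow_mass` and `n`.
#' @export
cu_histogram <- function(values, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    stop("`edges` must be strictly increasing with at least two values")
  }
  w <- diff(edges)
  if (max(w) - min(w) > 1e-9 * mean(w)) {
    stop("`edges` must define bins of identical width")
  }
  if (any(values < 0)) stop("activities must be non-negative")
  n <- length(values)
  lv <- suppressWarnings(log10(values))
  under <- sum(values <= 0 | lv < edges[1])
  inside <- lv[values > 0 & lv >= edges[1]]
  idx <- pmin(findInterval(inside, edges, rightmost.closed = FALSE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  density <- if (n > 0) counts / (n * w[1]) else counts * 0
  structure(list(edges = edges, density = density,
                 underflow_mass = if (n > 0) under / n else 0, n = n),
            class = "cu_histogram")
}

#' Default shared bin edges for activity histograms
#'
#' 30 identical-width bins on log10(C.U.) spanning `[log10(0.5), max]` of
#' the pooled positive values; cells below 0.5 C.U. fall into the underflow
#' pseudo-bin. Shared edges between simulated and observed histograms are
#' essential because the overlap score depends on edge positions.
#'
#' @param values pooled activities (C.U.) used to set the upper edge.
#' @param n_bins number of bins.
#' @param lower_cu lower domain limit in C.U.
#' @return Numeric vector of edges on the log10 axis.
#' @export
default_cu_edges <- function(values, n_bins = 30, lower_cu = 0.5) {
  pos <- values[values > 0]
  lo <- log10(lower_cu)
  # fully inactive populations carry all mass in the underflow bin
  hi <- if (length(pos)) max(log10(pos)) else lo + 1
  if (hi <= lo) hi <- lo + 1
  seq(lo, hi, length.out = n_bins + 1)
}

#' Jaccard overlap of simulated and observed activity histograms
#'
#' Goodness-of-fit score between matched sets of [cu_histogram]s: the areas
#' of intersection between simulated and observed histograms at each time
#' point are summed and divided by the summed areas of union (pooled-union
#' reading; per-time averaging available via `pooled = FALSE`). Underflow
#' masses enter as an extra pseudo-bin. The score is 1 for identical
#' histograms and 0 for disjoint supports.
#'
#' @param sim,obs a `cu_histogram` or list of them (same length and matching
#'   bin edges per element).
#' @param pooled sum intersections/unions across time points before taking
#'   the ratio (default), or average per-time scores.
#' @return Score in `[0, 1]`.
#' @export
jaccard_score <- function(sim, obs, pooled = TRUE) {
  if (inherits(sim, "cu_histogram")) sim <- list(sim)
  if (inherits(obs, "cu_histogram")) obs <- list(obs)
  if (length(sim) != length(obs)) stop("`sim` and `obs` must be same length")
  inter <- numeric(length(sim))
  uni <- numeric(length(sim))
  for (k in seq_along(sim)) {
    s <- sim[[k]]; o <- obs[[k]]
    if (length(s$edges) != length(o$edges) ||
        max(abs(s$edges - o$edges)) > 1e-9) {
      stop("mismatched bin edges between simulated and observed histograms")
    }
    w <- diff(s$edges)[1]
    inter[k] <- sum(pmin(s$density, o$density)) * w +
      min(s$underflow_mass, o$underflow_mass)
    uni[k] <- sum(pmax(s$density, o$density)) * w +
      max(s$underflow_mass, o$underflow_mass)
  }
  if (pooled) {
    if (sum(uni) == 0) return(0)
    sum(inter) / sum(uni)
  } else {
    mean(ifelse(uni == 0, 0, inter / uni))
  }
}

#' @keywords internal
#' @noRd
obs_histograms <- function(cells, edges) {
  keys <- unique(cells[, c("induction", "time_min")])
  keys <- keys[order(keys$induction, keys$time_min), , drop = FALSE]
  hs <- lapply(seq_len(nrow(keys)), function(i) {
    v <- cells$nascent_cu[cells$induction == keys$induction[i] &
                          cells$time_min == keys$time_min[i]]
    cu_histogram(v, edges)
  })
  list(keys = keys, histograms = hs)
}

#' @keywords internal
#' @noRd
score_params <- function(candidate, spec, gene, protocol, obs_keys, obs_hists,
                         edges, n_cells, tau, uninduced_mean_puncta, seed) {
  pop <- simulate_population(spec, candidate, gene, protocol, n_cells,
                             sample_times = unique(obs_keys$time_min),
                             seed = seed, tau = tau,
                             uninduced_mean_puncta = uninduced_mean_puncta)
  sim <- lapply(seq_len(nrow(obs_keys)), function(i) {
    v <- pop$nascent_cu[pop$induction == obs_keys$induction[i] &
                        pop$time_min == obs_keys$time_min[i]]
    cu_histogram(v, edges)
  })
  jaccard_score(sim, obs_hists)
}

#' Grid-search inference of promoter kinetics by histogram overlap
#'
#' Simulation-based inference: free kinetic parameters are searched on a
#' coarse log-spaced grid over their allowed ranges, then refined with local
#' linear grids around the running optimum (each refinement halves the
#' relative span), maximizing the Jaccard overlap [jaccard_score()] between
#' simulated and observed per-cell log-activity histograms across all
#' observed (induction, time) combinations. An optional mean-rate constraint
#' discards candidates whose analytic mean production-rate curve deviates
#' from a target curve by more than `rate_tol` RMS (relative), emulating the
#' use of prior bulk fits to narrow the search space.
#'
#' @param obs observed cell table with columns `induction`, `time_min`,
#'   `nascent_cu` (as produced by [simulate_population()]).
#' @param spec a [promoter_model_spec].
#' @param base_params a [kinetic_params]; non-free parameters are held at
#'   these values.
#' @param gene a [gene_model].
#' @param protocol an [induction_protocol].
#' @param free character vector naming the free parameters (fields of
#'   [kinetic_params()]).
#' @param ranges named list of length-2 numeric ranges for the free
#'   parameters; defaults are the canonical search bounds, `1e-8..1` per min
#'   for first-order rates and `1e-7..10` per min for loading rates.
#' @param n_coarse points per parameter on the coarse log grid.
#' @param n_refine number of local refinement stages.
#' @param refine_points points per parameter per refinement grid.
#' @param n_cells_coarse,n_cells_fine cells simulated per candidate in the
#'   coarse and refinement stages.
#' @param edges histogram bin edges; defaults to [default_cu_edges()] of the
#'   observed activities.
#' @param rate_target optional function `(induction, t)` giving the target
#'   mean production rate (mRNA/min per locus) used as constraint, or `NULL`.
#' @param rate_tol relative RMS tolerance of the rate constraint.
#' @param tau,uninduced_mean_puncta passed to [simulate_population()].
#' @param seed integer seed; every candidate evaluation uses a seed derived
#'   deterministically from it.
#' @return An object of class `search_result`: `best_params` (named numeric),
#'   `params` (full [kinetic_params]), `best_score`, `grid` (data.frame of
#'   all evaluated combinations with scores and stage), `seed`, `n_cells`.
#' @export
grid_search <- function(obs, spec, base_params, gene, protocol,
                        free = c("k_A", "k_C"),
                        ranges = NULL,
                        n_coarse = 8, n_refine = 2, refine_points = 7,
                        n_cells_coarse = 2000, n_cells_fine = 8000,
                        edges = NULL, rate_target = NULL, rate_tol = 0.15,
                        tau = 600, uninduced_mean_puncta = 2, seed = 1L) {
  default_ranges <- list(k_A = c(1e-8, 1), k_C = c(1e-8, 1),
                         k_polB = c(1e-7, 10), k_polL = c(1e-7, 10),
                         k_polH = c(1e-7, 10), k_pol = c(1e-7, 10),
                         alpha = c(1e-7, 10))
  if (is.null(ranges)) ranges <- default_ranges[free]
  if (!all(free %in% names(ranges))) stop("missing range for a free parameter")
  oh <- obs_histograms(obs, if (is.null(edges))
    default_cu_edges(obs$nascent_cu) else edges)
  edges <- oh$histograms[[1]]$edges

  hseg <- which(protocol$segments$hormone)
  elapsed_2nd <- if (length(hseg) >= 2) {
    protocol$segments$start_min[hseg[2]] - protocol$segments$start_min[hseg[1]]
  } else NA_real_

  feasible <- function(cand) {
    if (is.null(rate_target)) return(TRUE)
    tt <- seq(10, 240, by = 10)
    dev <- 0; norm <- 0
    for (ind in unique(oh$keys$induction)) {
      target <- rate_target(ind, tt)
      f_M0 <- if (ind > 1) memory_fraction(cand$k_C, elapsed_2nd) else 0
      got <- mean_production_rate(spec, cand, tt, f_M0 = f_M0)
      dev <- dev + sum((got - target)^2)
      norm <- norm + sum(target^2)
    }
    sqrt(dev / norm) <= rate_tol
  }

  eval_count <- 0L
  evaluate <- function(theta, n_cells, stage) {
    cand <- base_params
    cand[free] <- as.list(theta)
    eval_count <<- eval_count + 1L
    if (!feasible(cand)) return(NA_real_)
    score_params(cand, spec, gene, protocol, oh$keys, oh$histograms, edges,
                 n_cells, tau, uninduced_mean_puncta,
                 seed = (seed * 1000L + eval_count) %% .Machine$integer.max)
  }

  run_grid <- function(grids, n_cells, stage) {
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    scores <- vapply(seq_len(nrow(combos)), function(i) {
      evaluate(unlist(combos[i, , drop = FALSE]), n_cells, stage)
    }, numeric(1))
    combos$score <- scores
    combos$stage <- stage
    combos$n_cells <- n_cells
    combos
  }

  coarse_grids <- lapply(ranges[free], function(r) {
    exp(seq(log(r[1]), log(r[2]), length.out = n_coarse))
  })
  names(coarse_grids) <- free
  all_grid <- run_grid(coarse_grids, n_cells_coarse, 0L)
  if (all(is.na(all_grid$score))) {
    stop("empty feasible grid: the mean-rate constraint excluded every ",
         "candidate; relax `rate_tol` or the parameter ranges")
  }
  best <- all_grid[which.max(all_grid$score), free, drop = FALSE]

  # Local refinement with edge walking: while the stage optimum sits on the
  # boundary of its local grid the stage is re-centered at constant span
  # (the coarse log grid can land more than a refinement span away from the
  # optimum); once the optimum is interior the span halves.
  st <- 1L
  stages_run <- 0L
  while (st <= n_refine && stages_run < n_refine + 8L) {
    stages_run <- stages_run + 1L
    span <- 0.5 / 2^(st - 1)
    grids <- lapply(free, function(p) {
      ctr <- best[[p]]
      g <- seq(ctr * (1 - span), ctr * (1 + span),
               length.out = refine_points)
      pmin(pmax(g, ranges[[p]][1]), ranges[[p]][2])
    })
    names(grids) <- free
    ncl <- if (st == 1L) n_cells_coarse else n_cells_fine
    g <- run_grid(grids, ncl, st)
    all_grid <- rbind(all_grid, g)
    sub <- g[!is.na(g$score), , drop = FALSE]
    if (nrow(sub)) {
      best_stage <- sub[which.max(sub$score), free, drop = FALSE]
      at_edge <- any(vapply(free, function(p) {
        gp <- grids[[p]]
        on_bound <- best_stage[[p]] <= min(gp) + 1e-15 ||
          best_stage[[p]] >= max(gp) - 1e-15
        clipped <- min(gp) <= ranges[[p]][1] * (1 + 1e-12) &&
          best_stage[[p]] <= min(gp) + 1e-15 ||
          max(gp) >= ranges[[p]][2] * (1 - 1e-12) &&
          best_stage[[p]] >= max(gp) - 1e-15
        on_bound && !clipped
      }, logical(1)))
      best <- best_stage
      if (!at_edge) st <- st + 1L
    } else {
      st <- st + 1L
    }
  }

  # report the optimum among the evaluations with the most cells (the least
  # noisy scores); earlier coarse stages only steer the refinement
  ok <- !is.na(all_grid$score)
  finest <- all_grid[ok & all_grid$n_cells == max(all_grid$n_cells[ok]), ,
                     drop = FALSE]
  best <- finest[which.max(finest$score), free, drop = FALSE]
  best_params <- base_params
  best_params[free] <- as.list(unlist(best))
  structure(list(
    best_params = unlist(best),
    params = best_params,
    best_score = max(finest$score),
    grid = all_grid,
    edges = edges,
    seed = seed,
    n_cells = c(coarse = n_cells_coarse, fine = n_cells_fine)
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> JI =", signif(x$best_score, 4), "\n")
  print(signif(x$best_params, 4))
  invisible(x)
}

#' Bootstrap confidence intervals for grid-search estimates
#'
#' Resamples observed cells with replacement within each (induction, time)
#' group, reruns a narrowed grid search per resample and summarizes each
#' free parameter as mean and mean +/- 2 SD across resamples. The canonical
#' design uses 1000 resamples; smaller values are appropriate for quick
#' analyses.
#'
#' @inheritParams grid_search
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param ... further arguments passed to [grid_search()] (e.g. a narrowed
#'   `ranges`, smaller `n_coarse`, `n_cells_*`).
#' @return A data.frame with one row per free parameter: `mean`, `sd`,
#'   `lower` and `upper` (mean -/+ 2 SD).
#' @export
bootstrap_ci <- function(obs, spec, base_params, gene, protocol,
                         free = c("k_A", "k_C"), n_boot = 1000, seed = 1L,
                         ...) {
  if (n_boot < 2) stop("`n_boot` must be >= 2")
  set.seed(seed)
  groups <- interaction(obs$induction, obs$time_min, drop = TRUE)
  idx_by_group <- split(seq_len(nrow(obs)), groups)
  data_degenerate <- all(obs$nascent_cu == obs$nascent_cu[1])
  est <- matrix(NA_real_, n_boot, length(free),
                dimnames = list(NULL, free))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_group, function(ii)
      sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
    res_b <- obs[idx, , drop = FALSE]
    if (!data_degenerate &&
        all(res_b$nascent_cu == res_b$nascent_cu[1])) {
      warning("degenerate resample (all-identical cells) skipped")
      next
    }
    sr <- grid_search(res_b, spec, base_params, gene, protocol, free = free,
                      seed = seed + b, ...)
    est[b, ] <- sr$best_params[free]
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  data.frame(
    parameter = free,
    mean = colMeans(est),
    sd = apply(est, 2, sd),
    lower = colMeans(est) - 2 * apply(est, 2, sd),
    upper = colMeans(est) + 2 * apply(est, 2, sd),
    row.names = NULL
  )
}
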