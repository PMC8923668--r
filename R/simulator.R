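#' @keywords internal
#' @noRd
resolve_segment_rates <- function(spec, params, segment, seen_hormone) {
  model <- switch(spec$variant, two_state_model1 = 1L,
                  two_state_model2 = 2L, memory_switch = 3L)
  hormone <- isTRUE(segment$hormone)
  inhibited <- segment$inhibitor %in% c("FP", "TPL")
  act_rate <- if (!hormone) 0 else if (model == 2L || spec$immediate_activation)
    1000 else params$k_A
  conv_rate <- if (model != 3L) 0
    else if (hormone || (seen_hormone && !segment$nup98_depleted))
      params$k_C else 0
  if (model == 3L && identical(segment$inhibitor, "TPL")) {
    conv_rate <- conv_rate * params$tpl_kc_factor
  }
  zero <- inhibited
  list(
    model = model,
    act_rate = act_rate,
    conv_rate = conv_rate,
    polB = if (zero) 0 else if (model == 3L) params$k_polB else 0,
    polL = if (zero) 0 else if (model == 1L) params$k_pol else params$k_polL,
    polH = if (zero) 0 else if (model == 1L) params$k_pol else params$k_polH,
    alpha = if (zero || !hormone) 0 else params$alpha
  )
}

#' @keywords internal
#' @noRd
pool_decay <- function(counts, times_local, seg_duration, tau) {
  n_cells <- length(counts)
  total <- sum(counts)
  alive <- matrix(0L, n_cells, length(times_local))
  end <- integer(n_cells)
  if (total > 0) {
    cell <- rep.int(seq_len(n_cells), counts)
    death <- rexp(total, rate = 1 / tau)
    for (j in seq_along(times_local)) {
      alive[, j] <- tabulate(cell[death > times_local[j]], nbins = n_cells)
    }
    end <- tabulate(cell[death > seg_duration], nbins = n_cells)
  }
  list(alive = alive, end = end)
}

#' Analytic recovery shortcut between inductions
#'
#' Replaces explicit simulation of a hormone-free recovery period. Memory
#' status is reassigned per locus as an independent Bernoulli draw with the
#' closed-form converted fraction [memory_fraction()] evaluated at the total
#' time elapsed since the first hormone addition (induction plus recovery);
#' under Nup98 depletion the probability is exactly 0 (reversion on
#' withdrawal). The active state resets to inactive, nascent Pol IIs are
#' cleared, and mature mRNA pools decay with survival probability
#' `exp(-recovery_min / tau)`.
#'
#' @param state a population state as produced internally by
#'   [simulate_population()]: a list with logical vectors `active` and
#'   `memory` (one per locus), integer vector `pool` (mature mRNAs per cell)
#'   and scalar `elapsed_min` (minutes since first hormone addition at the
#'   start of the recovery).
#' @param params a [kinetic_params].
#' @param recovery_min duration of the recovery (min).
#' @param nup98_depleted logical.
#' @param tau mature mRNA lifetime (min).
#' @return The updated state (with `elapsed_min` advanced).
#' @export
apply_recovery_shortcut <- function(state, params, recovery_min,
                                    nup98_depleted = FALSE, tau = 600) {
  stopifnot(inherits(params, "kinetic_params"), recovery_min >= 0)
  elapsed_after <- state$elapsed_min + recovery_min
  p_mem <- if (nup98_depleted) 0 else memory_fraction(params$k_C, elapsed_after)
  n_loci <- length(state$memory)
  state$memory <- runif(n_loci) < p_mem
  state$active <- rep(FALSE, n_loci)
  state$pool <- rbinom(length(state$pool), state$pool,
                       exp(-recovery_min / tau))
  state$elapsed_min <- elapsed_after
  state
}

#' Simulate a single locus trajectory
#'
#' Runs the Monte Carlo engine for one locus across the hormone-on segments
#' of a protocol and records the promoter state and Pol II positions at each
#' sample time. The fixed-step engine updates every `1/v` minutes (the time
#' to transcribe one nucleotide); the event-driven engine draws exponential
#' waiting times and advances Pol IIs deterministically. The two agree on
#' population means within Monte Carlo error.
#'
#' @param spec a [promoter_model_spec].
#' @param params a [kinetic_params].
#' @param gene a [gene_model].
#' @param protocol an [induction_protocol].
#' @param sample_times global sample times (min).
#' @param seed integer RNG seed (optional).
#' @param engine `"event"` or `"fixed"`.
#' @param tau mature mRNA lifetime (min).
#' @return A `locus_trajectory`: list with `sample_times`, `promoter_state`
#'   (character), `polii_positions` (list of numeric vectors, nt),
#'   `nascent_cu`, and the running `completed_mrna_count`.
#' @export
simulate_locus <- function(spec, params, gene, protocol, sample_times,
                           seed = NULL, engine = c("event", "fixed"),
                           tau = 600) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  res <- simulate_population(spec, params, gene, protocol, n_cells = 2,
                             sample_times = sample_times, seed = NULL,
                             tau = tau, uninduced_mean_puncta = 0,
                             engine = engine, return_loci = TRUE,
                             detail = TRUE)
  loci <- res$loci
  one <- loci[loci$locus_id == 1L, , drop = FALSE]
  labels <- if (spec$variant == "memory_switch") {
    c("UD", "ID", "UM", "IM")
  } else {
    c("inactive", "active", "inactive", "active")
  }
  structure(list(
    sample_times = one$time_min,
    promoter_state = labels[one$state + 1L],
    polii_positions = res$positions[["1"]],
    nascent_cu = one$nascent_cu,
    completed_mrna_count = one$completed
  ), class = "locus_trajectory")
}

#' Simulate a cell population
#'
#' Simulates `6 * n_cells` independent loci under the given promoter model
#' and protocol, then randomly combines them into `n_cells/2` cells with 4
#' loci (G1) and `n_cells/2` cells with 8 loci (G2), mirroring a tetraploid
#' population that spends equal time in G1 and G2. Per cell the total
#' nascent activity (C.U.) is the probe-rendered signal summed over its
#' loci; mature mRNA counts start from a Poisson draw around the uninduced
#' mean and evolve by completed transcripts and first-order degradation with
#' lifetime `tau`. Hormone-free recovery segments that contain no sample
#' times are replaced by the analytic shortcut [apply_recovery_shortcut()];
#' segments containing samples are simulated explicitly.
#'
#' @inheritParams simulate_locus
#' @param n_cells even number of cells.
#' @param uninduced_mean_puncta Poisson mean of the starting mature count.
#' @param return_loci also return the per-locus table.
#' @param detail record Pol II positions at each sample (slow; small runs).
#' @return A data.frame (`cell_id`, `condition`, `induction`, `time_min`,
#'   `n_loci`, `nascent_cu`, `mature_count`, `nup98_depleted`), or a list with
#'   elements `cells`, `loci` (and `positions` when `detail = TRUE`) if
#'   `return_loci` is set.
#' @export
simulate_population <- function(spec, params, gene, protocol, n_cells,
                                sample_times, seed = NULL, tau = 600,
                                uninduced_mean_puncta = 2,
                                engine = c("event", "fixed"),
                                return_loci = FALSE, detail = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "promoter_model_spec"),
            inherits(params, "kinetic_params"),
            inherits(gene, "gene_model"),
            inherits(protocol, "induction_protocol"))
  if (n_cells %% 2 != 0 || n_cells < 2) stop("`n_cells` must be even and >= 2")
  sample_times <- sort(as.numeric(sample_times))
  if (any(sample_times < 0) || any(sample_times > protocol$total_min)) {
    stop("sample times must lie within the protocol duration")
  }
  if (!is.null(seed)) set.seed(seed)
  eng <- if (engine == "event") 0L else 1L

  n_loci <- 6L * n_cells
  sizes <- sample(rep(c(4L, 8L), each = n_cells / 2))
  cell_of_locus <- rep.int(seq_len(n_cells), sizes)

  state <- list(active = rep(FALSE, n_loci), memory = rep(FALSE, n_loci),
                pool = rpois(n_cells, uninduced_mean_puncta),
                elapsed_min = 0)
  seen_hormone <- FALSE
  induction_no <- 0L
  completed_base <- integer(n_loci)
  seg <- protocol$segments

  cells_out <- list()
  loci_out <- list()
  positions_out <- list()

  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    local_times <- sample_times[sample_times > s$start_min + 1e-9 &
                                sample_times <= s$end_min + 1e-9] - s$start_min
    if (s$hormone) {
      induction_no <- induction_no + 1L
      if (!seen_hormone) {
        seen_hormone <- TRUE
        state$elapsed_min <- 0
      }
    }
    if (!s$hormone && length(local_times) == 0 && seen_hormone) {
      state <- apply_recovery_shortcut(state, params, s$duration_min,
                                       nup98_depleted = s$nup98_depleted,
                                       tau = tau)
      next
    }
    if (!s$hormone && length(local_times) == 0) {
      state$pool <- rbinom(n_cells, state$pool, exp(-s$duration_min / tau))
      next
    }
    if (!s$hormone && s$nup98_depleted && seen_hormone) {
      state$memory <- rep(FALSE, n_loci)  # reversion on withdrawal
    }
    rr <- resolve_segment_rates(spec, params, s, seen_hormone)
    init_active <- if (s$hormone) state$active else rep(FALSE, n_loci)
    res <- .simulate_segment_cpp(
      n_loci, rr$model, rr$act_rate, rr$conv_rate, rr$polB, rr$polL, rr$polH,
      rr$alpha, params$footprint_nt, params$elongation_nt_per_min,
      gene$transcript_length_nt, gene$probe_positions_nt,
      s$duration_min, local_times, init_active, state$memory, tau, eng,
      isTRUE(detail))
    pd <- pool_decay(state$pool, local_times, s$duration_min, tau)

    if (length(local_times) > 0) {
      nasc_cell <- rowsum(res$nascent, cell_of_locus)
      mat_cell <- rowsum(res$mature_alive, cell_of_locus) + pd$alive
      for (j in seq_along(local_times)) {
        cells_out[[length(cells_out) + 1L]] <- data.frame(
          cell_id = seq_len(n_cells),
          condition = if (s$nup98_depleted) "dsNup98" else "control",
          induction = induction_no,
          time_min = s$start_min + local_times[j],
          n_loci = sizes,
          nascent_cu = nasc_cell[, j],
          mature_count = mat_cell[, j],
          nup98_depleted = s$nup98_depleted
        )
        if (return_loci) {
          loci_out[[length(loci_out) + 1L]] <- data.frame(
            locus_id = seq_len(n_loci),
            cell_id = cell_of_locus,
            induction = induction_no,
            time_min = s$start_min + local_times[j],
            nascent_cu = res$nascent[, j],
            completed = completed_base + res$completed[, j],
            state = res$state[, j]
          )
        }
        if (detail) {
          key <- as.character(s$start_min + local_times[j])
          positions_out[[key]] <- res$positions[[j]]
        }
      }
    }
    state$active <- res$final_active
    state$memory <- res$final_memory
    state$pool <- as.integer(rowsum(as.integer(res$alive_end),
                                    cell_of_locus)[, 1]) + pd$end
    completed_base <- completed_base + res$completed_end
    if (seen_hormone) state$elapsed_min <- state$elapsed_min + s$duration_min
  }

  cells <- do.call(rbind, cells_out)
  rownames(cells) <- NULL
  if (!return_loci && !detail) return(cells)
  out <- list(cells = cells)
  if (return_loci) {
    loci <- do.call(rbind, loci_out)
    rownames(loci) <- NULL
    out$loci <- loci
  }
  if (detail) {
    # reorganize as per-locus list of per-sample position vectors
    out$positions <- lapply(seq_len(n_loci), function(i) {
      lapply(positions_out, function(pp) pp[[i]])
    })
    names(out$positions) <- as.character(seq_len(n_loci))
  }
  out
}
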