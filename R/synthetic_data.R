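#' Synthetic-data scenario
#'
#' Bundles a promoter model, kinetic parameters, induction protocol, gene
#' model and all noise settings used by the synthetic generators, so that
#' every generated dataset carries its ground truth.
#'
#' @param spec a [promoter_model_spec].
#' @param params a [kinetic_params].
#' @param protocol an [induction_protocol].
#' @param gene a [gene_model].
#' @param tau mature mRNA lifetime (min).
#' @param qpcr_noise_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise on qPCR values.
#' @param n_cells cells per simulated population (even).
#' @param uninduced_mean_puncta Poisson mean of the uninduced puncta count.
#' @param cytoplasmic_probability probability that a mature mRNA spot lies
#'   in the cytoplasm.
#' @param spot_sigma log-normal sdlog of single-mRNA spot intensities around
#'   1 C.U.
#' @param spot_nascent_threshold minimum nascent activity (C.U.) for a locus
#'   to appear as a nuclear spot in the spot table.
#' @param seed integer seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(spec = promoter_model_spec("memory_switch"),
                               params = kinetic_params(),
                               protocol = standard_protocol(),
                               gene = default_gene(),
                               tau = 600,
                               qpcr_noise_cv = 0.10,
                               n_cells = 2000,
                               uninduced_mean_puncta = 2,
                               cytoplasmic_probability = 0.87,
                               spot_sigma = 0.25,
                               spot_nascent_threshold = 0.5,
                               seed = 1L) {
  stopifnot(inherits(spec, "promoter_model_spec"),
            inherits(params, "kinetic_params"),
            inherits(protocol, "induction_protocol"),
            inherits(gene, "gene_model"))
  if (qpcr_noise_cv < 0 || spot_sigma < 0) stop("noise parameters must be >= 0")
  if (cytoplasmic_probability < 0 || cytoplasmic_probability > 1) {
    stop("`cytoplasmic_probability` must be in [0, 1]")
  }
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @keywords internal
#' @noRd
induction_windows <- function(protocol) {
  seg <- protocol$segments
  h <- which(seg$hormone)
  data.frame(induction = seq_along(h), start_min = seg$start_min[h],
             duration_min = seg$duration_min[h],
             nup98_depleted = seg$nup98_depleted[h],
             inhibitor = seg$inhibitor[h])
}

#' Generate a synthetic qPCR time series
#'
#' Evaluates the analytic mean accumulation curve of the scenario's model
#' for each induction (carrying converted memory and residual mRNA across
#' the recovery) and multiplies by unit-mean log-normal replicate noise with
#' the scenario's CV. The default design samples every 30 min over a 4-hr
#' induction in triplicate.
#'
#' @param scenario a [synthetic_scenario].
#' @param times sample times within each induction (min from induction
#'   start).
#' @param n_replicates replicates per time point.
#' @param n_loci average loci per cell for the mean curve.
#' @return data.frame (`condition`, `induction`, `time_min`, `replicate`,
#'   `mrna_per_cell`) with the ground truth in `attr(, "truth")`.
#' @export
generate_qpcr_dataset <- function(scenario, times = seq(0, 240, by = 30),
                                  n_replicates = 3, n_loci = 6) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  wins <- induction_windows(scenario$protocol)
  if (any(times < 0) || any(times > max(wins$duration_min))) {
    stop("`times` must lie within each induction window")
  }
  cv <- scenario$qpcr_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  out <- list()
  truth_curves <- list()
  m_carry <- 0
  f_M0 <- 0
  prev_end <- NA_real_
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    if (i > 1) {
      gap <- w$start_min - prev_end
      m_carry <- m_carry * exp(-gap / scenario$tau)
      elapsed <- w$start_min - wins$start_min[1]
      f_M0 <- if (w$nup98_depleted) 0 else
        memory_fraction(scenario$params$k_C, elapsed)
    }
    inhibited <- w$inhibitor %in% c("FP", "TPL")
    mean_curve <- if (inhibited) {
      m_carry * exp(-times / scenario$tau)
    } else {
      mean_model_curve(scenario$spec, scenario$params, scenario$tau,
                       n_loci = n_loci, t_grid = times, m0 = m_carry,
                       f_M0 = f_M0)
    }
    truth_curves[[i]] <- data.frame(induction = w$induction,
                                    time_min = times, mean = mean_curve,
                                    f_M0 = f_M0)
    for (r in seq_len(n_replicates)) {
      noise <- if (cv > 0) rlnorm(length(times), -sdlog^2 / 2, sdlog) else 1
      out[[length(out) + 1L]] <- data.frame(
        condition = if (w$nup98_depleted) "dsNup98" else "control",
        induction = w$induction,
        time_min = times,
        replicate = r,
        mrna_per_cell = mean_curve * noise
      )
    }
    end_curve <- if (inhibited) m_carry * exp(-w$duration_min / scenario$tau)
      else mean_model_curve(scenario$spec, scenario$params, scenario$tau,
                            n_loci = n_loci, t_grid = w$duration_min,
                            m0 = m_carry, f_M0 = f_M0)
    m_carry <- end_curve
    prev_end <- w$start_min + w$duration_min
  }
  series <- do.call(rbind, out)
  rownames(series) <- NULL
  attr(series, "truth") <- list(params = scenario$params, tau = scenario$tau,
                                curves = do.call(rbind, truth_curves))
  series
}

#' Generate a synthetic smFISH population and spot table
#'
#' Runs the stochastic population simulator under the scenario and renders
#' its output as (a) a per-cell activity table (total nascent C.U. and
#' mature count per sample time) and (b) a spot table at `spot_time`: each
#' mature mRNA becomes one spot with log-normal intensity around 1 C.U.,
#' cytoplasmic with the scenario's probability; each locus whose nascent
#' signal reaches the spot threshold becomes a nuclear spot of that
#' intensity.
#'
#' @param scenario a [synthetic_scenario].
#' @param sample_times global sample times (min).
#' @param spot_time the sample time rendered as a spot table (default: the
#'   last).
#' @param engine simulation engine.
#' @return List with `activity`, `spots`, `loci` and `truth` (the scenario).
#' @export
generate_smfish_population <- function(scenario, sample_times,
                                       spot_time = max(sample_times),
                                       engine = "event") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sim <- simulate_population(scenario$spec, scenario$params, scenario$gene,
                             scenario$protocol, scenario$n_cells,
                             sample_times, seed = scenario$seed,
                             tau = scenario$tau,
                             uninduced_mean_puncta =
                               scenario$uninduced_mean_puncta,
                             engine = engine, return_loci = TRUE)
  cells <- sim$cells
  loci <- sim$loci
  at <- cells[abs(cells$time_min - spot_time) < 1e-9, , drop = FALSE]
  lat <- loci[abs(loci$time_min - spot_time) < 1e-9, , drop = FALSE]
  spots <- list()
  # mature mRNA spots
  n_mat <- at$mature_count
  if (sum(n_mat) > 0) {
    cell <- rep.int(at$cell_id, n_mat)
    spots[[1]] <- data.frame(
      cell_id = cell,
      compartment = ifelse(runif(length(cell)) <
                             scenario$cytoplasmic_probability,
                           "cytoplasmic", "nuclear"),
      intensity_cu = rlnorm(length(cell), 0, scenario$spot_sigma),
      is_nascent_truth = FALSE
    )
  }
  act <- lat[lat$nascent_cu >= scenario$spot_nascent_threshold, , drop = FALSE]
  if (nrow(act) > 0) {
    spots[[2]] <- data.frame(
      cell_id = act$cell_id,
      compartment = "nuclear",
      intensity_cu = act$nascent_cu,
      is_nascent_truth = TRUE
    )
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(cell_id = integer(), compartment = character(),
               intensity_cu = numeric(), is_nascent_truth = logical())
  spots <- spots[order(spots$cell_id), , drop = FALSE]
  spots$spot_id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  spots <- spots[, c("cell_id", "spot_id", "compartment", "intensity_cu",
                     "is_nascent_truth")]
  list(activity = cells, spots = spots, loci = loci, truth = scenario)
}

#' Generate a synthetic qPCR standard dilution series
#'
#' Copies at `10^k` for `k = 0..decades` with
#' `Ct = intercept + slope * log10(copies)` plus Gaussian Ct noise.
#'
#' @param true_slope slope (Ct per decade).
#' @param intercept Ct at one copy.
#' @param decades number of orders of magnitude (>= 3), default 6.
#' @param noise_sd_ct Gaussian noise SD on Ct.
#' @param seed optional integer seed.
#' @return data.frame (`copies`, `ct`) with truth in `attr(, "truth")`.
#' @export
generate_standard_dilution <- function(true_slope = -3.566, intercept = 40,
                                       decades = 6, noise_sd_ct = 0,
                                       seed = NULL) {
  if (decades < 3) stop("`decades` must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  copies <- 10^(0:decades)
  ct <- intercept + true_slope * log10(copies) +
    rnorm(length(copies), 0, noise_sd_ct)
  out <- data.frame(copies = copies, ct = ct)
  attr(out, "truth") <- list(slope = true_slope, intercept = intercept)
  out
}
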