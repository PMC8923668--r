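#' Kinetic parameters of the promoter models
#'
#' Bundles every rate constant used by the two-state and memory-switch
#' promoter models. Defaults are the fitted values for the ecdysone-induced
#' E74 response: activation `k_A = 17e-3` per minute, default-to-memory
#' conversion `k_C = 0.8e-3` per minute, low/high Pol II loading rates
#' `k_polL = 0.3` and `k_polH = 4.5` Pol II per minute (the 15-fold memory
#' speed-up), single-rate two-state loading `k_pol = 2.0` Pol II per minute,
#' and a Model-2 attempt-rate acceleration `alpha = 11.7e-3` Pol II per
#' minute squared. Elongation is fixed at 1500 nt/min; the minimum Pol II
#' spacing (footprint) defaults to 150 nt. The basal rate `k_polB` is not
#' constrained by data and defaults to a small value.
#'
#' @param k_A activation rate (1/min).
#' @param k_minus_A inactivation rate (1/min); treated as 0 while hormone is
#'   present (activation is effectively irreversible during exposure).
#' @param k_C default-to-memory conversion rate (1/min).
#' @param k_minus_C memory-to-default reversion rate (1/min); effectively
#'   infinite on hormone withdrawal under Nup98 depletion.
#' @param k_polB basal Pol II loading rate (Pol II/min, uninduced states).
#' @param k_polL low/default loading rate (Pol II/min).
#' @param k_polH high/memory loading rate (Pol II/min).
#' @param k_pol single loading rate for two-state Model 1 (Pol II/min).
#' @param alpha loading-attempt acceleration for Model 2 (Pol II/min^2).
#' @param footprint_nt minimum Pol II spacing (nt), >= 1.
#' @param elongation_nt_per_min elongation speed (nt/min).
#' @param tpl_kc_factor multiplicative scaling of `k_C` while triptolide is
#'   present (1 = no effect; < 1 models partial loss of conversion under
#'   initiation block).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_A = 17e-3,
                           k_minus_A = 0,
                           k_C = 0.8e-3,
                           k_minus_C = 0,
                           k_polB = 0.01,
                           k_polL = 0.3,
                           k_polH = 4.5,
                           k_pol = 2.0,
                           alpha = 11.7e-3,
                           footprint_nt = 150,
                           elongation_nt_per_min = 1500,
                           tpl_kc_factor = 1.0) {
  p <- list(k_A = k_A, k_minus_A = k_minus_A, k_C = k_C,
            k_minus_C = k_minus_C, k_polB = k_polB, k_polL = k_polL,
            k_polH = k_polH, k_pol = k_pol, alpha = alpha,
            footprint_nt = footprint_nt,
            elongation_nt_per_min = elongation_nt_per_min,
            tpl_kc_factor = tpl_kc_factor)
  rates <- p[c("k_A", "k_minus_A", "k_C", "k_minus_C", "k_polB", "k_polL",
               "k_polH", "k_pol", "alpha")]
  bad <- vapply(rates, function(r) !is.numeric(r) || length(r) != 1 ||
                  !is.finite(r) || r < 0, logical(1))
  if (any(bad)) stop("rate constants must be single non-negative numbers: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (footprint_nt < 1) stop("`footprint_nt` must be >= 1")
  if (elongation_nt_per_min <= 0) stop("`elongation_nt_per_min` must be > 0")
  if (tpl_kc_factor < 0 || tpl_kc_factor > 1) {
    stop("`tpl_kc_factor` must be in [0, 1]")
  }
  structure(p, class = "kinetic_params")
}

#' Promoter model variant
#'
#' @param variant one of `"memory_switch"` (four states: Uninduced/Induced
#'   crossed with Default/Memory), `"two_state_model1"` (slow activation,
#'   constant loading rate) or `"two_state_model2"` (immediate activation,
#'   loading-attempt rate increasing linearly in time, capped by the Pol II
#'   footprint).
#' @param immediate_activation logical; for Model 2 the activation rate is
#'   taken as very fast (1000/min) so essentially all loci are active within
#'   a minute of hormone exposure.
#' @return An object of class `promoter_model_spec`.
#' @export
promoter_model_spec <- function(variant = c("memory_switch",
                                            "two_state_model1",
                                            "two_state_model2"),
                                immediate_activation = NULL) {
  variant <- match.arg(variant)
  if (is.null(immediate_activation)) {
    immediate_activation <- identical(variant, "two_state_model2")
  }
  structure(list(variant = variant,
                 immediate_activation = isTRUE(immediate_activation)),
            class = "promoter_model_spec")
}

#' Induction protocol
#'
#' A timeline of hormone exposure segments. Each segment has a duration in
#' minutes, a hormone flag, a Nup98-depletion flag and an optional
#' transcription inhibitor (`"FP"` flavopiridol or `"TPL"` triptolide, both
#' modeled as zeroing all Pol II loading while leaving activation and
#' memory-conversion dynamics untouched).
#'
#' @param segments a data.frame with columns `duration_min` (> 0),
#'   `hormone` (logical), `nup98_depleted` (logical) and `inhibitor`
#'   (character, one of "none", "FP", "TPL").
#' @return An object of class `induction_protocol`.
#' @seealso [standard_protocol()]
#' @export
induction_protocol <- function(segments) {
  req <- c("duration_min", "hormone", "nup98_depleted", "inhibitor")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("protocol segments missing column: ",
                         paste(miss, collapse = ", "))
  if (any(segments$duration_min <= 0)) stop("segment durations must be > 0")
  if (!all(segments$inhibitor %in% c("none", "FP", "TPL"))) {
    stop("inhibitor must be one of 'none', 'FP', 'TPL'")
  }
  segments <- as.data.frame(segments)[, req]
  segments$end_min <- cumsum(segments$duration_min)
  segments$start_min <- segments$end_min - segments$duration_min
  structure(list(segments = segments,
                 total_min = sum(segments$duration_min)),
            class = "induction_protocol")
}

#' Standard two-induction protocol
#'
#' The reference treatment regimen: hormone for 4 hr, washout and recovery
#' for 24 hr, then hormone again for 4 hr.
#'
#' @param induction_min duration of the first hormone exposure (min).
#' @param recovery_min duration of the hormone-free recovery (min).
#' @param second_induction_min duration of the re-induction (min); use
#'   `NULL` for a single-induction protocol.
#' @param nup98_depleted logical, applied to all segments.
#' @param inhibitor_first inhibitor present during the first induction.
#' @return An [induction_protocol].
#' @export
standard_protocol <- function(induction_min = 240, recovery_min = 1440,
                              second_induction_min = 240,
                              nup98_depleted = FALSE,
                              inhibitor_first = "none") {
  seg <- data.frame(
    duration_min = c(induction_min, recovery_min, second_induction_min),
    hormone = c(TRUE, FALSE, TRUE),
    nup98_depleted = nup98_depleted,
    inhibitor = c(inhibitor_first, "none", "none"),
    stringsAsFactors = FALSE
  )
  if (is.null(second_induction_min)) seg <- seg[1:2, ]
  induction_protocol(seg)
}

#' Uninduced (no hormone) protocol
#' @param duration_min total duration in minutes.
#' @param nup98_depleted logical.
#' @return An [induction_protocol].
#' @export
uninduced_protocol <- function(duration_min = 240, nup98_depleted = FALSE) {
  induction_protocol(data.frame(duration_min = duration_min, hormone = FALSE,
                                nup98_depleted = nup98_depleted,
                                inhibitor = "none"))
}

#' Fraction of loci in the active state
#'
#' First-order irreversible activation while hormone is present
#' (`k_-A` negligible): `1 - exp(-k_A * t)`.
#'
#' @param k_A activation rate (1/min), >= 0.
#' @param t minutes since hormone addition, >= 0 (vectorized).
#' @return Fraction in `[0, 1]`.
#' @export
active_fraction <- function(k_A, t) {
  if (any(k_A < 0) || any(t < 0)) stop("`k_A` and `t` must be non-negative")
  1 - exp(-k_A * t)
}

#' Fraction of loci converted to the memory state
#'
#' First-order default-to-memory conversion that starts at the first hormone
#' addition and, in control cells, continues after hormone withdrawal:
#' `1 - exp(-k_C * t)`. Under Nup98 depletion the memory state reverts as
#' soon as hormone is withdrawn (`k_-C >> k_C`), so the converted fraction
#' is 0 in that regime.
#'
#' @param k_C conversion rate (1/min), >= 0.
#' @param t minutes since the first hormone addition, >= 0 (vectorized).
#' @param nup98_depleted logical.
#' @param hormone_present logical; only relevant when `nup98_depleted`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' memory_fraction(0.8e-3, 1680)  # ~0.74 after 4 hr induction + 24 hr recovery
#' @export
memory_fraction <- function(k_C, t, nup98_depleted = FALSE,
                            hormone_present = FALSE) {
  if (any(k_C < 0) || any(t < 0)) stop("`k_C` and `t` must be non-negative")
  if (isTRUE(nup98_depleted) && !isTRUE(hormone_present)) {
    return(rep(0, length.out = max(length(k_C), length(t))))
  }
  1 - exp(-k_C * t)
}

#' Footprint-limited effective Pol II loading rate
#'
#' Mean-field saturation of a loading process in which each successful load
#' blocks further loading until the polymerase has cleared the footprint
#' `s` at elongation speed `v`: successful rate `lambda / (1 + lambda*s/v)`.
#' The rate never exceeds the hard packing cap `v/s` and reduces to `lambda`
#' when `lambda*s/v << 1`.
#'
#' @param attempt_rate attempt rate lambda (Pol II/min), >= 0 (vectorized).
#' @param footprint_nt footprint s (nt), >= 0.
#' @param elongation elongation speed v (nt/min), > 0.
#' @return Effective loading rate (Pol II/min).
#' @export
effective_loading_rate <- function(attempt_rate, footprint_nt, elongation) {
  if (any(attempt_rate < 0) || footprint_nt < 0 || elongation <= 0) {
    stop("rates and footprint must be non-negative; elongation > 0")
  }
  ifelse(is.infinite(attempt_rate), elongation / footprint_nt,
         attempt_rate / (1 + attempt_rate * footprint_nt / elongation))
}

#' Mean per-locus mRNA production rate during a hormone-on segment
#'
#' Analytic population mean of the instantaneous production rate at time `t`
#' after hormone addition. Model 1: `k_pol * active_fraction(k_A, t)`.
#' Model 2: footprint-saturated loading of a linearly increasing attempt rate
#' `alpha * t` with all loci active. Memory switch: activation and conversion
#' are independent per locus, so the mean factorizes as
#' `f_A*(f_M*k_polH + (1-f_M)*k_polL) + (1-f_A)*k_polB`, where the memory
#' fraction `f_M(t) = 1 - (1-f_M0) * exp(-k_C*t)` carries over the fraction
#' `f_M0` converted during earlier protocol segments. Exclusion corrections
#' are ignored for Models 1 and memory switch (their fitted loading rates are
#' well below the packing cap); Model 2 applies the mean-field saturation by
#' construction.
#'
#' @param spec a [promoter_model_spec].
#' @param params a [kinetic_params].
#' @param t minutes since the start of the hormone-on segment (vectorized).
#' @param f_M0 memory fraction at segment start (memory switch only).
#' @return Mean production rate, mRNA/min per locus.
#' @export
mean_production_rate <- function(spec, params, t, f_M0 = 0) {
  stopifnot(inherits(spec, "promoter_model_spec"),
            inherits(params, "kinetic_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  switch(spec$variant,
    two_state_model1 = params$k_pol * active_fraction(params$k_A, t),
    two_state_model2 = effective_loading_rate(params$alpha * t,
                                              params$footprint_nt,
                                              params$elongation_nt_per_min),
    memory_switch = {
      f_A <- active_fraction(params$k_A, t)
      f_M <- 1 - (1 - f_M0) * exp(-params$k_C * t)
      f_A * (f_M * params$k_polH + (1 - f_M) * params$k_polL) +
        (1 - f_A) * params$k_polB
    },
    stop("unknown model variant: ", spec$variant)
  )
}
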