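#' Calibrated Memory Index
#'
#' Quantifies how much of the Nup98-dependent memory response survives a
#' perturbation, from the fitted slopes of the second-induction response:
#' `M_C` in control cells, `M_N` under Nup98 depletion and `M_I` with a
#' transcriptional inhibitor during the first induction. The literal formula
#' is `CMI = F * M_I / R` with `F = 1 - M_N/M_C` (the Nup98-dependent
#' fraction of the response) and `R = M_C - M_N` (the absolute
#' Nup98-dependent slope). This form equals 1 exactly whenever `M_I = M_C`.
#' An alternative normalization `(M_I - M_N) / R`, which is exactly 0 when
#' `M_I = M_N` (the stated depleted anchor) and 1 when `M_I = M_C`, is
#' returned alongside as `cmi_alt`.
#'
#' @param m_c control second-induction slope (mRNA/cell per min).
#' @param m_n Nup98-depleted slope; must differ from `m_c`.
#' @param m_i inhibitor-treated slope.
#' @return List with `F`, `R`, `cmi` and `cmi_alt`.
#' @examples
#' cmi(3, 1, 2)  # F = 2/3, R = 2, CMI = 2/3
#' @export
cmi <- function(m_c, m_n, m_i) {
  if (!all(is.finite(c(m_c, m_n, m_i)))) stop("slopes must be finite")
  if (m_c == 0) stop("`m_c` must be non-zero")
  if (m_c == m_n) stop("zero dynamic range: M_C equals M_N")
  f <- 1 - m_n / m_c
  r <- m_c - m_n
  list(F = f, R = r, cmi = f * m_i / r, cmi_alt = (m_i - m_n) / r)
}

#' Slope of the induction response
#'
#' Ordinary least squares slope of absolute mRNA level against time over one
#' induction window, the `M` entering [cmi()].
#'
#' @param series data.frame with columns `time_min` and `mrna_per_cell`,
#'   restricted to a single induction; at least 3 distinct time points.
#' @return List with `slope` and `se`.
#' @export
fit_induction_slope <- function(series) {
  check_columns(series, c("time_min", "mrna_per_cell"), "bulk series")
  if (length(unique(series$time_min)) < 3) {
    stop("need at least 3 distinct time points to fit a slope")
  }
  fit <- lm(mrna_per_cell ~ time_min, data = series)
  res <- residuals(fit)
  sxx <- sum((series$time_min - mean(series$time_min))^2)
  sigma2 <- sum(res^2) / max(length(res) - 2, 1)
  list(slope = unname(coef(fit)[2]),
       se = sqrt(sigma2 / sxx))
}

#' Classify nuclear spots as nascent transcription sites
#'
#' Applies the intensity rule used on smFISH spot tables: nuclear spots at
#' least `threshold_cu` (3 single-mRNA equivalents by default) are flagged
#' as nascent sites. In nuclei containing fewer than three supra-threshold
#' spots, one or two additional nuclear spots (count uniform on \{1, 2\},
#' spots uniform among the unflagged ones) are flagged at random -- random
#' assignment yields a less biased activity estimate than asserting that no
#' transcription occurs. Cytoplasmic spots are never flagged.
#'
#' @param spots data.frame with columns `cell_id`, `spot_id`, `compartment`
#'   (`"nuclear"`/`"cytoplasmic"`) and `intensity_cu`.
#' @param threshold_cu intensity threshold (C.U.).
#' @param seed optional integer seed for the random assignments.
#' @return The input table with a logical `nascent_flag` column.
#' @export
classify_nascent_sites <- function(spots, threshold_cu = 3, seed = NULL) {
  check_columns(spots, c("cell_id", "spot_id", "compartment", "intensity_cu"),
                "spot table")
  if (!all(spots$compartment %in% c("nuclear", "cytoplasmic"))) {
    stop("`compartment` must be 'nuclear' or 'cytoplasmic'")
  }
  if (any(spots$intensity_cu <= 0)) stop("intensities must be positive")
  if (!is.null(seed)) set.seed(seed)
  spots$nascent_flag <- spots$compartment == "nuclear" &
    spots$intensity_cu >= threshold_cu
  for (cid in unique(spots$cell_id)) {
    nuc <- which(spots$cell_id == cid & spots$compartment == "nuclear")
    if (!length(nuc)) next
    n_supra <- sum(spots$nascent_flag[nuc])
    if (n_supra < 3) {
      candidates <- nuc[!spots$nascent_flag[nuc]]
      if (length(candidates)) {
        k <- min(sample(1:2, 1), length(candidates))
        pick <- if (length(candidates) == 1) candidates else
          sample(candidates, k)
        spots$nascent_flag[pick] <- TRUE
      }
    }
  }
  spots
}

#' Fractions of cells with 0-4+ active transcription sites
#'
#' Tabulates per-cell counts of flagged nascent sites into fractions of
#' cells with 0, 1, 2, 3 and 4-or-more active loci.
#'
#' @param spots a spot table with a logical `nascent_flag` column, or a
#'   numeric vector of per-cell nascent-site counts.
#' @return Named numeric vector (`"0"`, `"1"`, `"2"`, `"3"`, `"4+"`) summing
#'   to 1.
#' @export
active_loci_fractions <- function(spots) {
  counts <- if (is.data.frame(spots)) {
    check_columns(spots, c("cell_id", "nascent_flag"), "spot table")
    tapply(spots$nascent_flag, spots$cell_id, sum)
  } else {
    as.numeric(spots)
  }
  capped <- pmin(counts, 4)
  fr <- tabulate(capped + 1L, nbins = 5L) / length(capped)
  setNames(fr, c("0", "1", "2", "3", "4+"))
}

#' Cytoplasmic fraction of mature mRNA puncta
#'
#' Per cell, the fraction of non-nascent spots whose centroid lies in the
#' cytoplasm; cells with no non-nascent spots are excluded (with a message).
#' The population mean is expected to exceed 0.85 in this system.
#'
#' @param spots a spot table; if a `nascent_flag` column is present, flagged
#'   spots are excluded first.
#' @return List with `per_cell` (named vector), `mean` and `sd`.
#' @export
cytoplasmic_fraction <- function(spots) {
  check_columns(spots, c("cell_id", "compartment"), "spot table")
  if ("nascent_flag" %in% names(spots)) {
    spots <- spots[!spots$nascent_flag, , drop = FALSE]
  }
  if (!nrow(spots)) stop("no non-nascent spots present")
  tot <- table(spots$cell_id)
  cyto <- tapply(spots$compartment == "cytoplasmic", spots$cell_id, sum)
  frac <- cyto / as.numeric(tot)
  dropped <- sum(tot == 0)
  if (dropped > 0) message(dropped, " cells without non-nascent spots excluded")
  list(per_cell = frac, mean = mean(frac), sd = sd(frac))
}
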