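#' Fit a qPCR standard curve (Ct vs log10 copies)
#'
#' Ordinary least squares of threshold cycle against log10 template copies
#' over a dilution series. A slope of -3.322 corresponds to 100%
#' amplification efficiency; the reference E74 DNA standard has slope
#' -3.566 (R^2 = 0.9985).
#'
#' @param copies template copy numbers (> 0), at least 3 points.
#' @param ct threshold cycles, same length.
#' @return An object of class `qpcr_curve`: `slope` (Ct per decade),
#'   `intercept` (Ct at 1 copy), `r_squared`, `efficiency`
#'   (`10^(-1/slope) - 1`).
#' @export
fit_log_linear <- function(copies, ct) {
  if (length(copies) != length(ct)) stop("`copies` and `ct` lengths differ")
  if (length(copies) < 3) stop("need at least 3 dilution points")
  if (any(copies <= 0)) stop("`copies` must be positive")
  x <- log10(copies)
  if (length(unique(x)) < 2) stop("rank-deficient dilution series: ",
                                  "need at least two distinct copy numbers")
  fit <- lm(ct ~ x)
  co <- coef(fit)
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  new_qpcr_curve(unname(co[2]), unname(co[1]), r2)
}

#' Fit a standard curve with a fixed slope
#'
#' Single-parameter fit: the intercept is the mean of
#' `ct - slope * log10(copies)` with the slope held at a reference value
#' (e.g. the -3.566 determined from a DNA standard). R^2 is computed
#' against the constrained line.
#'
#' @param copies template copy numbers (> 0), at least 1 point.
#' @param ct threshold cycles.
#' @param slope fixed slope (Ct per decade).
#' @return A `qpcr_curve`.
#' @export
fit_fixed_slope <- function(copies, ct, slope = -3.566) {
  if (length(copies) != length(ct)) stop("`copies` and `ct` lengths differ")
  if (length(copies) < 1) stop("need at least one point")
  if (any(copies <= 0)) stop("`copies` must be positive")
  x <- log10(copies)
  intercept <- mean(ct - slope * x)
  pred <- intercept + slope * x
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum((ct - pred)^2) / sst else 1
  new_qpcr_curve(slope, intercept, r2)
}

#' @keywords internal
#' @noRd
new_qpcr_curve <- function(slope, intercept, r_squared) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf(
    "<qpcr_curve> slope %.4g, intercept %.4g, R^2 %.4g, efficiency %.3g\n",
    x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Convert threshold cycles to template copies
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param ct threshold cycles (vectorized).
#' @param curve a `qpcr_curve` with negative slope.
#' @return Copy numbers.
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    stop("standard curve slope must be negative")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Convert RNA mass to molecule copies
#'
#' `copies = mass / MW * N_Avogadro`, with the reference RNA standard
#' molecular weight 126,060 g/mol by default.
#'
#' @param mass_g mass in grams (>= 0, vectorized).
#' @param mw_g_per_mol molecular weight (g/mol), > 0.
#' @return Copy numbers.
#' @export
mass_to_copies <- function(mass_g, mw_g_per_mol = 126060) {
  if (any(mass_g < 0)) stop("`mass_g` must be non-negative")
  if (mw_g_per_mol <= 0) stop("`mw_g_per_mol` must be positive")
  mass_g / mw_g_per_mol * 6.02214076e23
}

#' Absolute molecules per cell with extraction-loss correction
#'
#' Divides measured copies by the number of extracted cells and by the
#' fraction of RNA surviving extraction. The reference recovery is 0.44
#' (56% of RNA lost during extraction and purification).
#'
#' @param total_copies measured copies (vectorized).
#' @param n_cells number of cells in the extraction, >= 1.
#' @param recovery_fraction fraction of RNA recovered, in (0, 1].
#' @return Molecules per cell.
#' @export
copies_per_cell <- function(total_copies, n_cells, recovery_fraction = 0.44) {
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (recovery_fraction <= 0 || recovery_fraction > 1) {
    stop("`recovery_fraction` must be in (0, 1]")
  }
  total_copies / (recovery_fraction * n_cells)
}
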