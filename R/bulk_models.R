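#' Mean mRNA accumulation under constant production
#'
#' Closed-form solution of `dm/dt = P - m/tau`:
#' `m(t) = m0*exp(-t/tau) + P*tau*(1 - exp(-t/tau))`.
#'
#' @param P_cell production rate (mRNA/min per cell).
#' @param tau mRNA lifetime (min), > 0.
#' @param m0 initial mRNAs per cell.
#' @param t minutes (vectorized).
#' @return Molecules per cell.
#' @export
mean_constant_production <- function(P_cell, tau, m0, t) {
  if (tau <= 0) stop("`tau` must be > 0")
  m0 * exp(-t / tau) + P_cell * tau * (1 - exp(-t / tau))
}

#' Mean mRNA accumulation under linearly increasing production
#'
#' Closed-form solution of `dm/dt = a*t - m/tau`:
#' `m(t) = m0*exp(-t/tau) + a*tau*(t - tau*(1 - exp(-t/tau)))`.
#'
#' @param a_cell production acceleration (mRNA/min^2 per cell).
#' @inheritParams mean_constant_production
#' @return Molecules per cell.
#' @export
mean_linear_production <- function(a_cell, tau, m0, t) {
  if (tau <= 0) stop("`tau` must be > 0")
  m0 * exp(-t / tau) + a_cell * tau * (t - tau * (1 - exp(-t / tau)))
}

#' @keywords internal
#' @noRd
model1_mean_closed <- function(k_A, k_pol, n_loci, tau, m0, t) {
  P <- n_loci * k_pol
  base <- m0 * exp(-t / tau) + P * tau * (1 - exp(-t / tau))
  d <- 1 / tau - k_A
  corr <- if (abs(d) < 1e-12) {
    t * exp(-t / tau)
  } else {
    (exp(-k_A * t) - exp(-t / tau)) / d
  }
  base - P * corr
}

#' Mean per-cell accumulation curve for a promoter model
#'
#' Numerically integrates `dm/dt = n_loci * r(t) - m/tau` where `r(t)` is the
#' analytic mean per-locus production rate [mean_production_rate()] of the
#' chosen model during a hormone-on window starting at `t = 0`. The default
#' locus count is 6 (tetraploid cells, half G1 with 4 loci and half G2 with
#' 8). Closed forms exist for Model 1 and for constant/linear production and
#' agree with the integration.
#'
#' @param spec a [promoter_model_spec].
#' @param params a [kinetic_params].
#' @param tau mRNA lifetime (min), > 0.
#' @param n_loci average gene copies per cell (default 6).
#' @param t_grid times (min) at which to report the curve.
#' @param m0 initial molecules per cell.
#' @param f_M0 memory fraction at induction start (memory switch only).
#' @return Numeric vector, molecules per cell at `t_grid`.
#' @export
mean_model_curve <- function(spec, params, tau, n_loci = 6, t_grid,
                             m0 = 0, f_M0 = 0) {
  if (tau <= 0) stop("`tau` must be > 0")
  t_grid <- as.numeric(t_grid)
  times <- sort(unique(c(0, t_grid)))
  deriv <- function(t, y, parms) {
    list(n_loci * mean_production_rate(spec, params, t, f_M0 = f_M0) -
           y[1] / tau)
  }
  sol <- deSolve::ode(y = c(m = unname(m0)), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed for the mean ",
                                       "accumulation curve")
  unname(sol[match(t_grid, times), "m"])
}

#' Fit an exponential decay to post-shutoff mRNA levels
#'
#' Nonlinear least squares of `m(t) = m0 * exp(-t/tau)` to a time series
#' collected after transcription shutoff, returning the mRNA lifetime with
#' asymptotic 95% confidence intervals from the Jacobian covariance.
#' Non-decaying input is flagged and the lifetime is reported at the search
#' bound rather than failing.
#'
#' @param series data.frame with columns `time_min` and `mrna_per_cell`
#'   (replicates as extra rows); at least 4 distinct time points.
#' @param tau_upper upper bound for the lifetime (min).
#' @return An object of class `degradation_fit`: `lifetime_tau`, `m0`,
#'   `ci95` (2 x 2 matrix), `flag` (`"ok"` or `"non_decaying"`), `fit`.
#' @export
fit_degradation <- function(series, tau_upper = 1e6) {
  check_columns(series, c("time_min", "mrna_per_cell"), "bulk series")
  if (length(unique(series$time_min)) < 4) {
    stop("need at least 4 distinct time points after shutoff")
  }
  t <- series$time_min - min(series$time_min)
  m <- series$mrna_per_cell
  sl <- coef(lm(log(pmax(m, 1e-12)) ~ t))[2]
  if (sl >= 0) {
    warning("series does not decay; lifetime reported at the upper bound")
    est <- c(m0 = mean(m), tau = tau_upper)
    ci <- matrix(NA_real_, 2, 2, dimnames = list(c("m0", "tau"),
                                                 c("lower", "upper")))
    return(structure(list(lifetime_tau = tau_upper, m0 = mean(m), ci95 = ci,
                          flag = "non_decaying", fit = NULL),
                     class = "degradation_fit"))
  }
  start <- list(m0 = max(m), tau = min(-1 / sl, tau_upper))
  fit <- minpack.lm::nlsLM(m ~ m0 * exp(-t / tau), start = start,
                           lower = c(1e-9, 1e-3), upper = c(Inf, tau_upper),
                           data = data.frame(t = t, m = m))
  # qPCR replicate noise is multiplicative, so refit with 1/fitted^2 weights
  # (relative least squares); this keeps the Jacobian covariance calibrated
  w <- 1 / pmax(predict(fit), 1e-12)^2
  fit <- minpack.lm::nlsLM(m ~ m0 * exp(-t / tau), start = as.list(coef(fit)),
                           lower = c(1e-9, 1e-3), upper = c(Inf, tau_upper),
                           weights = w, data = data.frame(t = t, m = m))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(lifetime_tau = unname(est["tau"]), m0 = unname(est["m0"]),
                 ci95 = ci, flag = "ok", fit = fit),
            class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf("<degradation_fit> tau = %.4g min [%s], m0 = %.4g\n",
              x$lifetime_tau, x$flag, x$m0))
  invisible(x)
}

#' Fit a mean accumulation model to a qPCR time series
#'
#' Two-stage fitting: the mRNA lifetime `tau` is fixed externally (from
#' [fit_degradation()]) and the production parameters of the chosen model
#' are estimated by nonlinear least squares on absolute molecules/cell.
#' Available models: `"constant"` (free `P_cell`), `"linear"` (free
#' `a_cell`), `"model1"` (free `k_A`, `k_pol`), `"model2"` (free `alpha`,
#' optionally `footprint_nt`; activation is immediate) and
#' `"memory_switch"` (free subset of the four-state rates via `free`).
#' 95% confidence intervals come from the asymptotic Jacobian covariance.
#'
#' @param model one of `"constant"`, `"linear"`, `"model1"`, `"model2"`,
#'   `"memory_switch"`.
#' @param series data.frame with columns `time_min`, `mrna_per_cell`.
#' @param tau fixed mRNA lifetime (min).
#' @param n_loci average loci per cell (default 6).
#' @param m0 initial molecules per cell (fixed).
#' @param base_params a [kinetic_params] supplying fixed rates for
#'   `"model2"`/`"memory_switch"`.
#' @param free free parameter names for `"memory_switch"` (default
#'   `c("k_A", "k_polL")`) or `"model2"` (`"alpha"` or
#'   `c("alpha", "footprint_nt")`).
#' @param f_M0 starting memory fraction (memory switch).
#' @param start optional named list of starting values.
#' @return An object of class `bulk_fit`: `model`, `params` (named numeric),
#'   `ci95`, `rss`, `n_loci`, `tau`, `m0`, `curve` (function of t), `fit`.
#' @export
fit_accumulation <- function(model = c("constant", "linear", "model1",
                                       "model2", "memory_switch"),
                             series, tau, n_loci = 6, m0 = 0,
                             base_params = kinetic_params(),
                             free = NULL, f_M0 = 0, start = NULL) {
  model <- match.arg(model)
  check_columns(series, c("time_min", "mrna_per_cell"), "bulk series")
  if (tau <= 0) stop("`tau` must be > 0 (fit it with fit_degradation first)")
  t <- series$time_min
  m <- series$mrna_per_cell
  mk_curve <- NULL

  if (model == "constant") {
    free <- "P_cell"
    mk_curve <- function(th) function(tt)
      mean_constant_production(th[["P_cell"]], tau, m0, tt)
    if (is.null(start)) start <- list(P_cell = max(max(m) / tau, 1e-6))
    lower <- 0; upper <- Inf
  } else if (model == "linear") {
    free <- "a_cell"
    mk_curve <- function(th) function(tt)
      mean_linear_production(th[["a_cell"]], tau, m0, tt)
    if (is.null(start)) start <- list(a_cell = max(2 * max(m) /
                                                    max(t)^2 / tau, 1e-9))
    lower <- 0; upper <- Inf
  } else if (model == "model1") {
    free <- c("k_A", "k_pol")
    mk_curve <- function(th) function(tt)
      model1_mean_closed(th[["k_A"]], th[["k_pol"]], n_loci, tau, m0, tt)
    if (is.null(start)) start <- list(k_A = 5e-3, k_pol = 1)
    lower <- c(1e-8, 1e-7); upper <- c(1, 10)
  } else if (model == "model2") {
    if (is.null(free)) free <- "alpha"
    spec2 <- promoter_model_spec("two_state_model2")
    mk_curve <- function(th) {
      p <- base_params
      p[names(th)] <- as.list(unname(th))
      function(tt) mean_model_curve(spec2, p, tau, n_loci, tt, m0 = m0)
    }
    if (is.null(start)) {
      start <- list(alpha = 10e-3, footprint_nt = base_params$footprint_nt)
      start <- start[free]
    }
    lower <- c(alpha = 1e-7, footprint_nt = 1)[free]
    upper <- c(alpha = 10, footprint_nt = 2000)[free]
  } else { # memory_switch
    if (is.null(free)) free <- c("k_A", "k_polL")
    spec4 <- promoter_model_spec("memory_switch")
    mk_curve <- function(th) {
      p <- base_params
      p[names(th)] <- as.list(unname(th))
      function(tt) mean_model_curve(spec4, p, tau, n_loci, tt, m0 = m0,
                                    f_M0 = f_M0)
    }
    if (is.null(start)) start <- as.list(unlist(base_params[free]))
    bnd <- c(k_A = 1e-8, k_C = 1e-8, k_polB = 1e-7, k_polL = 1e-7,
             k_polH = 1e-7)
    lower <- bnd[free]
    upper <- c(k_A = 1, k_C = 1, k_polB = 10, k_polL = 10, k_polH = 10)[free]
  }

  resid_fun <- function(par) {
    th <- setNames(par, free)
    m - mk_curve(th)(t)
  }
  fit <- minpack.lm::nls.lm(par = unlist(start[free]), fn = resid_fun,
                            lower = unname(lower), upper = unname(upper),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  if (fit$info == 0 || fit$info > 4) {
    stop("nonlinear fit did not converge (info = ", fit$info,
         "); best-so-far: ",
         paste(sprintf("%s=%.4g", free, fit$par), collapse = ", "),
         "; RSS = ", signif(fit$deviance, 4))
  }
  est <- setNames(fit$par, free)
  covm <- tryCatch(solve(fit$hessian) * fit$deviance /
                     max(length(m) - length(est), 1),
                   error = function(e) matrix(NA_real_, length(est),
                                              length(est)))
  # nls.lm's hessian is the Gauss-Newton J'J; sigma^2 (J'J)^-1 is the
  # asymptotic covariance with sigma^2 = RSS / (n - p)
  se <- sqrt(pmax(diag(covm), 0))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(model = model, params = est, ci95 = ci,
                 rss = fit$deviance, n_loci = n_loci, tau = tau, m0 = m0,
                 f_M0 = f_M0, curve = mk_curve(est), fit = fit),
            class = "bulk_fit")
}

#' @export
print.bulk_fit <- function(x, ...) {
  cat(sprintf("<bulk_fit> model %s, RSS = %.4g\n", x$model, x$rss))
  print(signif(cbind(estimate = x$params, x$ci95), 4))
  invisible(x)
}

#' Accumulation rate and per-locus transcription rate of a fit
#'
#' Differentiates a fitted accumulation curve: the accumulation rate is
#' `dm/dt = production(t) - m(t)/tau` and the per-locus transcription rate is
#' the production term divided by the locus count.
#'
#' @param fit a [fit_accumulation()] result.
#' @param t_grid times (min).
#' @return data.frame with `time_min`, `accumulation_rate` (mRNA/min per
#'   cell) and `transcription_rate_per_locus` (mRNA/min per locus).
#' @export
accumulation_rate <- function(fit, t_grid) {
  stopifnot(inherits(fit, "bulk_fit"))
  m <- fit$curve(t_grid)
  production <- switch(fit$model,
    constant = rep(fit$params[["P_cell"]], length(t_grid)),
    linear = fit$params[["a_cell"]] * t_grid,
    model1 = fit$n_loci * fit$params[["k_pol"]] *
      active_fraction(fit$params[["k_A"]], t_grid),
    model2 = {
      p <- kinetic_params()
      p[names(fit$params)] <- as.list(unname(fit$params))
      fit$n_loci * mean_production_rate(
        promoter_model_spec("two_state_model2"), p, t_grid)
    },
    memory_switch = {
      p <- kinetic_params()
      p[names(fit$params)] <- as.list(unname(fit$params))
      fit$n_loci * mean_production_rate(
        promoter_model_spec("memory_switch"), p, t_grid, f_M0 = fit$f_M0)
    })
  data.frame(time_min = t_grid,
             accumulation_rate = production - m / fit$tau,
             transcription_rate_per_locus = production / fit$n_loci)
}
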