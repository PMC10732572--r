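# Guanine-nucleotide exchange progress curves (tryptophan fluorescence on
# GTPgammaS binding) and the one-site Ca2+ activation hyperbola
#   v = v0 + vmax * [Ca] / (Ka + [Ca]).

#' Progress curve container
#'
#' @param time Seconds, increasing; at least 30 points for fitting.
#' @param fluorescence Arbitrary units.
#' @param condition Label (e.g. "intrinsic", "Ric-8A", "NCS-1/Ric-8A").
#' @param ca_conc Free CaCl2 concentration (molar).
#' @return Object of class `progress_curve`.
#' @export
progress_curve <- function(time, fluorescence, condition = "unknown",
                           ca_conc = 0) {
  if (length(time) != length(fluorescence))
    stop("`time` and `fluorescence` must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("`time` must be strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time),
                 fluorescence = as.numeric(fluorescence),
                 condition = condition, ca_conc = ca_conc),
            class = "progress_curve")
}

#' Fit an exponential rate model to a progress curve
#'
#' Least squares on `F(t) = f0 + sum_i a_i (1 - exp(-k_i t))` with one or
#' two exponential phases.  For order 2 the rates are sorted so `k1 >= k2`;
#' `slow_rate` is always the slowest fitted rate (the phase conventionally
#' assigned to catalysed exchange when an intermediary-complex burst is
#' present).
#'
#' @param curve A [progress_curve()].
#' @param order 1 or 2 exponential phases.
#' @return Object of class `exp_fit`: `model_order`, `f0`, `amplitudes`,
#'   `rates` (1/s, descending), `slow_rate`, `rss`, `aicc`, `converged`.
#' @export
fit_exponential <- function(curve, order = 1L) {
  stopifnot(inherits(curve, "progress_curve"))
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2", call. = FALSE)
  tt <- curve$time
  yy <- curve$fluorescence
  if (length(tt) < 30L)
    stop("need at least 30 points in a progress curve", call. = FALSE)

  amp0 <- max(yy) - yy[1L]
  f00 <- yy[1L]
  # initial rate from the log-linearised approach to plateau
  k0 <- {
    plateau <- stats::median(utils::tail(yy, 5L))
    resid0 <- plateau - yy
    pos <- resid0 > max(abs(resid0)) * 1e-3
    if (sum(pos) > 3) {
      sl <- stats::coef(stats::lm(log(resid0[pos]) ~ tt[pos]))[[2L]]
      max(-sl, 1e-6)
    } else 1 / max(tt)
  }

  if (max(abs(yy - mean(yy))) < 1e-12) amp0 <- 0

  fit <- NULL
  if (order == 1L) {
    fit <- tryCatch(minpack.lm::nlsLM(
      yy ~ f0 + a1 * (1 - exp(-k1 * tt)),
      start = list(f0 = f00, a1 = max(amp0, 1e-9), k1 = k0),
      lower = c(-Inf, -Inf, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit))
      return(structure(list(model_order = 1L, f0 = f00, amplitudes = amp0,
                            rates = k0, slow_rate = k0, rss = NA_real_,
                            aicc = Inf, converged = FALSE), class = "exp_fit"))
    cf <- stats::coef(fit)
    rates <- cf[["k1"]]; amps <- cf[["a1"]]; f0 <- cf[["f0"]]
  } else {
    fit <- tryCatch(minpack.lm::nlsLM(
      yy ~ f0 + a1 * (1 - exp(-k1 * tt)) + a2 * (1 - exp(-k2 * tt)),
      start = list(f0 = f00, a1 = max(amp0, 1e-9) / 2, k1 = k0 * 5,
                   a2 = max(amp0, 1e-9) / 2, k2 = k0 / 2),
      lower = c(-Inf, -Inf, 1e-12, -Inf, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit))
      return(structure(list(model_order = 2L, f0 = f00,
                            amplitudes = c(amp0 / 2, amp0 / 2),
                            rates = c(k0 * 5, k0 / 2), slow_rate = k0 / 2,
                            rss = NA_real_, aicc = Inf, converged = FALSE),
                       class = "exp_fit"))
    cf <- stats::coef(fit)
    ord <- order(c(cf[["k1"]], cf[["k2"]]), decreasing = TRUE)
    rates <- c(cf[["k1"]], cf[["k2"]])[ord]
    amps <- c(cf[["a1"]], cf[["a2"]])[ord]
    f0 <- cf[["f0"]]
  }
  rss <- sum(stats::resid(fit)^2)
  n <- length(yy)
  k_par <- 1 + 2 * order
  structure(
    list(model_order = order, f0 = f0, amplitudes = amps, rates = rates,
         slow_rate = rates[length(rates)], rss = rss,
         aicc = .aicc(rss, n, k_par), converged = TRUE),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (order %d): rates = %s /s, slow = %.4g /s, rss = %.3g\n",
              x$model_order, paste(signif(x$rates, 4), collapse = ", "),
              x$slow_rate, x$rss))
  invisible(x)
}

#' Choose between single- and double-exponential progress-curve models
#'
#' Fits both orders and compares corrected AIC; ties (within 1e-6) go to
#' the single exponential.
#'
#' @param curve A [progress_curve()].
#' @return List with `order`, `aicc` (named length-2), and both fits.
#' @export
choose_exponential_model <- function(curve) {
  f1 <- fit_exponential(curve, 1L)
  f2 <- fit_exponential(curve, 2L)
  order <- if (is.finite(f2$aicc) && f2$aicc < f1$aicc - 1e-6) 2L else 1L
  list(order = order, aicc = c(order1 = f1$aicc, order2 = f2$aicc),
       fit1 = f1, fit2 = f2)
}

#' Subtract intrinsic exchange rates, matched on Ca2+ concentration
#'
#' Corrects condition rates by the intrinsic (uncatalysed) rate measured at
#' the same CaCl2 concentration.  Matching is exact — a missing intrinsic
#' entry is an error, never interpolated.
#'
#' @param rates Data frame with columns `condition`, `ca_conc`, `rate`.
#' @param intrinsic Data frame with columns `ca_conc`, `rate`.
#' @return `rates` with an added `corrected` column (rate - intrinsic).
#' @export
subtract_intrinsic <- function(rates, intrinsic) {
  stopifnot(all(c("condition", "ca_conc", "rate") %in% names(rates)),
            all(c("ca_conc", "rate") %in% names(intrinsic)))
  idx <- match(rates$ca_conc, intrinsic$ca_conc)
  if (anyNA(idx)) {
    miss <- unique(rates$ca_conc[is.na(idx)])
    stop("no intrinsic rate measured at Ca2+ = ",
         paste(signif(miss, 4), collapse = ", "),
         " M; refusing to interpolate", call. = FALSE)
  }
  rates$corrected <- rates$rate - intrinsic$rate[idx]
  rates
}

#' Evaluate the one-site activation hyperbola
#'
#' @param ca Ca2+ concentration(s) (molar).
#' @param v0 Basal rate (1/s).
#' @param v_max Maximal rate increment (1/s).
#' @param ka Apparent activation constant (molar).
#' @return Rate(s) `v0 + v_max * ca / (ka + ca)`.
#' @export
activation_hyperbola <- function(ca, v0, v_max, ka) {
  v0 + v_max * ca / (ka + ca)
}

#' Fit the one-site-total-binding velocity model to rate-vs-Ca2+ data
#'
#' Least squares on `v = v0 + vmax [Ca]/(Ka + [Ca])`.  At zero Ca2+ the
#' model returns `v0`; at `[Ca] = Ka` it returns `v0 + vmax/2`.  Data with
#' no concentration dependence yield `unidentifiable = TRUE`.
#'
#' @param ca_conc Ca2+ concentrations (molar); needs >= 4 distinct values
#'   including 0.
#' @param rate Exchange rates (1/s), same length.
#' @return Object of class `activation_fit`: `v0`, `v_max`, `ka` (molar),
#'   standard errors, `rss`, `unidentifiable`.
#' @export
fit_activation <- function(ca_conc, rate) {
  ca_conc <- as.numeric(ca_conc); rate <- as.numeric(rate)
  if (length(ca_conc) != length(rate))
    stop("`ca_conc` and `rate` must have equal length", call. = FALSE)
  if (length(unique(ca_conc)) < 4L)
    stop("need >= 4 distinct Ca2+ concentrations", call. = FALSE)
  if (!any(ca_conc == 0))
    stop("the concentration series must include 0 (to anchor v0)",
         call. = FALSE)

  v_span <- max(rate) - min(rate)
  if (v_span < 1e-15) {
    return(structure(
      list(v0 = mean(rate), v_max = 0, ka = NA_real_,
           se_v0 = NA_real_, se_vmax = NA_real_, se_ka = NA_real_,
           rss = sum((rate - mean(rate))^2), unidentifiable = TRUE),
      class = "activation_fit"))
  }

  pos <- ca_conc > 0
  ka0 <- stats::median(ca_conc[pos])
  fit <- minpack.lm::nlsLM(
    rate ~ v0 + vmax * ca_conc / (ka + ca_conc),
    start = list(v0 = rate[ca_conc == 0][1L], vmax = v_span, ka = ka0),
    lower = c(-Inf, -Inf, 1e-15),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v0 = NA, vmax = NA, ka = NA))
  unident <- cf[["ka"]] > 50 * max(ca_conc) || abs(cf[["vmax"]]) < 1e-12
  structure(
    list(v0 = cf[["v0"]], v_max = cf[["vmax"]], ka = cf[["ka"]],
         se_v0 = unname(se["v0"]), se_vmax = unname(se["vmax"]),
         se_ka = unname(se["ka"]),
         rss = sum(stats::resid(fit)^2), unidentifiable = unident),
    class = "activation_fit"
  )
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("Activation fit: v0 = %.4g /s, vmax = %.4g /s, Ka = %.4g M\n",
              x$v0, x$v_max, x$ka))
  if (isTRUE(x$unidentifiable)) cat("  warning: Ka unidentifiable\n")
  invisible(x)
}
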