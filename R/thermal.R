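# Nano-DSF melt curves: two-state van 't Hoff model of the 350/330 nm
# intrinsic-fluorescence ratio, and first-derivative inflection-temperature
# (Ti) detection.

#' Two-state melt curve of the 350/330 fluorescence ratio
#'
#' `ratio(T) = B_F(T) + (B_U(T) - B_F(T)) * thetaU(T)` with
#' `thetaU = 1 / (1 + exp[(dHvH/R)(1/T - 1/Tm)])` (T in kelvin) and linear
#' folded/unfolded baselines.  The inflection of a flat-baseline curve sits
#' exactly at Tm.
#'
#' @param tm Midpoint temperature (degC).
#' @param dh_vh Van 't Hoff enthalpy of unfolding (kcal/mol, > 0).
#' @param baseline_folded,baseline_unfolded Length-2 numeric
#'   `c(intercept, slope_per_degC)` evaluated on the Celsius axis.
#' @param t_grid Temperatures (degC), default `seq(35, 95, by = 0.1)`.
#' @param sample Label for the curve.
#' @return Object of class `melt_curve`: `temperature` (degC), `ratio`,
#'   `sample`.
#' @export
two_state_ratio_curve <- function(tm, dh_vh,
                                  baseline_folded = c(0.8, 0),
                                  baseline_unfolded = c(1.0, 0),
                                  t_grid = seq(35, 95, by = 0.1),
                                  sample = "synthetic") {
  if (dh_vh <= 0) stop("`dh_vh` must be positive", call. = FALSE)
  tk <- t_grid + 273.15
  tmk <- tm + 273.15
  theta_u <- 1 / (1 + exp((dh_vh / (R_CAL / 1000)) * (1 / tk - 1 / tmk)))
  bf <- baseline_folded[1L] + baseline_folded[2L] * t_grid
  bu <- baseline_unfolded[1L] + baseline_unfolded[2L] * t_grid
  melt_curve(t_grid, bf + (bu - bf) * theta_u, sample = sample)
}

#' Melt-curve container
#'
#' @param temperature Temperatures (degC), increasing.
#' @param ratio 350/330 nm fluorescence ratio, positive.
#' @param sample Label.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, ratio, sample = "sample") {
  if (length(temperature) != length(ratio))
    stop("`temperature` and `ratio` must have equal length", call. = FALSE)
  if (is.unsorted(temperature, strictly = TRUE))
    stop("`temperature` must be strictly increasing", call. = FALSE)
  structure(list(temperature = as.numeric(temperature),
                 ratio = as.numeric(ratio), sample = sample),
            class = "melt_curve")
}

# prominence of peak i in signal y: height above the higher of the two
# minima separating it from a taller peak (or the record edge)
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- 1L
    for (j in seq(p - 1L, 1L)) {
      if (p == 1L) break
      if (y[j] > h) { left <- j; break }
      left <- j
    }
    lmin <- if (left < p) min(y[left:p]) else h
    right <- length(y)
    for (j in seq(p + 1L, length(y))) {
      if (p == length(y)) break
      if (y[j] > h) { right <- j; break }
      right <- j
    }
    rmin <- if (right > p) min(y[p:right]) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect inflection temperatures from a melt curve
#'
#' Smooths the ratio with a local-quadratic (Savitzky-Golay) filter,
#' differentiates, and reports every local maximum of |d ratio / dT| whose
#' prominence exceeds `min_prominence` times the derivative range — the
#' "peak in the first-derivative view" readout of nano-DSF instruments.
#' Supports multiple transitions (e.g. a two-protein complex melt).
#'
#' @param curve A [melt_curve()].
#' @param smooth_window Smoothing window width in degC (default 1.5);
#'   rounded to an odd number of grid points.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   derivative range (default 0.05).
#' @return Object of class `ti_result`: `ti` (degC, ascending; length 0 if
#'   nothing detected), `prominence`, `smooth_window_pts`, `derivative`
#'   (for plotting).
#' @export
detect_ti <- function(curve, smooth_window = 1.5, min_prominence = 0.05) {
  stopifnot(inherits(curve, "melt_curve"))
  tt <- curve$temperature
  yy <- curve$ratio
  if (length(tt) < 50L)
    stop("need >= 50 points for derivative peak detection", call. = FALSE)
  dt <- stats::median(diff(tt))
  n_win <- max(5L, round(smooth_window / dt))
  if (n_win %% 2L == 0L) n_win <- n_win + 1L
  n_win <- min(n_win, length(tt) - (1L - length(tt) %% 2L))

  smoothed <- signal::sgolayfilt(yy, p = 2, n = n_win)
  deriv <- c(NA_real_, diff(smoothed) / diff(tt))
  deriv[1L] <- deriv[2L]
  mag <- abs(deriv)

  # a derivative that is essentially constant (pure baseline) has no
  # transition, whatever its absolute level
  if ((max(mag) - min(mag)) < 0.2 * max(max(mag), .Machine$double.eps)) {
    return(structure(
      list(ti = numeric(0), prominence = numeric(0),
           smooth_window_pts = n_win,
           derivative = data.frame(temperature = tt, dratio_dT = deriv)),
      class = "ti_result"))
  }

  # interior local maxima of the derivative magnitude
  k <- 2:(length(mag) - 1L)
  is_peak <- mag[k] > mag[k - 1L] & mag[k] >= mag[k + 1L]
  peaks <- k[is_peak]
  if (length(peaks)) {
    prom <- .peak_prominence(mag, peaks)
    keep <- prom >= min_prominence * (max(mag) - min(mag))
    peaks <- peaks[keep]
    prom <- prom[keep]
  } else prom <- numeric(0)

  ord <- order(tt[peaks])
  structure(
    list(ti = tt[peaks][ord], prominence = prom[ord],
         smooth_window_pts = n_win,
         derivative = data.frame(temperature = tt, dratio_dT = deriv)),
    class = "ti_result"
  )
}

#' @export
print.ti_result <- function(x, ...) {
  if (length(x$ti) == 0L) {
    cat("No thermal transition detected above the prominence threshold\n")
  } else {
    cat(sprintf("Detected Ti: %s degC\n",
                paste(sprintf("%.1f", x$ti), collapse = ", ")))
  }
  invisible(x)
}
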