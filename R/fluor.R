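# 1:1 saturation analysis of intrinsic-fluorescence cation titrations.
#
# Signals are normalised intensity changes |I - I0|/I0.  Ligand (cation) is
# in >= 1000-fold excess over protein, so free ~ total ligand; the fitted
# model is y = y_max * L / (Kd + L).

#' Titration curve container
#'
#' @param ligand_conc Cation concentrations (molar), non-negative, sorted.
#' @param y Normalised signal, conventionally `(I0 - I)/I0`; the magnitude
#'   is fitted and the sign of the raw change recorded as `sign`.
#' @param replicate Optional replicate identifier.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(ligand_conc, y, replicate = 1L) {
  ligand_conc <- as.numeric(ligand_conc)
  y <- as.numeric(y)
  if (length(ligand_conc) != length(y))
    stop("`ligand_conc` and `y` must have equal length", call. = FALSE)
  if (any(ligand_conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (is.unsorted(ligand_conc))
    stop("`ligand_conc` must be sorted ascending", call. = FALSE)
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  sgn <- sign(sum(y))
  structure(
    list(ligand_conc = ligand_conc, y = abs(y), sign = sgn,
         replicate = replicate),
    class = "titration_curve"
  )
}

#' Fit a 1:1 saturation model to a titration curve
#'
#' Least squares on `y = y_max * L / (kd + L)` (free ~ total ligand; valid
#' at the >= 1000-fold ligand excess of these assays).  When the data carry
#' no curvature (flat or linear) the fit is returned with
#' `unidentifiable = TRUE` rather than failing.
#'
#' @param curve A [titration_curve()].
#' @return An object of class `saturation_fit`: `kd_app` (molar), `y_max`,
#'   standard errors, `rss`, `unidentifiable`.
#' @export
fit_saturation_1to1 <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  L <- curve$ligand_conc
  y <- curve$y
  if (length(L) < 5L)
    warning("fewer than 5 points: identifiability of Kd is doubtful")

  y_span <- max(y) - min(y)
  if (max(abs(y)) < 1e-12 || y_span < 1e-12) {
    return(structure(
      list(kd_app = NA_real_, y_max = mean(y), se_kd = NA_real_,
           se_ymax = NA_real_, rss = sum((y - mean(y))^2),
           unidentifiable = TRUE),
      class = "saturation_fit"))
  }

  # half-saturation guess: concentration where y first crosses half its max
  half <- max(y) / 2
  kd0 <- L[which(y >= half)[1L]]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(L[L > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ ymax * L / (kd + L),
                      start = list(ymax = max(y), kd = kd0),
                      lower = c(0, .Machine$double.xmin),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(
      list(kd_app = NA_real_, y_max = max(y), se_kd = NA_real_,
           se_ymax = NA_real_, rss = NA_real_, unidentifiable = TRUE),
      class = "saturation_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(ymax = NA_real_, kd = NA_real_))
  # an apparent Kd far beyond the titrated range means no observed curvature
  unident <- cf[["kd"]] > 50 * max(L)
  structure(
    list(kd_app = cf[["kd"]], y_max = cf[["ymax"]],
         se_kd = unname(se["kd"]), se_ymax = unname(se["ymax"]),
         rss = sum(stats::resid(fit)^2), unidentifiable = unident),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("1:1 saturation fit: Kd_app = %.4g M (SE %.2g), ymax = %.3g, rss = %.3g\n",
              x$kd_app, x$se_kd, x$y_max, x$rss))
  if (isTRUE(x$unidentifiable)) cat("  warning: Kd unidentifiable (no curvature)\n")
  invisible(x)
}

#' Ordinary least-squares line through a titration curve
#'
#' The non-saturating alternative model (e.g. weak, linear K+ response).
#'
#' @param curve A [titration_curve()].
#' @return List with `slope`, `intercept`, `rss`.
#' @export
fit_linear_titration <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (length(curve$ligand_conc) < 2L)
    stop("need at least 2 points for a line", call. = FALSE)
  fit <- stats::lm(y ~ L, data = list(y = curve$y, L = curve$ligand_conc))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rss = sum(stats::resid(fit)^2))
}

.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  kk <- k + 1
  n * log(max(rss, 1e-300) / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
}

#' Select between saturating and linear titration behaviour
#'
#' Fits both the 1:1 saturation hyperbola and a straight line and compares
#' them by corrected AIC; ties (within 1e-8) and unidentifiable saturation
#' fits go to the linear model by parsimony.
#'
#' @param curve A [titration_curve()].
#' @return List with `model` ("saturating" or "linear"), `aicc_saturating`,
#'   `aicc_linear`, and both fit objects.
#' @export
select_binding_model <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  sat <- fit_saturation_1to1(curve)
  lin <- fit_linear_titration(curve)
  n <- length(curve$y)
  a_sat <- if (is.finite(sat$rss) && !isTRUE(sat$unidentifiable))
    .aicc(sat$rss, n, 2L) else Inf
  a_lin <- .aicc(lin$rss, n, 2L)
  model <- if (a_sat < a_lin - 1e-8) "saturating" else "linear"
  list(model = model, aicc_saturating = a_sat, aicc_linear = a_lin,
       saturation_fit = sat, linear_fit = lin)
}
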