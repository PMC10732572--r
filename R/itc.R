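# VP-ITC forward model and sequential-model fitter.
#
# The instrument perfuses: each injection of volume v displaces cell liquid,
# so totals in the (constant-volume) cell follow the discrete dilution
#   m_j = m_0 * prod_k (1 - v_k/V0)
#   l_j = c_syr * (1 - prod_k (1 - v_k/V0))
# Heats are differences of the cell's binding-enthalpy content plus a
# displacement correction using the mean of adjacent heat contents.

#' ITC titration protocol
#'
#' Geometry and schedule of an isothermal titration calorimetry experiment.
#' Defaults match a VP-ITC run: 1.4619 ml cell, 110 uM macromolecule in the
#' cell, 1.5 mM titrant in the syringe, a 2 ul pre-injection (discarded from
#' analysis) followed by 28 x 10 ul injections at 25 degC.
#'
#' @param cell_volume Cell volume in liters (default 1.4619e-3).
#' @param cell_conc Macromolecule concentration in the cell (molar).
#' @param syringe_conc Titrant concentration in the syringe (molar); must
#'   exceed `cell_conc`.
#' @param injection_volumes Vector of injection volumes in liters.
#' @param temperature Kelvin (default 298.15).
#' @param discard_first Drop the first injection from fitted isotherms
#'   (standard practice for the small pre-injection; default TRUE).
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume = 1.4619e-3,
                         cell_conc = 110e-6,
                         syringe_conc = 1.5e-3,
                         injection_volumes = c(2e-6, rep(10e-6, 28)),
                         temperature = 298.15,
                         discard_first = TRUE) {
  if (cell_volume <= 0) stop("`cell_volume` must be positive", call. = FALSE)
  if (any(injection_volumes <= 0))
    stop("all injection volumes must be positive", call. = FALSE)
  if (syringe_conc <= cell_conc)
    stop("`syringe_conc` must exceed `cell_conc`", call. = FALSE)
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature, discard_first = isTRUE(discard_first)),
    class = "itc_protocol"
  )
}

#' Cell concentrations after the j-th injection
#'
#' Applies the discrete perfusion dilution: after injections 1..j the
#' macromolecule has been diluted by `prod(1 - v_k/V0)` and the titrant has
#' accumulated to `syringe_conc * (1 - prod(1 - v_k/V0))`.
#'
#' @param protocol An [itc_protocol()].
#' @param j Injection index (1-based); `j = 0` returns pre-titration state.
#' @return Named numeric vector `c(m_total =, l_total =)` in molar.
#' @export
injection_concentrations <- function(protocol, j) {
  stopifnot(inherits(protocol, "itc_protocol"))
  n <- length(protocol$injection_volumes)
  if (j < 0 || j > n) stop(sprintf("injection index %d out of range 0..%d", j, n),
                           call. = FALSE)
  dil <- if (j == 0) 1 else
    prod(1 - protocol$injection_volumes[seq_len(j)] / protocol$cell_volume)
  c(m_total = protocol$cell_conc * dil,
    l_total = protocol$syringe_conc * (1 - dil))
}

# Heat content of the cell (kcal) for given totals: V0 * sum over species of
# [ML_i] * (cumulative enthalpy of forming ML_i)
.heat_content <- function(model, protocol, m_total, l_total) {
  st <- solve_free_ligand(model, m_total, l_total)
  cum_dh <- cumsum(model$dh)
  protocol$cell_volume * m_total *
    sum(cum_dh * st$fractions[-1L])
}

#' Forward-simulate an ITC isotherm under a sequential binding model
#'
#' Computes the heat of each injection as the change in the cell's binding
#' enthalpy content plus a displacement correction
#' `q_j = H_j - H_{j-1} + (v_j/V0) * (H_j + H_{j-1})/2`, normalised per mole
#' of injectant.  Dilution heats are taken as negligible.
#'
#' @param model A [seq_binding_model()].
#' @param protocol An [itc_protocol()].
#' @return An object of class `itc_isotherm`: data frame-like list with
#'   `injection`, `molar_ratio` (l_total/m_total in the cell), `raw_heat`
#'   (kcal) and `q_per_mol` (kcal per mole of injectant), plus the protocol.
#'   Honors `protocol$discard_first` via the `usable` logical column.
#' @export
simulate_isotherm <- function(model, protocol = itc_protocol()) {
  stopifnot(inherits(model, "seq_binding_model"),
            inherits(protocol, "itc_protocol"))
  v <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  n <- length(v)
  H <- numeric(n + 1L)
  mr <- numeric(n)
  conc0 <- injection_concentrations(protocol, 0)
  H[1L] <- .heat_content(model, protocol, conc0["m_total"], conc0["l_total"])
  q <- numeric(n)
  for (j in seq_len(n)) {
    cc <- injection_concentrations(protocol, j)
    H[j + 1L] <- .heat_content(model, protocol, cc["m_total"], cc["l_total"])
    q[j] <- H[j + 1L] - H[j] + (v[j] / V0) * (H[j + 1L] + H[j]) / 2
    mr[j] <- cc["l_total"] / cc["m_total"]
  }
  usable <- rep(TRUE, n)
  if (protocol$discard_first && n > 1L) usable[1L] <- FALSE
  structure(
    list(injection = seq_len(n), molar_ratio = mr, raw_heat = q,
         q_per_mol = q / (protocol$syringe_conc * v),
         usable = usable, protocol = protocol),
    class = "itc_isotherm"
  )
}

#' @export
print.itc_isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections (%d usable), molar ratio %.3g-%.3g\n",
              length(x$injection), sum(x$usable),
              min(x$molar_ratio), max(x$molar_ratio)))
  invisible(x)
}

#' Convert an isotherm to a data frame
#' @param x An `itc_isotherm`.
#' @param ... Unused.
#' @export
as.data.frame.itc_isotherm <- function(x, ...) {
  data.frame(injection = x$injection, molar_ratio = x$molar_ratio,
             raw_heat = x$raw_heat, q_per_mol = x$q_per_mol,
             usable = x$usable)
}

#' Fit a sequential binding model to an ITC isotherm
#'
#' Nonlinear least squares on the per-injection heats, minimising
#' `sum((q_obs - q_model)^2)` over the usable injections.  Dissociation
#' constants are fitted in log10 space (positivity and scale invariance),
#' enthalpies in linear space.  Uses Levenberg-Marquardt, with a multistart
#' over scaled initial Kd values if the first attempt fails to converge.
#'
#' @param isotherm An `itc_isotherm` (simulated or built from data via
#'   [isotherm_from_table()]).
#' @param init A [seq_binding_model()] giving initial parameter values.
#' @param control Optional [minpack.lm::nls.lm.control()] list.
#' @return An object of class `itc_fit`: list with `model` (fitted
#'   [seq_binding_model()]), `se_log10_kd`, `se_dh` (linearised standard
#'   errors), `rss`, `converged`, `n_evaluations` and `unidentifiable`
#'   (TRUE when the heats carry no signal).
#' @export
fit_sequential_itc <- function(isotherm, init,
                               control = minpack.lm::nls.lm.control(maxiter = 500)) {
  stopifnot(inherits(isotherm, "itc_isotherm"),
            inherits(init, "seq_binding_model"))
  use <- isotherm$usable
  if (sum(use) < 12L)
    stop("need at least 12 usable injections to fit six parameters",
         call. = FALSE)
  q_obs <- isotherm$q_per_mol[use]
  protocol <- isotherm$protocol
  n_step <- init$n_sites

  if (max(abs(q_obs)) < .Machine$double.eps^0.5) {
    # no heat signal at all: enthalpies are zero, Kd carries no information
    zero_model <- seq_binding_model(init$kd, rep(0, n_step), init$temperature)
    return(structure(
      list(model = zero_model,
           se_log10_kd = rep(NA_real_, n_step), se_dh = rep(NA_real_, n_step),
           rss = 0, converged = TRUE, n_evaluations = 0L,
           unidentifiable = TRUE),
      class = "itc_fit"))
  }

  residual_fun <- function(par) {
    kd <- 10^par[seq_len(n_step)]
    dh <- par[n_step + seq_len(n_step)]
    m <- seq_binding_model(kd, dh, init$temperature)
    sim <- simulate_isotherm(m, protocol)
    sim$q_per_mol[use] - q_obs
  }

  starts <- list(c(log10(init$kd), init$dh))
  for (s in c(0.1, 10))
    starts <- c(starts, list(c(log10(init$kd * s), init$dh)))

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fun, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (is.null(best) || (ok && rss < best$rss - 1e-300) ||
        (ok && !best$ok)) {
      best <- list(fit = fit, rss = rss, ok = ok)
      if (ok && rss < 1e-20 * sum(q_obs^2)) break
    }
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)

  fit <- best$fit
  par <- fit$par
  kd_hat <- 10^par[seq_len(n_step)]
  dh_hat <- par[n_step + seq_len(n_step)]

  se <- rep(NA_real_, 2 * n_step)
  cov <- tryCatch({
    dof <- length(q_obs) - length(par)
    s2 <- best$rss / max(dof, 1L)
    s2 * solve(fit$hessian / 2)  # hessian of 0.5*rss approx J'J
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se <- ifelse(d > 0, sqrt(d), NA_real_)
  }

  structure(
    list(model = seq_binding_model(kd_hat, dh_hat, init$temperature),
         se_log10_kd = se[seq_len(n_step)],
         se_dh = se[n_step + seq_len(n_step)],
         rss = best$rss, converged = best$ok,
         n_evaluations = fit$niter, unidentifiable = FALSE),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("Sequential ITC fit (%s, rss = %.4g)\n",
              if (x$converged) "converged" else "NOT converged", x$rss))
  for (i in seq_len(x$model$n_sites))
    cat(sprintf("  step %d: Kd = %.4g M, dH = %.4g kcal/mol\n",
                i, x$model$kd[i], x$model$dh[i]))
  if (isTRUE(x$unidentifiable))
    cat("  warning: heats carry no binding signal; Kd unidentifiable\n")
  invisible(x)
}

#' Build an isotherm object from a tabulated titration
#'
#' @param df Data frame with columns `injection`, `molar_ratio`, plus
#'   `volume_ul` and `q_kcal_per_mol` (raw CSV schema) or their
#'   [read_table()]-normalised forms `volume` (liters) and `q`.
#' @param protocol An [itc_protocol()]; its injection volumes are replaced
#'   by the table's.
#' @return An `itc_isotherm`.
#' @export
isotherm_from_table <- function(df, protocol = itc_protocol()) {
  if ("volume_ul" %in% names(df)) df$volume <- df$volume_ul * 1e-6
  if ("q_kcal_per_mol" %in% names(df)) df$q <- df$q_kcal_per_mol
  need <- c("injection", "volume", "molar_ratio", "q")
  if (!all(need %in% names(df)))
    stop("isotherm table needs columns: injection, molar_ratio, ",
         "volume_ul (or volume), q_kcal_per_mol (or q)", call. = FALSE)
  protocol$injection_volumes <- df$volume
  n <- nrow(df)
  usable <- rep(TRUE, n)
  if (protocol$discard_first && n > 1L) usable[1L] <- FALSE
  structure(
    list(injection = df$injection, molar_ratio = df$molar_ratio,
         raw_heat = df$q * protocol$syringe_conc *
           protocol$injection_volumes,
         q_per_mol = df$q, usable = usable, protocol = protocol),
    class = "itc_isotherm"
  )
}
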