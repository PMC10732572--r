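# 1:1 Langmuir biolayer-interferometry sensograms: closed-form simulation
# and global association/dissociation fitting.
#
# Association: R(t) = Req * (1 - exp(-kobs t)), kobs = kon*C + koff,
#              Req  = rmax * C / (C + koff/kon)
# Dissociation: R(t) = R(t_assoc) * exp(-koff * (t - t_assoc))

#' Simulate a 1:1 biosensor sensogram
#'
#' @param k_on Association rate constant (1/M/s, > 0).
#' @param k_off Dissociation rate constant (1/s, > 0).
#' @param r_max Saturating response (nm).
#' @param analyte_conc Analyte concentration during association (molar).
#' @param t_assoc,t_dissoc Phase durations in seconds (defaults 300/300).
#' @param dt Sampling interval (s, default 0.5).
#' @return An object of class `sensogram`: `time` (s), `shift` (nm),
#'   `phase` (factor: association/dissociation), `analyte_conc`,
#'   `t_assoc`.
#' @export
simulate_sensogram <- function(k_on, k_off, r_max, analyte_conc,
                               t_assoc = 300, t_dissoc = 300, dt = 0.5) {
  if (k_on <= 0 || k_off <= 0) stop("rate constants must be positive", call. = FALSE)
  if (analyte_conc < 0) stop("`analyte_conc` must be non-negative", call. = FALSE)
  t_a <- seq(0, t_assoc, by = dt)
  t_d <- seq(dt, t_dissoc, by = dt)
  kd <- k_off / k_on
  req <- r_max * analyte_conc / (analyte_conc + kd)
  k_obs <- k_on * analyte_conc + k_off
  r_a <- req * (1 - exp(-k_obs * t_a))
  r_end <- req * (1 - exp(-k_obs * t_assoc))
  r_d <- r_end * exp(-k_off * t_d)
  structure(
    list(time = c(t_a, t_assoc + t_d),
         shift = c(r_a, r_d),
         phase = factor(rep(c("association", "dissociation"),
                            c(length(t_a), length(t_d))),
                        levels = c("baseline", "association", "dissociation")),
         analyte_conc = analyte_conc, t_assoc = t_assoc),
    class = "sensogram"
  )
}

#' Globally fit the 1:1 kinetic model to a sensogram
#'
#' Fits `k_on`, `k_off` and `r_max` jointly to the association and
#' dissociation phases (equal weighting, `k_off` shared), rates in log10
#' space.  The apparent dissociation constant is `k_off / k_on` by
#' construction.  When the response is far below saturation
#' (`R_eq / r_max` small, a near-linear regime) `k_on` and `r_max` are not
#' separately identifiable and the fit is flagged.
#'
#' @param sensogram A `sensogram` (or anything with `time`, `shift`,
#'   `phase`, `analyte_conc`, `t_assoc`).
#' @param baseline_correct Subtract the mean of any `baseline`-phase points
#'   before fitting (default TRUE).
#' @return An object of class `kinetic_fit`: `k_on`, `k_off`, `r_max`,
#'   `kd_app` (= k_off/k_on), standard errors (log10 scale for rates),
#'   `rss`, `converged`, `weak_identifiability`, and `missing` naming any
#'   parameter that could not be estimated (e.g. `k_on` without an
#'   association phase).
#' @export
fit_1to1_kinetics <- function(sensogram, baseline_correct = TRUE) {
  tm <- sensogram$time
  y <- sensogram$shift
  ph <- as.character(sensogram$phase)
  C <- sensogram$analyte_conc
  t0 <- sensogram$t_assoc

  if (baseline_correct && any(ph == "baseline"))
    y <- y - mean(y[ph == "baseline"])

  ia <- ph == "association"
  id <- ph == "dissociation"

  if (max(abs(y), na.rm = TRUE) < 1e-12) {
    return(structure(
      list(k_on = NA_real_, k_off = NA_real_, r_max = NA_real_,
           kd_app = NA_real_, se_log10_kon = NA_real_,
           se_log10_koff = NA_real_, se_rmax = NA_real_, rss = 0,
           converged = FALSE, weak_identifiability = TRUE,
           missing = c("k_on", "k_off", "r_max")),
      class = "kinetic_fit"))
  }

  if (!any(ia)) {
    # dissociation only: koff from a single exponential decay
    td <- tm[id] - min(tm[id])
    yd <- y[id]
    fit <- minpack.lm::nlsLM(yd ~ a * exp(-koff * td),
                             start = list(a = max(yd), koff = 1 / max(td)),
                             lower = c(0, 1e-12))
    cf <- stats::coef(fit)
    return(structure(
      list(k_on = NA_real_, k_off = cf[["koff"]], r_max = NA_real_,
           kd_app = NA_real_, se_log10_kon = NA_real_,
           se_log10_koff = NA_real_, se_rmax = NA_real_,
           rss = sum(stats::resid(fit)^2), converged = TRUE,
           weak_identifiability = FALSE, missing = c("k_on", "r_max")),
      class = "kinetic_fit"))
  }
  if (sum(ia) < 20L || sum(id) < 20L)
    stop("need >= 20 points in each phase for the global fit", call. = FALSE)

  model_curve <- function(p) {
    kon <- 10^p[1L]; koff <- 10^p[2L]; rmax <- p[3L]
    req <- rmax * C / (C + koff / kon)
    kobs <- kon * C + koff
    out <- numeric(length(tm))
    out[ia] <- req * (1 - exp(-kobs * tm[ia]))
    r_end <- req * (1 - exp(-kobs * t0))
    out[id] <- r_end * exp(-koff * (tm[id] - t0))
    out
  }

  # starts: kobs from log-linearised association tail, koff from dissociation
  y_end <- stats::median(utils::tail(y[ia], 5L))
  koff0 <- {
    td <- tm[id] - t0; yd <- pmax(y[id], 1e-12)
    max(-stats::coef(stats::lm(log(yd) ~ td))[[2L]], 1e-6)
  }
  kobs0 <- max(koff0 * 2, 1 / max(tm[ia]))
  kon0 <- max((kobs0 - koff0) / max(C, 1e-12), 1e-3)
  rmax0 <- max(y_end * (C + koff0 / kon0) / max(C, 1e-30), max(y))

  mask <- ia | id
  fit <- minpack.lm::nls.lm(
    par = c(log10(kon0), log10(koff0), rmax0),
    fn = function(p) model_curve(p)[mask] - y[mask],
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  kon <- 10^fit$par[1L]; koff <- 10^fit$par[2L]; rmax <- fit$par[3L]
  rss <- sum(fit$fvec^2)

  se <- rep(NA_real_, 3L)
  cov <- tryCatch({
    s2 <- rss / max(sum(mask) - 3L, 1L)
    s2 * solve(fit$hessian / 2)
  }, error = function(e) NULL)
  if (!is.null(cov) && all(diag(cov) >= 0)) se <- sqrt(diag(cov))

  # near-linear regime: response a tiny fraction of saturation, or C far
  # from Kd so kon/rmax trade off freely; also flag kinetics faster than
  # the sampling interval can resolve (the trace is then a step function
  # and the rate constants are not determined by the data)
  req_frac <- (C / (C + koff / kon))
  dt_s <- stats::median(diff(tm))
  unresolved <- (kon * C + koff) * dt_s > 1 || koff * dt_s > 1
  weak <- req_frac < 0.05 || req_frac > 0.995 || unresolved

  structure(
    list(k_on = kon, k_off = koff, r_max = rmax, kd_app = koff / kon,
         se_log10_kon = se[1L], se_log10_koff = se[2L], se_rmax = se[3L],
         rss = rss, converged = fit$info %in% 1:4,
         weak_identifiability = weak, missing = character(0)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: kon = %.4g /M/s, koff = %.4g /s, Kd_app = %.4g M\n",
              x$k_on, x$k_off, x$kd_app))
  if (isTRUE(x$weak_identifiability))
    cat("  warning: weak identifiability (response far from saturation)\n")
  if (length(x$missing))
    cat("  missing parameters:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Observed-rate analysis across analyte concentrations
#'
#' Fits each association phase to a single exponential to obtain k_obs(C),
#' then regresses k_obs on C: slope = k_on, intercept = k_off.  An
#' independent route to the rate constants that does not share code with
#' the global fit.
#'
#' @param sensograms List of `sensogram` objects at distinct analyte
#'   concentrations.
#' @return List with `k_on`, `k_off`, and the per-curve `k_obs` table.
#' @export
kobs_linear_analysis <- function(sensograms) {
  kobs <- vapply(sensograms, function(s) {
    ia <- as.character(s$phase) == "association"
    tt <- s$time[ia]; yy <- s$shift[ia]
    fit <- minpack.lm::nlsLM(yy ~ req * (1 - exp(-k * tt)),
                             start = list(req = max(yy), k = 2 / max(tt)),
                             lower = c(0, 1e-9))
    stats::coef(fit)[["k"]]
  }, numeric(1))
  conc <- vapply(sensograms, `[[`, numeric(1), "analyte_conc")
  line <- stats::lm(kobs ~ conc)
  list(k_on = unname(stats::coef(line)[2L]),
       k_off = unname(stats::coef(line)[1L]),
       table = data.frame(analyte_conc = conc, k_obs = kobs))
}
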