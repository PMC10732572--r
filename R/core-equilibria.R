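# Exact solution of the stoichiometric sequential binding equilibrium
#
#   M + L <-> ML1 + L <-> ML2 + L <-> ML3
#
# parameterised by stepwise dissociation constants K_i (molar) and per-step
# molar enthalpies dH_i (kcal/mol).  All concentrations are molar internally.

#' Gas constant used throughout, in cal/mol/K
#'
#' Fixed at 1.986 cal/mol/K (the convention of the calorimetric analysis this
#' package reproduces), not the CODATA value.
#' @keywords internal
R_CAL <- 1.986

#' Sequential multi-site binding model
#'
#' Constructs a stoichiometric sequential binding model: the macromolecule M
#' binds ligand L in `n` ordered steps, step i governed by the stepwise
#' (stoichiometric) dissociation constant `kd[i]` and releasing molar
#' enthalpy `dh[i]`.  Stepwise constants describe the i-th ligand added to
#' ML(i-1) irrespective of which physical site binds.
#'
#' @param kd Numeric vector of stepwise dissociation constants (molar),
#'   one per binding step.  All must be positive.
#' @param dh Numeric vector of per-step enthalpy changes (kcal/mol).
#'   Defaults to zeros (athermal model).
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @return An object of class `seq_binding_model`.
#' @examples
#' # three-site Ca2+ ladder of an EF-hand sensor in Na+ buffer
#' m <- seq_binding_model(kd = c(265e-9, 758e-9, 379e-9),
#'                        dh = c(-7.7, 3.0, -9.1))
#' @export
seq_binding_model <- function(kd, dh = rep(0, length(kd)), temperature = 298.15) {
  kd <- as.numeric(kd)
  dh <- as.numeric(dh)
  if (length(kd) < 1L)
    stop("at least one binding step is required", call. = FALSE)
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("all stepwise dissociation constants must be positive and finite",
         call. = FALSE)
  if (length(dh) != length(kd))
    stop("`dh` must have one entry per binding step", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be a positive absolute temperature (K)",
         call. = FALSE)
  structure(
    list(kd = kd, dh = dh, temperature = temperature,
         n_sites = length(kd)),
    class = "seq_binding_model"
  )
}

#' @export
print.seq_binding_model <- function(x, ...) {
  cat(sprintf("Sequential binding model (%d sites, T = %.2f K)\n",
              x$n_sites, x$temperature))
  for (i in seq_len(x$n_sites))
    cat(sprintf("  step %d: Kd = %.4g M, dH = %.3g kcal/mol\n",
                i, x$kd[i], x$dh[i]))
  invisible(x)
}

#' Overall (cumulative) association constants of a sequential model
#'
#' beta_i = prod_{k <= i} 1/Kd_k, the overall association constant for
#' forming ML_i from M + i L.  Units M^-i.
#'
#' @param model A [seq_binding_model()].
#' @return Numeric vector `beta` of length `n_sites`.
#' @export
stepwise_to_overall <- function(model) {
  stopifnot(inherits(model, "seq_binding_model"))
  cumprod(1 / model$kd)
}

# Polynomial terms t_i = beta_i * l^i (t_0 = 1), built by cascade so the
# intermediate ratios l/kd_i stay in double range.
.binding_poly_terms <- function(kd, l_free) {
  n <- length(kd)
  terms <- numeric(n + 1L)
  terms[1L] <- 1
  for (i in seq_len(n)) terms[i + 1L] <- terms[i] * (l_free / kd[i])
  terms
}

# Bound ligand per mole of macromolecule at free-ligand concentration l:
# <n>(l) = sum i t_i / sum t_i
.mean_bound <- function(kd, l_free) {
  t <- .binding_poly_terms(kd, l_free)
  sum(seq_along(t[-1L]) * t[-1L]) / sum(t)
}

#' Solve the free-ligand concentration of a sequential equilibrium
#'
#' Inverts the ligand mass balance
#' `l_free + m_total * <n>(l_free) = l_total`, where `<n>` is the binding
#' polynomial's mean number of ligands bound, by bisection on
#' `[0, l_total]` (the residual is monotone there).  Returns the complete
#' species distribution.
#'
#' @param model A [seq_binding_model()].
#' @param m_total Total macromolecule concentration (molar, >= 0).
#' @param l_total Total ligand concentration (molar, >= 0).
#' @param rel_tol Relative convergence tolerance on `l_free`
#'   (default 1e-12).
#' @return An object of class `species_state`: list with `l_free` (molar),
#'   `fractions` (numeric vector of length `n_sites + 1`, the fraction of
#'   macromolecule carrying exactly 0..n ligands), and the input totals.
#' @export
solve_free_ligand <- function(model, m_total, l_total, rel_tol = 1e-12) {
  stopifnot(inherits(model, "seq_binding_model"))
  if (!is.finite(m_total) || m_total < 0)
    stop("`m_total` must be non-negative", call. = FALSE)
  if (!is.finite(l_total) || l_total < 0)
    stop("`l_total` must be non-negative", call. = FALSE)
  kd <- model$kd

  if (l_total == 0 || m_total == 0) {
    l_free <- l_total
  } else {
    resid <- function(l) l + m_total * .mean_bound(kd, l) - l_total
    lo <- 0
    hi <- l_total
    # resid(0) = -l_total < 0, resid(l_total) >= 0: bracket guaranteed
    for (iter in seq_len(10000L)) {
      mid <- (lo + hi) / 2
      if (resid(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= rel_tol * max(hi, .Machine$double.xmin)) break
    }
    if (iter == 10000L)
      stop(sprintf(
        "free-ligand bisection did not converge (bracket [%g, %g])", lo, hi),
        call. = FALSE)
    l_free <- (lo + hi) / 2
  }

  terms <- .binding_poly_terms(kd, l_free)
  fractions <- terms / sum(terms)
  structure(
    list(l_free = l_free, fractions = fractions,
         m_total = m_total, l_total = l_total),
    class = "species_state"
  )
}

#' Site-availability profile along a titration
#'
#' For each stoichiometric binding class i, Theta_i(L_total) is the fraction
#' of macromolecules at which step i has not yet occurred, i.e. that carry
#' fewer than i ligands: `Theta_i = sum_{j < i} f_j`.  Theta starts at 1 for
#' every class and decays to 0 at saturation.  This is a stoichiometric-step
#' availability, not a site-specific (microscopic) one; the distinction is
#' recorded in the returned object's `definition` field.
#'
#' @param model A [seq_binding_model()].
#' @param m_total Total macromolecule concentration (molar).
#' @param l_total_grid Ascending vector of total ligand concentrations
#'   (molar).
#' @return An object of class `theta_profile`: list with `l_total_grid`,
#'   `theta` (`n_sites` x `length(grid)` matrix) and `definition`.
#' @export
site_occupancy_profile <- function(model, m_total, l_total_grid) {
  stopifnot(inherits(model, "seq_binding_model"))
  if (length(l_total_grid) == 0L)
    stop("`l_total_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(l_total_grid))
    stop("`l_total_grid` must be sorted ascending", call. = FALSE)
  n <- model$n_sites
  theta <- matrix(NA_real_, nrow = n, ncol = length(l_total_grid))
  for (j in seq_along(l_total_grid)) {
    f <- solve_free_ligand(model, m_total, l_total_grid[j])$fractions
    theta[, j] <- cumsum(f)[seq_len(n)]  # sum_{j<i} f_j for i = 1..n
  }
  structure(
    list(l_total_grid = l_total_grid, theta = theta,
         definition = "stoichiometric-step availability: Theta_i = P(fewer than i ligands bound)"),
    class = "theta_profile"
  )
}

#' Standard free energy of a binding step
#'
#' `dG = -R T ln(1/Kd)` with R = 1.986 cal/mol/K, reported in kcal/mol.
#' Negative for sub-molar dissociation constants (favourable binding).
#'
#' @param kd Dissociation constant (molar, > 0); vectorised.
#' @param temperature Absolute temperature (K), default 298.15.
#' @return Free energy change(s) in kcal/mol.
#' @export
delta_g <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("`kd` must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  -(R_CAL / 1000) * temperature * log(1 / kd)
}

#' Bound fraction of a 1:1 equilibrium (exact quadratic solution)
#'
#' Fraction of macromolecule bound in M + L <-> ML with dissociation
#' constant `kd`, from the exact quadratic root of the coupled mass
#' balances.  In the ligand-excess limit this reduces to
#' `l / (kd + l)`.
#'
#' @param kd Dissociation constant (molar, > 0).
#' @param m_total Total macromolecule (molar, >= 0).
#' @param l_total Total ligand (molar, >= 0).
#' @return Bound fraction in [0, 1]; 0 when `m_total` is 0.
#' @export
one_to_one_bound_fraction <- function(kd, m_total, l_total) {
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be positive", call. = FALSE)
  if (m_total < 0 || l_total < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (m_total == 0 || l_total == 0) return(0)
  b <- m_total + l_total + kd
  # smaller root of x^2 - b x + m l = 0; rearranged for cancellation safety
  ml <- 2 * m_total * l_total / (b + sqrt(b^2 - 4 * m_total * l_total))
  min(max(ml / m_total, 0), 1)
}
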