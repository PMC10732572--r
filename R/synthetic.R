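# Synthetic-data generators: every assay's input with known ground truth,
# stated noise models, and deterministic per-dataset seeds, so all fitting
# stages are testable offline.  Ground truth travels as the "ground_truth"
# attribute of each object — never as part of the data a fitter sees.
#
# Default noise levels (sd): ITC 2% of |q|max; titration/BLI 2% of
# amplitude; exchange 3% of amplitude; melt 0.5% of the ratio range.
# These are chosen to visually match published trace scatter and are
# arbitrary in that sense.

#' Derive a deterministic per-dataset seed
#'
#' Maps (master seed, assay label, replicate) to a 31-bit seed so studies
#' are reproducible and parallelizable without stream collisions.
#'
#' @param master Master integer seed.
#' @param assay Assay label (character).
#' @param replicate Replicate index (default 1).
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(master, assay, replicate = 1L) {
  h <- sum(utf8ToInt(assay) * seq_along(utf8ToInt(assay)))
  as.integer((as.numeric(master) * 1000003 + h * 7919 + replicate * 104729) %%
               2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Parameter presets from the characterised NCS-1 / Ric-8A system
#'
#' Named ground-truth parameter sets used throughout the tests and the
#' reproduction script: the three-site Ca2+ ladders measured in Na+ and K+
#' buffers, the BLI affinities across the Ca2+ series, the two activation
#' constants, and the melt midpoints.
#'
#' @param name One of `"table_na"`, `"table_k"` (sequential ITC: kd in M,
#'   dh in kcal/mol), `"bli_ca0"`, `"bli_ca250"`, `"bli_ca375"`,
#'   `"bli_ca425"` (kd_app in M), `"ka_exc"`, `"ka_complex"` (ka in M),
#'   `"ti_free_ric8a"`, `"ti_free_ncs1"`, `"ti_complex_ric8a"`,
#'   `"ti_complex_ncs1"` (tm in degC), `"fluor_na"` (kd_app in M).
#' @return Named list of ground-truth parameters.
#' @export
assay_preset <- function(name) {
  presets <- list(
    table_na = list(kd = c(265e-9, 758e-9, 379e-9), dh = c(-7.7, 3.0, -9.1)),
    table_k = list(kd = c(165.6e-9, 362.3e-9, 253e-9), dh = c(-7.66, 1.00, -9.44)),
    fluor_na = list(kd_app = 123.4e-3, y_max = 1),
    bli_ca0 = list(kd_app = 140e-6),
    bli_ca250 = list(kd_app = 344e-6),
    bli_ca375 = list(kd_app = 381e-6),
    bli_ca425 = list(kd_app = 98620e-6),
    ka_exc = list(ka = 29e-6),
    ka_complex = list(ka = 61e-6),
    ti_free_ric8a = list(tm = 53.5),
    ti_free_ncs1 = list(tm = 58.4),
    ti_complex_ric8a = list(tm = 79.7),
    ti_complex_ncs1 = list(tm = 82.8)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Generate a synthetic ITC isotherm
#'
#' Forward-simulates the sequential-model isotherm under the given protocol
#' and adds Gaussian noise (sd expressed as a fraction of the largest
#' per-mole heat).  `noise_sd = 0` reproduces [simulate_isotherm()]
#' exactly.
#'
#' @param model A [seq_binding_model()] (the ground truth).
#' @param protocol An [itc_protocol()].
#' @param noise_sd Relative noise sd (fraction of max |q|; default 0.02).
#' @param seed Integer seed.
#' @return An `itc_isotherm` with attribute `ground_truth = model`.
#' @export
gen_itc <- function(model, protocol = itc_protocol(), noise_sd = 0.02,
                    seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  iso <- simulate_isotherm(model, protocol)
  if (noise_sd > 0) {
    scale <- noise_sd * max(abs(iso$q_per_mol))
    noise <- .with_seed(seed, stats::rnorm(length(iso$q_per_mol), 0, scale))
    iso$q_per_mol <- iso$q_per_mol + noise
    iso$raw_heat <- iso$q_per_mol * protocol$syringe_conc *
      protocol$injection_volumes
  }
  attr(iso, "ground_truth") <- model
  iso
}

#' Generate a synthetic 1:1 saturation titration
#'
#' @param kd_app Apparent dissociation constant (molar).
#' @param y_max Saturating amplitude (default 1).
#' @param conc_grid Ligand concentrations (molar); default 15 points over
#'   0-300 mM.
#' @param noise_sd Gaussian sd as a fraction of `y_max` (default 0.02).
#' @param seed Integer seed.
#' @return A [titration_curve()] with `ground_truth` attribute.
#' @export
gen_titration <- function(kd_app, y_max = 1,
                          conc_grid = seq(0, 300e-3, length.out = 15),
                          noise_sd = 0.02, seed = 1L) {
  y <- y_max * conc_grid / (kd_app + conc_grid)
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, noise_sd * y_max))
  out <- titration_curve(conc_grid, y)
  attr(out, "ground_truth") <- list(kd_app = kd_app, y_max = y_max)
  out
}

#' Generate a synthetic linear (non-saturating) titration
#'
#' The weak-binder control: signal proportional to concentration with no
#' curvature over the titrated range.
#'
#' @param slope Signal per molar.
#' @param conc_grid Ligand concentrations (molar).
#' @param noise_sd Absolute Gaussian sd (default 0).
#' @param seed Integer seed.
#' @return A [titration_curve()] with `ground_truth` attribute.
#' @export
gen_titration_linear <- function(slope,
                                 conc_grid = seq(0, 500e-3, length.out = 15),
                                 noise_sd = 0, seed = 1L) {
  y <- slope * conc_grid
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  out <- titration_curve(conc_grid, y)
  attr(out, "ground_truth") <- list(slope = slope)
  out
}

#' Generate a synthetic BLI sensogram
#'
#' @param k_on,k_off,r_max 1:1 kinetic ground truth.
#' @param analyte_conc Analyte concentration (molar; default 50e-6).
#' @param noise_sd Gaussian sd as a fraction of the response amplitude
#'   (default 0.02).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_sensogram()] (`t_assoc`, `t_dissoc`,
#'   `dt`).
#' @return A `sensogram` with `ground_truth` attribute.
#' @export
gen_sensogram <- function(k_on, k_off, r_max = 1, analyte_conc = 50e-6,
                          noise_sd = 0.02, seed = 1L, ...) {
  s <- simulate_sensogram(k_on, k_off, r_max, analyte_conc, ...)
  if (noise_sd > 0) {
    amp <- max(abs(s$shift))
    s$shift <- s$shift +
      .with_seed(seed, stats::rnorm(length(s$shift), 0, noise_sd * amp))
  }
  attr(s, "ground_truth") <- list(k_on = k_on, k_off = k_off, r_max = r_max,
                                  kd_app = k_off / k_on)
  s
}

#' Generate a set of exchange progress curves across a Ca2+ series
#'
#' For each CaCl2 concentration, the observed (slow) exchange rate is drawn
#' from the activation hyperbola `v = v0 + vmax [Ca]/(Ka + [Ca])` and a
#' single-exponential fluorescence progress curve is built at that rate;
#' optionally a fast intermediary-complex phase is superimposed.
#'
#' @param ka Activation constant (molar).
#' @param v0 Basal rate (1/s, default 0.002).
#' @param v_max Rate increment (1/s, default 0.006).
#' @param ca_series CaCl2 concentrations (molar); default the assay set
#'   0, 1, 10, 25, 50, 500 uM.
#' @param f0 Baseline fluorescence (default 1).
#' @param amplitude Fluorescence amplitude (default 0.5).
#' @param fast_rate If non-NULL, adds a fast phase at this rate (1/s) with
#'   `fast_amplitude`.
#' @param fast_amplitude Amplitude of the fast phase (default 0.2).
#' @param t_max Duration (s, default 1200), `dt` sampling step (s).
#' @param dt Sampling interval (s, default 5).
#' @param noise_sd Gaussian sd as a fraction of `amplitude` (default 0.03).
#' @param seed Integer seed.
#' @return List of [progress_curve()]s with a `ground_truth` attribute
#'   carrying `ka`, `v0`, `v_max` and the per-curve true rates.
#' @export
gen_progress <- function(ka, v0 = 0.002, v_max = 0.006,
                         ca_series = c(0, 1, 10, 25, 50, 500) * 1e-6,
                         f0 = 1, amplitude = 0.5,
                         fast_rate = NULL, fast_amplitude = 0.2,
                         t_max = 1200, dt = 5, noise_sd = 0.03, seed = 1L) {
  tt <- seq(0, t_max, by = dt)
  rates <- activation_hyperbola(ca_series, v0, v_max, ka)
  curves <- lapply(seq_along(ca_series), function(i) {
    ff <- f0 + amplitude * (1 - exp(-rates[i] * tt))
    if (!is.null(fast_rate))
      ff <- ff + fast_amplitude * (1 - exp(-fast_rate * tt))
    if (noise_sd > 0)
      ff <- ff + .with_seed(derive_seed(seed, "progress", i),
                            stats::rnorm(length(tt), 0, noise_sd * amplitude))
    progress_curve(tt, ff, condition = sprintf("Ca_%g_uM", ca_series[i] * 1e6),
                   ca_conc = ca_series[i])
  })
  attr(curves, "ground_truth") <- list(ka = ka, v0 = v0, v_max = v_max,
                                       ca_series = ca_series, rates = rates,
                                       fast_rate = fast_rate)
  curves
}

#' Generate a synthetic nano-DSF melt curve
#'
#' One or more two-state transitions with linear baselines; multiple
#' transitions are summed as independent unfolding amplitudes (the melt of
#' a two-protein complex).
#'
#' @param tm Midpoint(s), degC.
#' @param dh_vh Van 't Hoff enthalpy(ies), kcal/mol; recycled.
#' @param amplitudes Per-transition ratio amplitude(s); recycled
#'   (default 0.2).
#' @param baseline Length-2 `c(intercept, slope_per_degC)` of the folded
#'   baseline (default `c(0.8, 0)`).
#' @param t_grid Temperatures (degC), default 35-95 by 0.1.
#' @param noise_sd Gaussian sd as a fraction of the total amplitude
#'   (default 0.005).
#' @param seed Integer seed.
#' @return A [melt_curve()] with `ground_truth` attribute.
#' @export
gen_melt <- function(tm, dh_vh = 100, amplitudes = 0.2,
                     baseline = c(0.8, 0), t_grid = seq(35, 95, by = 0.1),
                     noise_sd = 0.005, seed = 1L) {
  k <- length(tm)
  dh_vh <- rep_len(dh_vh, k)
  amplitudes <- rep_len(amplitudes, k)
  ratio <- baseline[1L] + baseline[2L] * t_grid
  tk <- t_grid + 273.15
  for (i in seq_len(k)) {
    theta <- 1 / (1 + exp((dh_vh[i] / (R_CAL / 1000)) *
                            (1 / tk - 1 / (tm[i] + 273.15))))
    ratio <- ratio + amplitudes[i] * theta
  }
  if (noise_sd > 0)
    ratio <- ratio + .with_seed(seed, stats::rnorm(length(ratio), 0,
                                                   noise_sd * sum(amplitudes)))
  out <- melt_curve(t_grid, ratio)
  attr(out, "ground_truth") <- list(tm = tm, dh_vh = dh_vh,
                                    amplitudes = amplitudes)
  out
}

#' Generate a toy two-chain complex with a known contact count
#'
#' Builds chain A as carbon atoms spaced far apart (> 2x cutoff), then
#' places exactly `n_contacts_target` chain-B atoms each 3.5 A from a
#' distinct A atom, plus decoy B atoms far from everything.  By
#' construction the inter-chain contact census at the default 4.2 A cutoff
#' equals `n_contacts_target` exactly.
#'
#' @param n_atoms Total atoms per chain (>= `n_contacts_target`).
#' @param n_contacts_target Exact number of inter-chain contacts to build.
#' @param seed Integer seed.
#' @param cutoff Contact cutoff the construction guarantees (default 4.2).
#' @return An [xtal_structure()] with chains "A" and "B" and attribute
#'   `ground_truth = list(n_contacts = ...)`.
#' @export
gen_toy_complex <- function(n_atoms = 50, n_contacts_target = 10, seed = 1L,
                            cutoff = 4.2) {
  if (n_contacts_target > n_atoms)
    stop("`n_contacts_target` cannot exceed `n_atoms`", call. = FALSE)
  spacing <- 3 * cutoff
  .with_seed(seed, {
    # chain A on a jittered cubic lattice, sites >= 2*cutoff apart
    side <- ceiling(n_atoms^(1 / 3))
    grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    grid <- grid[seq_len(n_atoms), ] * spacing
    jit <- matrix(stats::runif(3 * n_atoms, -0.5, 0.5), ncol = 3)
    xyz_a <- as.matrix(grid) + jit

    # contact-forming B atoms: 3.5 A from distinct A atoms, random direction
    dirs <- matrix(stats::rnorm(3 * n_contacts_target), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    xyz_b_near <- xyz_a[seq_len(n_contacts_target), , drop = FALSE] + 3.5 * dirs

    # decoy B atoms displaced far outside the A lattice
    n_far <- n_atoms - n_contacts_target
    xyz_b_far <- if (n_far > 0) {
      off <- (side + 3) * spacing
      cbind(stats::runif(n_far, off, off + side * spacing),
            stats::runif(n_far, 0, side * spacing),
            stats::runif(n_far, 0, side * spacing))
    } else matrix(numeric(0), ncol = 3)

    xyz_b <- rbind(xyz_b_near, xyz_b_far)
    mk <- function(chain, xyz) data.frame(
      chain = chain, resno = seq_len(nrow(xyz)), insert = "",
      resid = "ALA", elety = paste0("C", seq_len(nrow(xyz))), elesy = "C",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
      is_water = FALSE, is_ion = FALSE, stringsAsFactors = FALSE)
    out <- xtal_structure(rbind(mk("A", xyz_a), mk("B", xyz_b)))
    attr(out, "ground_truth") <- list(n_contacts = n_contacts_target)
    out
  })
}
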