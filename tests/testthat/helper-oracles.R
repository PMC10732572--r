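# Independent oracles used across the suite.  These deliberately share no
# code with the package internals they check.

# brute-force bisection for the free ligand of a sequential equilibrium,
# written directly from the mass balance with overall constants
oracle_free_ligand <- function(kd, m_total, l_total, tol = 1e-14) {
  beta <- cumprod(1 / kd)
  bound_per_m <- function(l) {
    terms <- beta * l^seq_along(beta)
    sum(seq_along(beta) * terms) / (1 + sum(terms))
  }
  g <- function(l) l + m_total * bound_per_m(l) - l_total
  lo <- 0; hi <- l_total
  for (i in 1:200) {  # halving 200 times reaches double-precision resolution
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# closed-form single-site (Wiseman) per-injection heats under the same
# discrete-dilution protocol; quadratic bound-species solution
oracle_wiseman_isotherm <- function(kd, dh, protocol) {
  v <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  bound <- function(m, l) {
    b <- m + l + kd
    (b - sqrt(b^2 - 4 * m * l)) / 2
  }
  heat <- function(j) {
    dil <- if (j == 0) 1 else prod(1 - v[seq_len(j)] / V0)
    m <- protocol$cell_conc * dil
    l <- protocol$syringe_conc * (1 - dil)
    V0 * dh * bound(m, l)
  }
  q <- numeric(length(v))
  H_prev <- heat(0)
  for (j in seq_along(v)) {
    H <- heat(j)
    q[j] <- H - H_prev + (v[j] / V0) * (H + H_prev) / 2
    H_prev <- H
  }
  q / (protocol$syringe_conc * v)
}

# exhaustive 2-D grid search for the 1:1 saturation fit
oracle_grid_saturation <- function(L, y, kd_range, ymax_range, n = 500) {
  kds <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n))
  ymaxs <- seq(ymax_range[1], ymax_range[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (kd in kds) {
    pred_unit <- L / (kd + L)
    # profile over ymax analytically within the grid for speed
    rss <- vapply(ymaxs, function(ym) sum((y - ym * pred_unit)^2), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(kd, ymaxs[i], rss[i])
  }
  list(kd = best[1], y_max = best[2], rss = best[3])
}

# O(n^2) triple-loop contact count between two chains of a structure
oracle_contact_count <- function(struct, chain_a, chain_b, cutoff) {
  a <- struct$atoms
  ia <- which(a$chain == chain_a)
  ib <- which(a$chain == chain_b)
  n <- 0L
  for (i in ia) for (j in ib) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff) n <- n + 1L
  }
  n
}

# analytic buried SASA of two overlapping spheres (spherical caps)
oracle_two_sphere_buried <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}

# tiny structure builder for geometric fixtures
make_structure <- function(chain, elesy, xyz, resid = "ALA",
                           elety = NULL, is_water = FALSE) {
  n <- nrow(xyz)
  if (is.null(elety)) elety <- paste0(elesy, seq_len(n))
  xtal_structure(data.frame(
    chain = rep_len(chain, n), resno = seq_len(n), insert = "",
    resid = rep_len(resid, n), elety = elety, elesy = rep_len(elesy, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
    is_water = rep_len(is_water, n), is_ion = FALSE,
    stringsAsFactors = FALSE))
}
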