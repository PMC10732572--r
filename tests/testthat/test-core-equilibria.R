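test_that("overall association constants follow the stepwise cascade", {
  expect_equal(stepwise_to_overall(seq_binding_model(c(1, 1, 1))), c(1, 1, 1))

  m <- seq_binding_model(c(265e-9, 758e-9, 379e-9))
  beta <- stepwise_to_overall(m)
  expect_equal(beta[1], 1 / 265e-9)
  expect_equal(beta[2], beta[1] / 758e-9)
  expect_equal(beta[3], beta[2] / 379e-9)

  # log-space cross-check for the equal-micro molar ladder
  beta3 <- stepwise_to_overall(seq_binding_model(rep(1e-6, 3)))[3]
  expect_equal(log10(beta3), 18, tolerance = 1e-12)

  expect_error(seq_binding_model(c(1, -1, 1)), "positive")
})

test_that("free-ligand solver satisfies its limits and the bisection oracle", {
  m <- seq_binding_model(rep(1e-6, 3))

  st0 <- solve_free_ligand(m, 1e-6, 0)
  expect_equal(st0$l_free, 0)
  expect_equal(st0$fractions, c(1, 0, 0, 0))

  st_nom <- solve_free_ligand(m, 0, 5e-6)
  expect_equal(st_nom$l_free, 5e-6)

  st <- solve_free_ligand(m, 1e-6, 2e-6)
  l_or <- oracle_free_ligand(rep(1e-6, 3), 1e-6, 2e-6)
  expect_equal(st$l_free, l_or, tolerance = 1e-10)
  expect_equal(sum(st$fractions), 1, tolerance = 1e-10)
})

test_that("fraction normalization and ligand mass balance hold over random draws", {
  set.seed(42)
  n_draw <- 10000
  for (i in seq_len(n_draw)) {
    kd <- 10^stats::runif(3, -9, 0)
    m_tot <- 10^stats::runif(1, -9, 0)
    l_tot <- 10^stats::runif(1, -9, 0)
    st <- solve_free_ligand(seq_binding_model(kd), m_tot, l_tot)
    f <- st$fractions
    if (abs(sum(f) - 1) > 1e-10 || any(f < -1e-15 | f > 1 + 1e-15))
      fail(sprintf("fraction invariant broken at draw %d", i))
    bound <- m_tot * sum(seq_len(3) * f[-1])
    if (abs(st$l_free + bound - l_tot) > 1e-9 * l_tot)
      fail(sprintf("mass balance broken at draw %d", i))
  }
  succeed()
})

test_that("free ligand increases strictly with total ligand", {
  m <- seq_binding_model(c(265e-9, 758e-9, 379e-9))
  grid <- seq(1e-8, 5e-4, length.out = 40)
  lf <- vapply(grid, function(lt) solve_free_ligand(m, 110e-6, lt)$l_free,
               numeric(1))
  expect_true(all(diff(lf) > 0))
})

test_that("sequential solver collapses to the 1:1 quadratic with one active step", {
  # steps 2 and 3 switched off by pushing their Kd to +infinity
  kd1 <- 3e-7
  m <- seq_binding_model(c(kd1, 1e12, 1e12))
  for (lt in c(1e-7, 1e-6, 5e-6)) {
    st <- solve_free_ligand(m, 1e-6, lt)
    frac_seq <- sum(seq_len(3) * st$fractions[-1])
    frac_quad <- one_to_one_bound_fraction(kd1, 1e-6, lt)
    expect_equal(frac_seq, frac_quad, tolerance = 1e-10)
  }
})

test_that("site-availability profile starts full, decays to zero, monotone", {
  m <- seq_binding_model(c(265e-9, 758e-9, 379e-9))
  m_tot <- 110e-6
  sat <- 1e6 * max(m$kd) + 3 * m_tot
  grid <- c(0, 10^seq(-7, log10(sat), length.out = 25))
  prof <- site_occupancy_profile(m, m_tot, grid)

  expect_equal(prof$theta[, 1], c(1, 1, 1))
  expect_true(all(prof$theta[, ncol(prof$theta)] < 1e-3))
  expect_true(all(prof$theta >= 0 & prof$theta <= 1))
  # availability never increases along the titration
  expect_true(all(apply(prof$theta, 1, function(r) all(diff(r) <= 1e-12))))

  expect_error(site_occupancy_profile(m, m_tot, numeric(0)), "non-empty")
})

test_that("third binding class fills last under the Na+ ladder and ITC grid", {
  m <- seq_binding_model(c(265e-9, 758e-9, 379e-9))
  prot <- itc_protocol()
  grid <- vapply(seq_along(prot$injection_volumes),
                 function(j) injection_concentrations(prot, j)[["l_total"]],
                 numeric(1))
  prof <- site_occupancy_profile(m, prot$cell_conc, grid)
  # at every point along the titration, step 3 has more availability left
  # than steps 1 and 2: its filling is delayed
  expect_true(all(prof$theta[3, ] >= prof$theta[2, ] - 1e-12))
  expect_true(all(prof$theta[2, ] >= prof$theta[1, ] - 1e-12))
  mid <- ceiling(ncol(prof$theta) / 2)
  expect_gt(prof$theta[3, mid], prof$theta[1, mid])
})

test_that("free energy conversion matches the stated formula and its laws", {
  expect_equal(delta_g(1), 0)
  # independent hand evaluation of -RT ln(1/K), R = 1.986 cal/mol/K
  expect_equal(delta_g(265e-9, 298.15),
               -(1.986e-3) * 298.15 * log(1 / 265e-9))
  # halving Kd at fixed T lowers dG by RT ln 2
  expect_equal(delta_g(1e-6) - delta_g(5e-7),
               1.986e-3 * 298.15 * log(2))
  # monotone in kd
  kds <- 10^seq(-9, 0, length.out = 20)
  expect_true(all(diff(delta_g(kds)) > 0))
  expect_error(delta_g(0), "positive")
})

test_that("1:1 bound fraction is exact against bisection and its limits", {
  # half saturation in ligand excess
  expect_equal(one_to_one_bound_fraction(1e-3, 1e-9, 1e-3), 0.5,
               tolerance = 1e-3)
  expect_equal(one_to_one_bound_fraction(1e-3, 1e-6, 0), 0)
  # quadratic vs bisection oracle on a mM-range case
  kd <- 123.4e-3; m_tot <- 10e-6; l_tot <- 300e-3
  bisect <- local({
    g <- function(x) (m_tot - x) * (l_tot - x) - kd * x
    lo <- 0; hi <- m_tot
    while (hi - lo > 1e-20) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2 / m_tot
  })
  expect_equal(one_to_one_bound_fraction(kd, m_tot, l_tot), bisect,
               tolerance = 1e-9)
})
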