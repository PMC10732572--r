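sel_A <- list(chain = "A")
sel_B <- list(chain = "B")

test_that("structures round-trip through PDB read/write", {
  toy <- gen_toy_complex(n_atoms = 20, n_contacts_target = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$atoms))
  expect_equal(back$atoms$chain, toy$atoms$chain)
  expect_equal(back$atoms$resno, toy$atoms$resno)
  # PDB fixed columns carry 3 decimals; equality to that precision
  expect_equal(back$atoms$x, toy$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$z, toy$atoms$z, tolerance = 1e-3)

  expect_error(read_structure("no/such/file.pdb"), "no such file")
})

test_that("contact counting respects the cutoff boundary exactly", {
  two_far <- make_structure(c("A", "B"), "C",
                            rbind(c(0, 0, 0), c(4.30, 0, 0)))
  expect_equal(count_contacts(two_far, sel_A, sel_B)$n_contacts, 0)

  two_near <- make_structure(c("A", "B"), "C",
                             rbind(c(0, 0, 0), c(4.10, 0, 0)))
  expect_equal(count_contacts(two_near, sel_A, sel_B)$n_contacts, 1)

  expect_error(count_contacts(two_near, list(chain = "Z"), sel_B), "empty")
  expect_error(count_contacts(two_near, sel_A, sel_A), "disjoint")
})

test_that("census equals the all-pairs oracle and survives rigid motion", {
  set.seed(99)
  for (rep in 1:6) {
    struct <- make_structure(
      rep(c("A", "B"), each = 100), "C",
      matrix(stats::runif(600, 0, 30), ncol = 3))
    n_pkg <- count_contacts(struct, sel_A, sel_B)$n_contacts
    n_oracle <- oracle_contact_count(struct, "A", "B", 4.2)
    expect_equal(n_pkg, n_oracle)

    # random rotation + translation preserves the census
    theta <- stats::runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(theta), -sin(theta), 0,
                    sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
    a <- struct$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% rot
    xyz <- sweep(xyz, 2, c(10, -5, 3), "+")
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    expect_equal(count_contacts(xtal_structure(a), sel_A, sel_B)$n_contacts,
                 n_oracle)
  }
})

test_that("toy complexes carry their engineered contact count", {
  for (seed in 1:5) {
    toy <- gen_toy_complex(n_atoms = 40, n_contacts_target = 8, seed = seed)
    expect_equal(count_contacts(toy, sel_A, sel_B)$n_contacts,
                 attr(toy, "ground_truth")$n_contacts)
  }
})

test_that("hydrogen bonds follow donor-acceptor distance rules", {
  # backbone amide N (donor, chain A) vs carbonyl O (acceptor, chain B)
  near <- make_structure(c("A", "B"), c("N", "O"),
                         rbind(c(0, 0, 0), c(2.9, 0, 0)),
                         elety = c("N", "O"))
  expect_equal(detect_hbonds(near, sel_A, sel_B)$n_hbonds, 1)

  far <- make_structure(c("A", "B"), c("N", "O"),
                        rbind(c(0, 0, 0), c(3.6, 0, 0)),
                        elety = c("N", "O"))
  expect_equal(detect_hbonds(far, sel_A, sel_B)$n_hbonds, 0)

  # A-water-B triad at 2.8 / 2.9 A is one water-mediated bridge, no direct
  triad <- xtal_structure(data.frame(
    chain = c("A", "W", "B"), resno = 1:3, insert = "",
    resid = c("SER", "HOH", "THR"), elety = c("OG", "O", "OG1"),
    elesy = "O", x = c(0, 2.8, 5.7), y = 0, z = 0, o = 1, b = 0,
    is_water = c(FALSE, TRUE, FALSE), is_ion = FALSE,
    stringsAsFactors = FALSE))
  hb <- detect_hbonds(triad, sel_A, sel_B, water_mediated = TRUE)
  expect_equal(hb$n_hbonds, 0)
  expect_equal(hb$n_water_mediated, 1)
})

test_that("SASA quadrature matches single-sphere and two-sphere closed forms", {
  lone <- make_structure("A", "C", rbind(c(0, 0, 0)))
  area <- sasa(lone)
  expect_equal(area, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-2)

  # two distant chains bury nothing
  apart <- make_structure(c("A", "B"), "C",
                          rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(as.numeric(buried_area(apart, sel_A, sel_B)), 0,
               tolerance = 0.5)

  # overlapping carbon-nitrogen pair vs the analytic spherical-cap result
  pair <- make_structure(c("A", "B"), c("C", "N"),
                         rbind(c(0, 0, 0), c(3.0, 0, 0)))
  buried <- as.numeric(buried_area(pair, sel_A, sel_B))
  analytic <- oracle_two_sphere_buried(1.70, 1.55, 3.0)
  expect_equal(buried, analytic, tolerance = 1e-2 * analytic)
})

test_that("buried area is symmetric, non-negative and converges with quadrature", {
  toy <- gen_toy_complex(n_atoms = 15, n_contacts_target = 6, seed = 7)
  ab <- as.numeric(buried_area(toy, sel_A, sel_B, n_points = 480))
  ba <- as.numeric(buried_area(toy, sel_B, sel_A, n_points = 480))
  expect_equal(ab, ba, tolerance = 1e-10)
  expect_gte(ab, 0)

  finer <- as.numeric(buried_area(toy, sel_A, sel_B, n_points = 960))
  expect_lt(abs(finer - ab) / finer, 0.005 * 2 + 0.01)
})

test_that("contact shares cover the trivial subsets and a hot-spot census", {
  toy <- gen_toy_complex(n_atoms = 30, n_contacts_target = 10, seed = 4)
  contacts <- count_contacts(toy, sel_A, sel_B)
  all_res <- unique(toy$atoms[, c("chain", "resno")])
  expect_equal(contact_share(contacts, all_res), 1)
  expect_equal(contact_share(contacts, data.frame(chain = character(0),
                                                  resno = integer(0))), 0)

  # engineered hot spot: contacts touching A residues 1-2 counted by hand
  subset <- data.frame(chain = "A", resno = 1:2)
  hand <- with(contacts$pairs,
               mean(chain_a == "A" & resno_a %in% 1:2 |
                      chain_b == "A" & resno_b %in% 1:2))
  expect_equal(contact_share(contacts, subset), hand)
})
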