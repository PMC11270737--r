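test_that("dihedral computation agrees with an independent torsion oracle", {
  # independent four-atom torsion via the Gram-matrix-free atan2 form,
  # written against raw coordinates
  oracle <- function(p1, p2, p3, p4) {
    xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    c1 <- xp(b1, b2); c2 <- xp(b2, b3)
    atan2(sum(b2 * xp(c1, c2)) / sqrt(sum(b2 * b2)),
          sum(c1 * c2)) * 180 / pi
  }
  tr <- synthetic_ensemble(parse_sequence("KDAQAG", 1), two_state_model(),
                           2, seed = 16, side_chains = FALSE)
  dih <- compute_dihedrals(tr)
  at <- tr$atoms
  for (f in 1:2) {
    x <- frame_coords(tr, f)
    get <- function(rn, nm) x[at$resno == rn & at$name == nm, ]
    for (r in 2:5) {
      phi_o <- oracle(get(r - 1, "C"), get(r, "N"), get(r, "CA"),
                      get(r, "C"))
      psi_o <- oracle(get(r, "N"), get(r, "CA"), get(r, "C"),
                      get(r + 1, "N"))
      expect_lt(abs(wrap_angle(dih$phi[f, r] - phi_o)), 1e-6)
      expect_lt(abs(wrap_angle(dih$psi[f, r] - psi_o)), 1e-6)
    }
  }
  # terminal angles are undefined
  expect_true(all(is.na(dih$phi[, 1])))
  expect_true(all(is.na(dih$psi[, ncol(dih$psi)])))
})

test_that("named basins classify to their regions", {
  expect_equal(classify_region(-75, 145), "P")
  expect_equal(classify_region(-57, -47), "alpha")
  expect_equal(classify_region(120, 10), "gamma")
  expect_equal(classify_region(-150, 150), "beta")
  expect_equal(classify_region(-150, 0), "delta")
  expect_equal(classify_region(60, 30), "L")
})

test_that("classification is total and single-valued on the torus", {
  set.seed(17)
  phi <- stats::runif(5000, -180, 180)
  psi <- stats::runif(5000, -180, 180)
  lab <- classify_region(phi, psi)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% default_region_table()$label))
})

test_that("uniform angles populate regions proportionally to area", {
  # analytic areas from the default table bounds (priority-ordered,
  # computed here by interval arithmetic, independent of classify)
  areas <- c(P = 70 * 80,
             beta = 70 * (90 + 20),
             alpha = 100 * 110,
             delta = 60 * 150,
             L = 90 * 120,
             gamma = 180 * 360 - 90 * 120)
  areas <- c(areas, other = 360 * 360 - sum(areas))
  expected <- areas / sum(areas)

  set.seed(18)
  n <- 2e5
  dih <- list(phi = matrix(stats::runif(n, -180, 180), ncol = 1),
              psi = matrix(stats::runif(n, -180, 180), ncol = 1))
  pop <- region_populations(dih)
  expect_equal(sum(pop), 1)
  expect_equal(unname(pop[names(expected)]), unname(expected),
               tolerance = 0.02)
})

test_that("a single-basin walk concentrates in its region", {
  m <- markov_dihedral_model(matrix(c(-75, 145), 1), matrix(1),
                             jitter_sd = 5)
  tr <- synthetic_ensemble(parse_sequence("KDAQAG"), m, 10, seed = 19,
                           side_chains = FALSE)
  pop <- region_populations(tr)
  expect_gt(pop["P"], 0.9)
})

test_that("population differences are signed and antisymmetric", {
  m1 <- markov_dihedral_model(matrix(c(-75, 145), 1), matrix(1), 5)
  m2 <- markov_dihedral_model(matrix(c(-57, -47), 1), matrix(1), 5)
  t1 <- synthetic_ensemble(parse_sequence("KDAQA"), m1, 5, seed = 20,
                           side_chains = FALSE)
  t2 <- synthetic_ensemble(parse_sequence("KDAQA"), m2, 5, seed = 20,
                           side_chains = FALSE)
  p1 <- region_populations(t1); p2 <- region_populations(t2)
  d <- population_difference(p2, p1)
  expect_equal(unname(population_difference(p1, p1)), rep(0, 7))
  expect_equal(population_difference(p1, p2), -d)
  # planted shift: basin moved from P to alpha
  expect_lt(d["P"], -0.8)
  expect_gt(d["alpha"], 0.8)
})
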