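test_that("peptide construction round-trips its dihedrals", {
  for (ang in list(c(-75, 145), c(-57, -47), c(180, 180))) {
    tr <- build_peptide(strrep("A", 8), ang[1], ang[2])
    dih <- compute_dihedrals(tr)
    expect_lt(max(abs(wrap_angle(dih$phi[1, 2:8] - ang[1]))), 1e-3)
    expect_lt(max(abs(wrap_angle(dih$psi[1, 1:7] - ang[2]))), 1e-3)
  }
  expect_error(build_peptide("AZX", -57, -47), "unknown residue")
})

test_that("constructed backbones carry canonical bond lengths", {
  tr <- build_peptide("KDAQA", -75, 145)
  x <- frame_coords(tr)
  at <- tr$atoms
  get <- function(rn, nm) x[at$resno == rn & at$name == nm, ]
  for (rn in 1:5) {
    expect_equal(sqrt(sum((get(rn, "N") - get(rn, "CA"))^2)), 0.1458,
                 tolerance = 1e-4)
    expect_equal(sqrt(sum((get(rn, "CA") - get(rn, "C"))^2)), 0.1525,
                 tolerance = 1e-4)
  }
  for (rn in 1:4) {
    expect_equal(sqrt(sum((get(rn, "C") - get(rn + 1, "N"))^2)), 0.1329,
                 tolerance = 1e-4)
  }
})

test_that("helical dihedrals give the alpha-helical CA span", {
  tr <- build_peptide(strrep("A", 10), -57, -47)
  d <- as.numeric(pair_distance(tr, 1, 10))
  # 9 residues x ~0.15 nm helical rise, plus the CA radial offset
  expect_equal(d, 9 * 0.15, tolerance = 0.1)
  # frozen value from the canonical-geometry construction
  expect_equal(d, 1.4739, tolerance = 1e-3)
})

test_that("full extension maximizes the end-to-end distance", {
  n <- 10
  ee <- function(phi, psi)
    as.numeric(end_to_end(build_peptide(strrep("A", n), phi, psi)))
  e_ext <- ee(180, 180)
  for (ang in list(c(-57, -47), c(-75, 145), c(-120, 130), c(60, 60))) {
    expect_gt(e_ext, ee(ang[1], ang[2]))
  }
})

test_that("markov walk matches its chain's stationary and mixing behavior", {
  m <- two_state_model(p = 0.1)
  w <- markov_dihedral_walk(m, 1e5, 2, seed = 4)
  expect_equal(mean(w$states == 1), 0.5, tolerance = 0.01)

  # slowest autocorrelation decays at lambda2 = 1 - p - q = 0.8
  ac <- stats::acf(w$states, lag.max = 5, plot = FALSE)$acf[-1]
  expect_equal(ac[1], 0.8, tolerance = 0.02)
  expect_equal(log(ac[1] / ac[2]), log(1 / 0.8), tolerance = 0.05)

  # identity transition matrix freezes the state
  mid <- markov_dihedral_model(rbind(c(-75, 145), c(-57, -47)), diag(2))
  wid <- markov_dihedral_walk(mid, 100, 1, seed = 1)
  expect_equal(length(unique(wid$states)), 1L)

  expect_error(markov_dihedral_model(rbind(c(0, 0), c(0, 0)),
                                     rbind(c(0.5, 0.4), c(0.5, 0.5))),
               "sum to 1")
})

test_that("generators are seed-deterministic", {
  m <- two_state_model()
  w1 <- markov_dihedral_walk(m, 500, 3, seed = 9)
  w2 <- markov_dihedral_walk(m, 500, 3, seed = 9)
  expect_identical(w1, w2)

  f1 <- freely_jointed_chain(20, 0.38, 5, seed = 9)
  f2 <- freely_jointed_chain(20, 0.38, 5, seed = 9)
  expect_identical(f1$coords, f2$coords)

  e1 <- synthetic_ensemble(parse_sequence("KDAQ"), m, 3, seed = 9)
  e2 <- synthetic_ensemble(parse_sequence("KDAQ"), m, 3, seed = 9)
  expect_identical(e1$coords, e2$coords)
})

test_that("freely jointed chains obey the closed-form size statistics", {
  nb <- 100; b <- 0.38; nf <- 2000
  fjc <- freely_jointed_chain(nb, b, nf, seed = 21)
  r2 <- as.numeric(end_to_end(fjc))^2
  rg2 <- as.numeric(radius_of_gyration(fjc, mass_weighted = FALSE))^2
  se_r2 <- stats::sd(r2) / sqrt(nf)
  expect_lt(abs(mean(r2) - nb * b^2), 3 * se_r2)
  se_rg2 <- stats::sd(rg2) / sqrt(nf)
  expect_lt(abs(mean(rg2) - nb * b^2 / 6), 3 * se_rg2 + nb^-1 * b^2)

  one <- freely_jointed_chain(1, 0.38, 3, seed = 2)
  expect_equal(as.numeric(end_to_end(one)), rep(0.38, 3), tolerance = 1e-12)
})

test_that("pinning the first residue anchors its CA at the origin", {
  tr <- synthetic_ensemble(parse_sequence("KDAQA", 1), two_state_model(),
                           5, seed = 3, pin_first = TRUE)
  ica <- which(tr$atoms$resno == 1 & tr$atoms$name == "CA")
  expect_lt(max(abs(tr$coords[, ica, ])), 1e-12)
})

test_that("planted contact ensembles hit their occupancy exactly", {
  top <- reg_top_np()
  for (f in c(0, 0.25, 1)) {
    pl <- plant_contact_ensemble(top, c("K373", "D391"), f,
                                 n_frames = 200)
    occ <- saltbridge_occupancy(pl, top)
    expect_equal(occ["K373", "D391"], f)
  }
})
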