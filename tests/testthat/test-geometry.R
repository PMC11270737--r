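make_point_traj <- function(coords) {
  # frames x atoms x 3 helper with unit-mass pseudo atoms
  if (length(dim(coords)) == 2)
    coords <- array(coords, dim = c(1, dim(coords)))
  atoms <- data.frame(name = "CA", element = "C",
                      resno = seq_len(dim(coords)[2]), resname = "G",
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms)
}

test_that("radius of gyration matches closed forms", {
  tr <- make_point_traj(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(as.numeric(radius_of_gyration(tr)), 1.0)
  one <- make_point_traj(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.numeric(radius_of_gyration(one)), 0)
})

test_that("mass weighting shifts Rg toward heavy atoms", {
  atoms <- data.frame(name = c("O", "H"), element = c("O", "H"),
                      resno = 1:2, resname = "X",
                      stringsAsFactors = FALSE)
  tr <- trajectory(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE), atoms)
  rg_m <- as.numeric(radius_of_gyration(tr, mass_weighted = TRUE))
  rg_u <- as.numeric(radius_of_gyration(tr, mass_weighted = FALSE))
  expect_lt(rg_m, rg_u)
  expect_equal(rg_u, 1.0)
})

test_that("end-to-end and pair distances are exact on constructions", {
  tr <- make_point_traj(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(as.numeric(end_to_end(tr)), 2.0)
  expect_equal(as.numeric(pair_distance(tr, 1, 2)), 1.0)
  same <- make_point_traj(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(as.numeric(pair_distance(same, 1, 2)), 0)
})

test_that("descriptors are invariant under rigid motion", {
  set.seed(8)
  tr <- synthetic_ensemble(parse_sequence("KDAQAG"), two_state_model(),
                           3, seed = 8)
  th <- 0.9
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr2 <- tr
  for (f in 1:3)
    tr2$coords[f, , ] <- frame_coords(tr, f) %*% t(rot) + 3.3
  expect_equal(as.numeric(radius_of_gyration(tr2)),
               as.numeric(radius_of_gyration(tr)), tolerance = 1e-8)
  expect_equal(as.numeric(end_to_end(tr2)),
               as.numeric(end_to_end(tr)), tolerance = 1e-8)
  p1 <- region_populations(tr); p2 <- region_populations(tr2)
  expect_equal(p1, p2)
})

test_that("Kabsch RMSD vanishes under rigid motion and is symmetric", {
  set.seed(3)
  a <- matrix(rnorm(45), 15, 3)
  th <- 1.2
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  b <- a %*% t(rot) + c(1, -2, 0.5)[col(a)]
  expect_lt(kabsch_rmsd(a, b), 1e-8)
  expect_equal(kabsch_rmsd(a, a), 0)
  set.seed(4)
  b2 <- a + matrix(rnorm(45, sd = 0.1), 15, 3)
  expect_equal(kabsch_rmsd(a, b2), kabsch_rmsd(b2, a), tolerance = 1e-10)
})

test_that("single displaced atom yields the translation-corrected RMSD", {
  set.seed(5)
  n <- 60; d <- 0.2
  a <- matrix(rnorm(3 * n, sd = 2), n, 3)
  b <- a
  b[1, 1] <- b[1, 1] + d
  expected <- d * sqrt(n - 1) / n  # optimal translation, identity rotation
  r <- kabsch_rmsd(a, b)
  expect_lte(r, expected * (1 + 1e-9))
  expect_gt(r, 0.97 * expected)
})

test_that("degenerate point sets are rejected for superposition", {
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(kabsch_rmsd(line, line), "non-collinear")
  expect_error(kabsch_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)))
})

test_that("rolling mean uses valid windows", {
  expect_equal(rolling_mean(c(1, 2, 3), 3), 2)
  expect_equal(rolling_mean(rep(4, 10), 5), rep(4, 6))
  x <- c(5, 1, 9, 2)
  expect_equal(rolling_mean(x, 1), x)
})
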