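test_that("dihedral featurization is bounded, periodic, and drops NAs", {
  f0 <- featurize_dihedrals(list(phi = matrix(c(0, 90), 2, 1),
                                 psi = matrix(c(0, 0), 2, 1)))
  expect_equal(f0[1, ], c(1, 1, 0, 0))   # cos/sin of 0
  expect_equal(f0[2, ], c(0, 1, 1, 0))   # cos/sin of 90 degrees
  dih <- list(phi = matrix(c(NA, 0, NA, 90), 2, 2),
              psi = matrix(c(45, 45, NA, NA), 2, 2))
  f <- featurize_dihedrals(dih)
  expect_equal(ncol(f), 2L)  # only the fully defined psi column survives
  expect_true(all(f >= -1 & f <= 1))
  # periodicity
  dih2 <- list(phi = matrix(c(10, 370 - 360), 2, 1),
               psi = matrix(c(-350 + 360, 10), 2, 1))
  f2 <- featurize_dihedrals(dih2)
  expect_equal(f2[1, ], f2[2, ])
})

test_that("tICA recovers the spectral timescale of a two-state walk", {
  m <- two_state_model(p = 0.1)
  w <- markov_dihedral_walk(m, 1e5, 3, seed = 30)
  x <- featurize_dihedrals(list(phi = w$phi, psi = w$psi))
  tic <- fit_tica(x, lag = 1)
  expect_equal(tic$eigenvalues[1], 0.8, tolerance = 0.02)
  expect_equal(tic$timescales[1], -1 / log(0.8), tolerance = 0.1 * 4.48)
  # eigenvalues sorted and real
  expect_true(all(diff(tic$eigenvalues) <= 1e-12))
  expect_true(is.numeric(tic$eigenvalues))
})

test_that("implied timescale recovery holds across seeds at the 10% level", {
  for (s in c(41, 42, 43)) {
    w <- markov_dihedral_walk(two_state_model(p = 0.1), 1e5, 2, seed = s)
    x <- featurize_dihedrals(list(phi = w$phi, psi = w$psi))
    tic <- fit_tica(x, lag = 1)
    expect_lt(abs(tic$timescales[1] - (-1 / log(0.8))) / (-1 / log(0.8)),
              0.10)
  }
})

test_that("i.i.d. noise features give near-zero eigenvalues", {
  set.seed(31)
  x <- matrix(rnorm(2e4 * 4), ncol = 4)
  tic <- fit_tica(x, lag = 1)
  expect_lt(max(abs(tic$eigenvalues)), 0.1)  # O(n^-1/2) scale
})

test_that("projections are whitened and lag bounds enforced", {
  w <- markov_dihedral_walk(two_state_model(), 5000, 2, seed = 32)
  x <- featurize_dihedrals(list(phi = w$phi, psi = w$psi))
  tic <- fit_tica(x, lag = 5, n_components = 2)
  cv <- stats::cov(tic$projection)
  expect_equal(unname(diag(cv)), c(1, 1), tolerance = 0.05)
  expect_lt(abs(cv[1, 2]), 0.05)
  expect_error(fit_tica(x[1:4, ], lag = 5))
})

test_that("the free-energy surface has zero minimum and closed-form gaps", {
  set.seed(33)
  # two-Gaussian mixture with density ratio e -> Delta F of 1 kT
  p1 <- exp(1) / (1 + exp(1))
  n <- 4e4
  pick <- stats::runif(n) < p1
  x <- ifelse(pick, stats::rnorm(n, -3, 0.5), stats::rnorm(n, 3, 0.5))
  y <- stats::rnorm(n, 0, 0.5)
  fes <- free_energy_surface(cbind(x, y), grid_size = 120,
                             bandwidth = 0.5)
  expect_equal(min(fes$F), 0)
  at <- function(px, py) fes$F[which.min(abs(fes$x - px)),
                               which.min(abs(fes$y - py))]
  expect_equal(at(3, 0) - at(-3, 0), 1, tolerance = 0.15)

  # uniform samples give a flat interior
  u <- cbind(stats::runif(2e4), stats::runif(2e4))
  fu <- free_energy_surface(u, grid_size = 40, bandwidth = 0.15)
  inner <- fu$F[10:30, 10:30]
  expect_lt(max(inner) - min(inner), 0.5)
})

test_that("the surface is invariant under affine rescaling with matched bandwidth", {
  set.seed(34)
  p <- cbind(rnorm(5000), rnorm(5000))
  f1 <- free_energy_surface(p, grid_size = 50, bandwidth = 0.4)
  f2 <- free_energy_surface(p * 3, grid_size = 50, bandwidth = 1.2)
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("silhouette and Davies-Bouldin match hand-computed values", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c(1, 1, 2, 2)
  # hand evaluation: s = (b - a) / max(a, b) per point, averaged
  s_hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                   (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(silhouette_score(x, lab), s_hand, tolerance = 1e-10)
  expect_equal(silhouette_score(x, lab), 0.990, tolerance = 1e-3)
  # DB: scatter 0.05 each, centroid gap 10 -> 0.01
  expect_equal(davies_bouldin(x, lab), 0.01, tolerance = 1e-10)
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(35)
  x <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  ours <- silhouette_score(x, lab)
  ref <- mean(cluster::silhouette(lab, stats::dist(x))[, 3])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cluster scan selects k = 3 on three separated blobs", {
  set.seed(36)
  blobs <- rbind(matrix(rnorm(160, 0, 0.5), ncol = 2),
                 matrix(rnorm(160, 6, 0.5), ncol = 2),
                 cbind(rnorm(80, 0, 0.5), rnorm(80, 12, 0.5)))
  cs <- cluster_scan(blobs, ks = 2:8)
  expect_equal(cs$selected_k, 3L)
  expect_gt(max(cs$table$silhouette), 0.8)
  expect_equal(length(cs$retained), 3L)
})

test_that("sparse clusters are pruned from the retained list", {
  set.seed(37)
  pts <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
               matrix(rnorm(100, 5, 0.3), ncol = 2),
               matrix(c(20, 20, 20.1, 20.1), 2, 2))  # 2-frame outlier blob
  cs <- cluster_scan(pts, ks = 2:5, min_population = 10)
  sizes <- tabulate(cs$labels)
  expect_true(all(sizes[cs$retained] >= 10))
  expect_lt(length(cs$retained), cs$selected_k)
})

test_that("medoids minimize summed in-cluster distance (brute force)", {
  set.seed(38)
  x <- matrix(rnorm(40), 20, 2)
  cs <- cluster_scan(x, ks = 2:3, min_population = 1)
  dm <- as.matrix(stats::dist(x))
  for (c in cs$retained) {
    idx <- which(cs$labels == c)
    sums <- rowSums(dm[idx, idx, drop = FALSE])
    expect_equal(sum(dm[cs$medoids[as.character(c)], idx]), min(sums))
  }
  # singleton cluster is its own representative
  y <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2), c(50, 50))
  cs2 <- cluster_scan(y, ks = 2, min_population = 1)
  single <- which(tabulate(cs2$labels) == 1)
  expect_equal(unname(cs2$medoids[as.character(single)]),
               which(cs2$labels == single))
})

test_that("cluster labels survive a permutation round-trip", {
  set.seed(39)
  x <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 2),
             matrix(rnorm(60, 5, 0.4), ncol = 2))
  cs <- cluster_scan(x, ks = 2)
  perm <- sample(nrow(x))
  csp <- cluster_scan(x[perm, ], ks = 2)
  # undo the permutation; partitions must coincide (up to label names)
  back <- integer(nrow(x)); back[perm] <- csp$labels
  expect_equal(length(unique(paste(cs$labels, back))), 2L)
})

test_that("state paths smooth label occupancy", {
  lab <- rep(1L, 10)
  sp <- state_path(lab, window = 3)
  expect_true(all(sp[, 1] == 1))
  alt <- rep(c(1L, 2L), 10)
  sp2 <- state_path(alt, window = 2)
  expect_true(all(abs(sp2 - 0.5) < 1e-12))
  raw <- state_path(alt, window = 1)
  expect_equal(raw[, "1"], as.numeric(alt == 1))
})
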