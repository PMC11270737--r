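# Shared fixtures: small topologies, basin models, and an independent
# brute-force SASA oracle (random-direction point sampling, a different
# sphere covering than the implementation's golden spiral).

reg_top_np <- function() parse_sequence(reg_sequence(), 351)
reg_top_fp <- function() parse_sequence(reg_sequence(), 351,
                                        reg_phosphosites())
reg_top_sp <- function() parse_sequence(reg_sequence(), 351, 392L)

two_state_model <- function(p = 0.1, jitter = 10) {
  markov_dihedral_model(
    centers = rbind(c(-75, 145), c(-57, -47)),
    transition = rbind(c(1 - p, p), c(p, 1 - p)),
    jitter_sd = jitter)
}

three_basin_model <- function(stay = 0.8, jitter = 10) {
  k <- 3
  tr <- matrix((1 - stay) / (k - 1), k, k)
  diag(tr) <- stay
  markov_dihedral_model(
    centers = rbind(c(-75, 145), c(-57, -47), c(-135, 135)),
    transition = tr, jitter_sd = jitter)
}

# Brute-force SASA oracle: for each atom, sample n_pts random directions
# on its solvent sphere and count directions outside every neighbour's
# solvent sphere.
sasa_oracle <- function(coords, radii, probe = 0.14, n_pts = 1e5,
                        seed = 1) {
  set.seed(seed)
  n <- nrow(coords)
  rs <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rs[i], 2, coords[i, ], `+`)
    free <- rep(TRUE, n_pts)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      free <- free & d2 >= rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * mean(free)
  }
  out
}

# random compact atom cluster for SASA comparisons
random_cluster <- function(n_atoms = 5, spread = 0.25, seed = 1) {
  set.seed(seed)
  list(coords = matrix(stats::rnorm(3 * n_atoms, sd = spread), ncol = 3),
       radii = stats::runif(n_atoms, 0.12, 0.18))
}
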