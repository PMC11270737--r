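# Synthetic-ensemble generators.  These replace microsecond MD
# trajectories with constructions whose ground truth is known in closed
# form, so every analysis stage downstream is verifiable at desk scale.
# No sterics and no solvent: physical realism is a non-goal.

# Engh-Huber backbone geometry (nm / degrees)
.bb <- list(
  n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329, c_o = 0.1231, n_h = 0.100,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

#' Build a single-conformer peptide backbone from dihedral angles
#'
#' Constructs backbone atoms (N, H, CA, CB, C, O) with canonical
#' Engh-Huber bond lengths/angles and the supplied phi/psi dihedrals
#' (omega fixed at 180 degrees).  Recomputing dihedrals on the output
#' returns the inputs to construction precision.  Glycine gets no CB,
#' proline and the first residue no amide H.
#'
#' @param sequence One-letter sequence string or a `reg_topology`.
#' @param phi,psi Dihedrals in degrees; scalars are recycled.  The first
#'   residue's phi and last residue's psi are undefined and ignored.
#' @param first_author_number Author number of the first residue (ignored
#'   when `sequence` is a topology).
#' @return A single-frame `reg_traj`.
#' @export
#' @examples
#' helix <- build_peptide(strrep("A", 12), phi = -57, psi = -47)
build_peptide <- function(sequence, phi, psi, first_author_number = 1L) {
  if (inherits(sequence, "reg_topology")) {
    top <- sequence
    codes <- top$code
    authors <- top$author_number
  } else {
    top <- parse_sequence(sequence, first_author_number)
    codes <- top$code
    authors <- top$author_number
  }
  n <- length(codes)
  stopifnot(n >= 2L)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  # first C placed in the xy-plane using a virtual predecessor
  dummy <- c(0, -0.1, 0)
  C[1, ] <- nerf_place(dummy, N[1, ], CA[1, ], .bb$ca_c, .bb$ang_n_ca_c, 0)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         .bb$c_n, .bb$ang_ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         .bb$ca_c, .bb$ang_n_ca_c, phi[i])
  }

  name <- character(0); el <- character(0); resno <- integer(0)
  resnm <- character(0)
  xyz <- matrix(numeric(0), ncol = 3)
  add <- function(nm, e, i, p) {
    name <<- c(name, nm); el <<- c(el, e)
    resno <<- c(resno, authors[i]); resnm <<- c(resnm, codes[i])
    xyz <<- rbind(xyz, p)
  }
  for (i in seq_len(n)) {
    add("N", "N", i, N[i, ])
    if (i > 1L && codes[i] != "P") {
      # amide H at 0.1 nm along the reversed bisector of N->C(i-1), N->CA
      u <- -(.unit(C[i - 1, ] - N[i, ]) + .unit(CA[i, ] - N[i, ]))
      add("H", "H", i, N[i, ] + .unit(u) * .bb$n_h)
    }
    add("CA", "C", i, CA[i, ])
    if (codes[i] != "G") {
      b1 <- CA[i, ] - N[i, ]; b2 <- C[i, ] - CA[i, ]
      nn <- .cross(b1, b2)
      add("CB", "C", i, CA[i, ] - 0.58273431 * nn + 0.56802827 * b1 -
            0.54067466 * b2)
    }
    add("C", "C", i, C[i, ])
    # carbonyl O anti to the next amide N (or trans for the last residue)
    otor <- if (i < n) psi[i] - 180 else 0
    add("O", "O", i, nerf_place(N[i, ], CA[i, ], C[i, ],
                                .bb$c_o, .bb$ang_ca_c_o, otor))
  }
  atoms <- data.frame(name = name, element = el, resno = resno,
                      resname = resnm, stringsAsFactors = FALSE)
  trajectory(array(xyz, dim = c(1L, nrow(xyz), 3L)), atoms)
}

#' A Markov-chain model over Ramachandran basins
#'
#' @param centers Matrix `states x 2` of basin centres (phi, psi) degrees.
#' @param transition Row-stochastic `states x states` transition matrix.
#' @param jitter_sd Gaussian jitter (degrees) added to emitted angles.
#' @return A `markov_dihedral_model`.
#' @export
markov_dihedral_model <- function(centers, transition, jitter_sd = 8) {
  centers <- as.matrix(centers)
  transition <- as.matrix(transition)
  stopifnot(ncol(centers) == 2L, nrow(transition) == nrow(centers),
            ncol(transition) == nrow(centers), jitter_sd >= 0)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix rows must be non-negative and sum to 1")
  structure(list(centers = centers, transition = transition,
                 jitter_sd = jitter_sd),
            class = "markov_dihedral_model")
}

#' Sample a dihedral time series from a Markov basin model
#'
#' One hidden chain drives all residues: each frame samples a basin state,
#' and every residue emits that basin's (phi, psi) centre plus independent
#' Gaussian jitter.  Stationary state frequencies converge to the chain's
#' stationary vector and the slowest autocorrelation decays at the chain's
#' second eigenvalue, which is what the tICA stage is tested against.
#'
#' @param model A `markov_dihedral_model`.
#' @param n_frames Number of frames (>= 2).
#' @param n_residues Number of residues emitting angles.
#' @param seed Optional integer seed (generator is seed-deterministic).
#' @return List with `phi`, `psi` (`frames x residues` matrices, degrees)
#'   and `states` (integer vector per frame).
#' @export
markov_dihedral_walk <- function(model, n_frames, n_residues, seed = NULL) {
  stopifnot(inherits(model, "markov_dihedral_model"), n_frames >= 2L)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(model$centers)
  states <- integer(n_frames)
  states[1] <- sample.int(k, 1L)
  tr <- model$transition
  u <- stats::runif(n_frames - 1L)
  cum <- t(apply(tr, 1L, cumsum))
  for (f in 2:n_frames) {
    states[f] <- findInterval(u[f - 1L], cum[states[f - 1L], ]) + 1L
  }
  jit <- function() matrix(stats::rnorm(n_frames * n_residues,
                                        sd = model$jitter_sd),
                           n_frames, n_residues)
  phi <- matrix(model$centers[states, 1L], n_frames, n_residues) + jit()
  psi <- matrix(model$centers[states, 2L], n_frames, n_residues) + jit()
  list(phi = wrap_angle(phi), psi = wrap_angle(psi), states = states)
}

#' Build a multi-frame backbone ensemble from a Markov dihedral walk
#'
#' Convenience wrapper: samples [markov_dihedral_walk()] and constructs one
#' backbone conformer per frame with [build_peptide()].
#'
#' @param topology A `reg_topology` (or sequence string).
#' @param model A `markov_dihedral_model`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param pin_first If `TRUE`, translate every frame so the first
#'   residue's CA sits at the origin (emulates an N-terminal positional
#'   restraint for comparative analyses).
#' @param side_chains If `TRUE` (default), attach pseudo charged
#'   side-chain atoms with [add_charged_atoms()] so contact analyses have
#'   atoms to measure.
#' @return A `reg_traj` with the walk's `states` attached as an attribute.
#' @export
synthetic_ensemble <- function(topology, model, n_frames, seed = NULL,
                               pin_first = FALSE, side_chains = TRUE) {
  if (!inherits(topology, "reg_topology"))
    topology <- parse_sequence(topology)
  nres <- nrow(topology)
  walk <- markov_dihedral_walk(model, n_frames, nres, seed = seed)
  f1 <- build_peptide(topology, walk$phi[1L, ], walk$psi[1L, ])
  coords <- array(NA_real_, dim = c(n_frames, n_atoms(f1), 3L))
  coords[1L, , ] <- f1$coords[1L, , ]
  if (n_frames > 1L) for (f in 2:n_frames) {
    coords[f, , ] <-
      build_peptide(topology, walk$phi[f, ], walk$psi[f, ])$coords[1L, , ]
  }
  if (pin_first) {
    ica <- which(f1$atoms$resno == topology$author_number[1L] &
                   f1$atoms$name == "CA")
    for (f in seq_len(n_frames)) {
      coords[f, , ] <- sweep(coords[f, , ], 2L, coords[f, ica, ])
    }
  }
  out <- trajectory(coords, f1$atoms)
  if (side_chains) out <- add_charged_atoms(out, topology)
  attr(out, "states") <- walk$states
  out
}

#' Freely jointed chain ensemble
#'
#' Point chains of `n_bonds` i.i.d. random unit-vector bonds of fixed
#' length; closed-form size statistics (`<R^2> = N b^2`,
#' `<Rg^2> ~ N b^2 / 6`) make it the reference input for the size
#' estimators.
#'
#' @param n_bonds Number of bonds (>= 1); the chain has `n_bonds + 1`
#'   beads.
#' @param bond_length Bond length in nm (default 0.38, a CA-CA step).
#' @param n_frames Number of independent chains to draw.
#' @param seed Optional integer seed.
#' @return A `reg_traj` of point chains (one bead per pseudo-residue,
#'   atom name `CA`).
#' @export
freely_jointed_chain <- function(n_bonds, bond_length = 0.38,
                                 n_frames = 1L, seed = NULL) {
  stopifnot(n_bonds >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nb <- n_bonds
  coords <- array(NA_real_, dim = c(n_frames, nb + 1L, 3L))
  for (f in seq_len(n_frames)) {
    # isotropic unit vectors
    z <- stats::runif(nb, -1, 1)
    th <- stats::runif(nb, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    bonds <- cbind(r * cos(th), r * sin(th), z) * bond_length
    coords[f, , ] <- rbind(c(0, 0, 0), apply(bonds, 2L, cumsum))
  }
  atoms <- data.frame(name = "CA", element = "C",
                      resno = seq_len(nb + 1L), resname = "G",
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms)
}

#' Attach pseudo side-chain charged atoms to a backbone ensemble
#'
#' Places each charged group's atoms on a short stalk beyond CB (or CA for
#' glycine) so that contact criteria have concrete atoms to measure.
#' Purely geometric scaffolding for synthetic contact ensembles.
#'
#' @param traj Backbone `reg_traj` from [build_peptide()].
#' @param topology Matching `reg_topology`.
#' @return A `reg_traj` with the extra atoms appended.
#' @export
add_charged_atoms <- function(traj, topology) {
  groups <- charged_groups(topology)
  atoms <- traj$atoms
  nf <- n_frames(traj)
  new_atoms <- atoms
  extra <- list()
  for (g in seq_len(nrow(groups))) {
    rn <- groups$author_number[g]
    ica <- which(atoms$resno == rn & atoms$name == "CA")
    icb <- which(atoms$resno == rn & atoms$name == "CB")
    if (length(icb) == 0L) icb <- ica
    for (ai in seq_along(groups$atoms[[g]])) {
      extra[[length(extra) + 1L]] <- list(
        name = groups$atoms[[g]][ai],
        element = substr(groups$atoms[[g]][ai], 1L, 1L),
        resno = rn, resname = atoms$resname[ica][1L],
        ica = ica, icb = icb, k = ai)
    }
  }
  ne <- length(extra)
  coords <- array(NA_real_, dim = c(nf, nrow(atoms) + ne, 3L))
  coords[, seq_len(nrow(atoms)), ] <- traj$coords
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    for (e in seq_len(ne)) {
      it <- extra[[e]]
      dir <- x[it$icb, ] - x[it$ica, ]
      if (.vnorm(dir) < 1e-9) dir <- c(0, 0, 1)
      p <- x[it$icb, ] + .unit(dir) * (0.20 + 0.02 * (it$k - 1L))
      coords[f, nrow(atoms) + e, ] <- p
    }
  }
  add_df <- data.frame(
    name = vapply(extra, `[[`, character(1), "name"),
    element = vapply(extra, `[[`, character(1), "element"),
    resno = vapply(extra, function(z) as.integer(z$resno), integer(1)),
    resname = vapply(extra, `[[`, character(1), "resname"),
    stringsAsFactors = FALSE
  )
  trajectory(coords, rbind(atoms[, c("name", "element", "resno", "resname")],
                           add_df))
}

#' Plant charged-pair contacts at known occupancy
#'
#' Builds an extended-backbone ensemble of the topology, attaches charged
#' atoms, then places each named group pair in contact (closest charged
#' atoms at 0.7 x cutoff) in exactly `round(f * n_frames)` frames and far
#' apart (2.5 x cutoff) in all others.  Placement is deterministic, so the
#' measured occupancy equals the planted fraction exactly.
#'
#' @param topology A `reg_topology`.
#' @param pairs List of length-2 character vectors of group labels
#'   (as in [charged_groups()], e.g. `c("K373", "D391")`), or a single
#'   such vector.
#' @param occupancy Numeric vector in `[0, 1]`, one fraction per pair
#'   (recycled).
#' @param cutoff Contact cutoff in nm (default 0.35).
#' @param n_frames Number of frames.
#' @return A `reg_traj`; the planted per-pair frame masks are attached as
#'   attribute `planted` (named list of logical vectors).
#' @export
plant_contact_ensemble <- function(topology, pairs, occupancy,
                                   cutoff = 0.35, n_frames = 100L) {
  stopifnot(all(occupancy >= 0), all(occupancy <= 1))
  if (!is.list(pairs)) pairs <- list(pairs)
  occupancy <- rep_len(occupancy, length(pairs))
  base <- build_peptide(topology, 180, 180)
  base <- add_charged_atoms(base, topology)
  groups <- charged_groups(topology)
  coords <- array(rep(base$coords[1L, , ], each = n_frames),
                  dim = c(n_frames, n_atoms(base), 3L))
  planted <- list()
  for (p in seq_along(pairs)) {
    la <- pairs[[p]][1L]; lb <- pairs[[p]][2L]
    ga <- groups[groups$label == la, ]
    gb <- groups[groups$label == lb, ]
    if (nrow(ga) != 1L || nrow(gb) != 1L)
      stop("unknown group label in pair ", la, "-", lb)
    ia <- which(base$atoms$resno == ga$author_number &
                  base$atoms$name %in% ga$atoms[[1L]])
    ib <- which(base$atoms$resno == gb$author_number &
                  base$atoms$name %in% gb$atoms[[1L]])
    n_on <- round(occupancy[p] * n_frames)
    on <- seq_len(n_frames) <= n_on
    # per-pair offset direction so planted pairs do not collide
    ang <- 2 * pi * (p - 1L) / max(1L, length(pairs))
    dir <- c(cos(ang), sin(ang), 0.3); dir <- .unit(dir)
    anchor <- coords[1L, ia[1L], ]
    for (f in seq_len(n_frames)) {
      d <- if (on[f]) 0.7 * cutoff else 2.5 * cutoff
      for (k in seq_along(ib)) {
        coords[f, ib[k], ] <- anchor + dir * (d + 0.05 * (k - 1L))
      }
    }
    planted[[paste(la, lb, sep = "-")]] <- on
  }
  out <- trajectory(coords, base$atoms)
  attr(out, "planted") <- planted
  out
}
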