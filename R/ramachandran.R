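# Backbone dihedral computation and Ramachandran-region accounting.
# Regions follow the named basins of the integrated Ramachandran analysis
# (alpha, deformed-alpha, beta, PPII, left-handed, phi>0); the numeric
# bounds are configuration, not code.

# Vectorized torsion over frames: a,b,c,d are frames x 3 matrices
.torsion_frames <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  b2n <- b2 / sqrt(rowSums(b2^2))
  cr <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
              n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
              n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  wrap_angle(atan2(rowSums(cr * b2n), rowSums(n1 * n2)) * 180 / pi)
}

#' Backbone phi/psi dihedrals for every frame and residue
#'
#' @param traj A `reg_traj` with complete backbone (N, CA, C per residue).
#' @return List with `phi` and `psi`, `frames x residues` matrices in
#'   degrees wrapped to `[-180, 180)`; the first residue's phi and last
#'   residue's psi are `NA` (undefined).  Columns are named by author
#'   residue number.
#' @export
compute_dihedrals <- function(traj) {
  resnos <- sort(unique(traj$atoms$resno))
  nres <- length(resnos)
  nf <- n_frames(traj)
  idx <- function(rn, nm) {
    i <- which(traj$atoms$resno == rn & traj$atoms$name == nm)
    if (length(i) != 1L)
      stop("backbone atom ", nm, " missing in residue ", rn)
    i
  }
  iN <- vapply(resnos, idx, integer(1), nm = "N")
  iCA <- vapply(resnos, idx, integer(1), nm = "CA")
  iC <- vapply(resnos, idx, integer(1), nm = "C")
  at <- function(i) matrix(traj$coords[, i, ], ncol = 3L)
  phi <- psi <- matrix(NA_real_, nf, nres,
                       dimnames = list(NULL, resnos))
  for (r in seq_len(nres)) {
    if (r > 1L)
      phi[, r] <- .torsion_frames(at(iC[r - 1L]), at(iN[r]),
                                  at(iCA[r]), at(iC[r]))
    if (r < nres)
      psi[, r] <- .torsion_frames(at(iN[r]), at(iCA[r]),
                                  at(iC[r]), at(iN[r + 1L]))
  }
  list(phi = phi, psi = psi)
}

#' Default Ramachandran region table
#'
#' Ordered (priority-evaluated) intervals for the named basins: PPII (P),
#' beta-sheet, normal alpha-helix, deformed alpha-helix (delta),
#' left-handed helix (L), the remaining phi > 0 half-plane (gamma), and
#' `other`.  Evaluation in row order yields exactly one label for any
#' (phi, psi) in `[-180, 180)^2`.
#'
#' @return Data frame with columns `label`, `phi_min`, `phi_max`,
#'   `psi_min`, `psi_max` (list-columns allow the split beta psi range).
#' @export
default_region_table <- function() {
  structure(list(
    label = c("P", "beta", "alpha", "delta", "L", "gamma", "other"),
    phi = list(c(-110, -40), c(-180, -110), c(-120, -20), c(-180, -120),
               c(0, 90), c(0, 180), c(-180, 180)),
    psi = list(list(c(100, 180.001)), list(c(90, 180.001), c(-180, -160)),
               list(c(-80, 30)), list(c(-90, 60)), list(c(-30, 90)),
               list(c(-180, 180.001)), list(c(-180, 180.001)))
  ), class = "data.frame", row.names = 1:7)
}

.in_iv <- function(x, iv) x >= iv[1] & x < iv[2]

#' Classify dihedral pairs into Ramachandran regions
#'
#' @param phi,psi Angles in degrees (vectors of equal length; wrapped to
#'   `[-180, 180)` internally).
#' @param table Region table (default [default_region_table()]).
#' @return Character vector of region labels; `NA` inputs give `NA`.
#' @export
#' @examples
#' classify_region(-75, 145)   # "P"
#' classify_region(-57, -47)   # "alpha"
classify_region <- function(phi, psi, table = default_region_table()) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  out <- rep(NA_character_, length(phi))
  ok <- is.finite(phi) & is.finite(psi)
  for (r in seq_len(nrow(table))) {
    piv <- table$phi[[r]]
    hit <- ok & is.na(out) & .in_iv(phi, piv)
    if (!any(hit)) next
    psis <- table$psi[[r]]
    inps <- Reduce(`|`, lapply(psis, function(iv) .in_iv(psi, iv)))
    out[hit & inps] <- table$label[r]
  }
  out
}

#' Region populations of an ensemble
#'
#' Fractions of all defined (phi, psi) pairs over frames and residues
#' falling in each region; a probability vector over the table's labels.
#'
#' @param traj A `reg_traj`, or a list with `phi`/`psi` matrices as
#'   returned by [compute_dihedrals()].
#' @param table Region table.
#' @return Named numeric vector summing to 1.
#' @export
region_populations <- function(traj, table = default_region_table()) {
  dih <- if (inherits(traj, "reg_traj")) compute_dihedrals(traj) else traj
  lab <- classify_region(as.numeric(dih$phi), as.numeric(dih$psi), table)
  lab <- lab[!is.na(lab)]
  tab <- table(factor(lab, levels = table$label))
  as.numeric(tab) / length(lab) -> p
  names(p) <- table$label
  p
}

#' Signed population difference between two conditions
#'
#' @param cond,control Named population vectors from
#'   [region_populations()] (matched by label).
#' @return Named signed differences (condition minus control).
#' @export
population_difference <- function(cond, control) {
  stopifnot(setequal(names(cond), names(control)))
  cond - control[names(cond)]
}
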