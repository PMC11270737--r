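# Shrake-Rupley solvent-accessible surface area with the two accounting
# modes used for phosphorylated constructs: totals over all residues and
# totals excluding the phosphosites.

#' Per-atom Shrake-Rupley solvent-accessible surface area
#'
#' Golden-spiral test points on each atom's solvent sphere
#' (radius + probe); a point is exposed when outside every neighbour's
#' solvent sphere, and the atom's area is the exposed fraction times
#' `4 pi (r + probe)^2`.
#'
#' @param frame `atoms x 3` coordinate matrix (nm) or a single-frame
#'   `reg_traj`.
#' @param radii Per-atom van der Waals radii (nm); taken from the
#'   trajectory's atom table when `frame` is a `reg_traj`.
#' @param probe Probe radius, nm (water default 0.14).
#' @param n_points Test points per atom (default 960).
#' @return Numeric vector of per-atom areas in nm^2.
#' @export
shrake_rupley <- function(frame, radii = NULL, probe = 0.14,
                          n_points = 960L) {
  if (inherits(frame, "reg_traj")) {
    if (is.null(radii)) radii <- frame$atoms$radius
    frame <- frame_coords(frame, 1L)
  }
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  if (is.null(radii) || length(radii) != nrow(frame) || anyNA(radii))
    stop("missing van der Waals radius for atom(s) ",
         paste(which(is.null(radii) | is.na(radii)), collapse = ", "))
  .sasa_frame(frame, as.numeric(radii), probe, as.integer(n_points))
}

#' Residue-level SASA over all frames
#'
#' @param traj A `reg_traj`.
#' @param probe Probe radius (nm).
#' @param n_points Test points per atom.
#' @return A `frames x residues` matrix (nm^2) of class `sasa_matrix`,
#'   columns named by author residue number.
#' @export
residue_sasa_series <- function(traj, probe = 0.14, n_points = 960L) {
  resnos <- sort(unique(traj$atoms$resno))
  ridx <- match(traj$atoms$resno, resnos)
  nf <- n_frames(traj)
  out <- matrix(0, nf, length(resnos),
                dimnames = list(NULL, resnos))
  for (f in seq_len(nf)) {
    a <- shrake_rupley(frame_coords(traj, f), traj$atoms$radius,
                       probe, n_points)
    out[f, ] <- as.numeric(tapply(a, ridx, sum))
  }
  structure(out, class = c("sasa_matrix", "matrix"),
            probe = probe, n_points = n_points)
}

#' Total SASA series, optionally excluding residues
#'
#' The phosphosite-excluded mode controls for the extra surface the
#' phosphate groups themselves carry when comparing conditions.
#'
#' @param mat A `sasa_matrix` from [residue_sasa_series()].
#' @param exclude_sites Author residue numbers to drop from the total.
#' @return A `frame_series` of per-frame totals (nm^2).
#' @export
total_sasa <- function(mat, exclude_sites = NULL) {
  keep <- !(colnames(mat) %in% as.character(exclude_sites))
  vals <- if (any(keep)) rowSums(mat[, keep, drop = FALSE]) else
    rep(0, nrow(mat))
  frame_series(vals, if (is.null(exclude_sites)) "SASA_total"
               else "SASA_total_excl", "nm^2")
}

#' Mean per-residue SASA difference between two conditions
#'
#' Residues are aligned by author number regardless of chemical identity,
#' so a phosphosite column is compared directly against its unmodified
#' counterpart.
#'
#' @param mat_condition,mat_control `sasa_matrix` objects with matching
#'   author-number columns.
#' @return Named numeric vector of mean differences (condition minus
#'   control), nm^2 per residue.
#' @export
sasa_difference <- function(mat_condition, mat_control) {
  stopifnot(setequal(colnames(mat_condition), colnames(mat_control)))
  m1 <- colMeans(mat_condition)
  m0 <- colMeans(mat_control)[colnames(mat_condition)]
  m1 - m0
}

#' Per-residue SASA summary (mean and variance)
#'
#' @param mat A `sasa_matrix`.
#' @return Data frame with `resno`, `mean`, `variance` (nm^2).
#' @export
sasa_residue_summary <- function(mat) {
  data.frame(resno = as.integer(colnames(mat)),
             mean = as.numeric(colMeans(mat)),
             variance = as.numeric(apply(mat, 2L, stats::var)))
}
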