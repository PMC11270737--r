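# Per-frame geometric descriptors: radius of gyration, end-to-end
# distance, named pair distances, Kabsch RMSD, rolling averages.

#' Construct a labelled per-frame series
#'
#' @param values Numeric vector, one value per frame.
#' @param label Short label (e.g. `"Rg"`).
#' @param units Unit string (e.g. `"nm"`).
#' @return A numeric vector of class `frame_series` with `label` and
#'   `units` attributes.
#' @export
frame_series <- function(values, label = "series", units = "") {
  stopifnot(all(is.finite(values)))
  structure(as.numeric(values), class = "frame_series",
            label = label, units = units)
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series '%s' [%s]: %d frames, mean %.4g\n",
              attr(x, "label"), attr(x, "units"), length(x), mean(x)))
  invisible(x)
}

#' Radius of gyration per frame
#'
#' Mass-weighted (default) root-mean-square distance of atoms from the
#' centre of mass, the standard global compactness measure for disordered
#' ensembles.
#'
#' @param traj A `reg_traj`.
#' @param mass_weighted Use atomic masses (default) or equal weights.
#' @return A `frame_series` in nm.
#' @export
radius_of_gyration <- function(traj, mass_weighted = TRUE) {
  w <- if (mass_weighted) traj$atoms$mass else rep(1, n_atoms(traj))
  w <- w / sum(w)
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    cm <- colSums(x * w)
    d2 <- (x[, 1] - cm[1])^2 + (x[, 2] - cm[2])^2 + (x[, 3] - cm[3])^2
    sqrt(sum(w * d2))
  }, numeric(1))
  frame_series(out, "Rg", "nm")
}

#' End-to-end distance per frame
#'
#' Distance between reference atoms of the first and last residues
#' (default the alpha-carbons).
#'
#' @param traj A `reg_traj`.
#' @param atom Reference atom name in both terminal residues.
#' @return A `frame_series` in nm.
#' @export
end_to_end <- function(traj, atom = "CA") {
  rn <- traj$atoms$resno
  i <- which(rn == min(rn) & traj$atoms$name == atom)
  j <- which(rn == max(rn) & traj$atoms$name == atom)
  if (length(i) != 1L || length(j) != 1L)
    stop("terminal reference atom '", atom, "' not found exactly once")
  d <- sqrt(rowSums((traj$coords[, i, , drop = FALSE] -
                       traj$coords[, j, , drop = FALSE])^2, dims = 1L))
  frame_series(as.numeric(d), "EE_dist", "nm")
}

#' Distance between two named atoms per frame
#'
#' @param traj A `reg_traj`.
#' @param res_i,res_j Author residue numbers.
#' @param atom Atom name present in both residues (default `"CA"`).
#' @return A `frame_series` in nm.
#' @export
pair_distance <- function(traj, res_i, res_j, atom = "CA") {
  i <- which(traj$atoms$resno == res_i & traj$atoms$name == atom)
  j <- which(traj$atoms$resno == res_j & traj$atoms$name == atom)
  if (length(i) != 1L || length(j) != 1L)
    stop("atom '", atom, "' not found exactly once in residues ",
         res_i, "/", res_j)
  d <- sqrt(rowSums((traj$coords[, i, , drop = FALSE] -
                       traj$coords[, j, , drop = FALSE])^2, dims = 1L))
  frame_series(as.numeric(d),
               paste0("d(", res_i, "-", res_j, ":", atom, ")"), "nm")
}

#' Minimal RMSD between two frames under rigid superposition
#'
#' Optimal rotation by the Kabsch algorithm: SVD of the 3x3 weighted
#' covariance with a determinant guard against improper rotations.
#'
#' @param a,b `atoms x 3` coordinate matrices (nm) with equal atom counts,
#'   or single-frame `reg_traj` objects.
#' @param weights Optional per-atom weights (default uniform).
#' @return RMSD in nm after optimal superposition.
#' @export
kabsch_rmsd <- function(a, b, weights = NULL) {
  if (inherits(a, "reg_traj")) a <- frame_coords(a, 1L)
  if (inherits(b, "reg_traj")) b <- frame_coords(b, 1L)
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            ncol(a) == 3L)
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ac <- sweep(a, 2, colSums(a * w))
  bc <- sweep(b, 2, colSums(b * w))
  # reject degenerate point sets (rotation undetermined)
  if (n < 3L || qr(ac)$rank < 2L)
    stop("need at least 3 non-collinear atoms for superposition")
  h <- t(ac * w) %*% bc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  ar <- ac %*% t(rot)
  sqrt(sum(w * rowSums((ar - bc)^2)))
}

#' Centered rolling mean of a series
#'
#' Valid-window convolution: the output has `length(x) - window + 1`
#' values, window 1 is the identity.
#'
#' @param x Numeric vector or `frame_series`.
#' @param window Positive integer window length.
#' @return Numeric vector (a `frame_series` if the input was one).
#' @export
rolling_mean <- function(x, window) {
  stopifnot(window >= 1L, window <= length(x))
  v <- as.numeric(stats::filter(as.numeric(x), rep(1 / window, window),
                                sides = 2L))
  v <- v[!is.na(v)]
  if (inherits(x, "frame_series"))
    v <- frame_series(v, paste0(attr(x, "label"), "_roll", window),
                      attr(x, "units"))
  v
}
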