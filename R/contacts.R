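# Salt-bridge and hydrogen-bond occupancy maps between charged groups,
# condition differences, and contact-conditioned frame masks.

# atom indices of a charged-group row in a trajectory
.group_atom_idx <- function(traj, group_row) {
  idx <- which(traj$atoms$resno == group_row$author_number &
                 traj$atoms$name %in% group_row$atoms[[1L]])
  if (length(idx) == 0L)
    stop("no atoms found for group ", group_row$label)
  idx
}

#' Minimum distance between two atom groups in a frame
#'
#' @param frame `atoms x 3` coordinate matrix (nm) or a `reg_traj` (with
#'   `which_frame` selecting the frame).
#' @param idx_a,idx_b Atom index vectors of the two groups.
#' @param which_frame Frame index when `frame` is a trajectory.
#' @return Minimum over all atom pairs, nm.
#' @export
min_group_distance <- function(frame, idx_a, idx_b, which_frame = 1L) {
  if (inherits(frame, "reg_traj")) frame <- frame_coords(frame, which_frame)
  a <- frame[idx_a, , drop = FALSE]
  b <- frame[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * (a %*% t(b))
  sqrt(max(0, min(d2)))
}

# per-frame min distances for a group pair, vectorized over frames
.pair_min_series <- function(traj, idx_a, idx_b) {
  nf <- n_frames(traj)
  out <- numeric(nf)
  a <- traj$coords[, idx_a, , drop = FALSE]
  b <- traj$coords[, idx_b, , drop = FALSE]
  for (f in seq_len(nf)) {
    am <- matrix(a[f, , ], ncol = 3L)
    bm <- matrix(b[f, , ], ncol = 3L)
    d2 <- outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * (am %*% t(bm))
    out[f] <- sqrt(max(0, min(d2)))
  }
  out
}

.occupancy_matrix <- function(traj, groups, pairs_idx, cutoff, criterion,
                              mode) {
  ng <- nrow(groups)
  occ <- matrix(NA_real_, ng, ng, dimnames = list(groups$label,
                                                  groups$label))
  idx_list <- lapply(seq_len(ng), function(g)
    .group_atom_idx(traj, groups[g, ]))
  cent <- function(f, idx) colMeans(matrix(traj$coords[f, idx, ],
                                           ncol = 3L))
  for (p in seq_len(nrow(pairs_idx))) {
    i <- pairs_idx[p, 1L]; j <- pairs_idx[p, 2L]
    if (mode == "min") {
      d <- .pair_min_series(traj, idx_list[[i]], idx_list[[j]])
    } else {
      d <- vapply(seq_len(n_frames(traj)), function(f)
        .vnorm(cent(f, idx_list[[i]]) - cent(f, idx_list[[j]])),
        numeric(1))
    }
    occ[i, j] <- occ[j, i] <- mean(d < cutoff)
  }
  structure(occ, class = c("contact_occupancy", "matrix"),
            cutoff = cutoff, criterion = criterion, mode = mode)
}

#' Salt-bridge occupancy between oppositely charged groups
#'
#' Fraction of frames in which the minimum distance between the charged
#' atoms of two oppositely signed groups falls below the cutoff
#' (default 0.35 nm, i.e. 3.5 Angstrom).
#'
#' @param traj A `reg_traj` containing the groups' charged atoms.
#' @param topology A `reg_topology` (groups from [charged_groups()]).
#' @param cutoff Distance cutoff, nm.
#' @param mode `"min"` (minimum over atom pairs, default) or
#'   `"centroid"` (distance between group centroids).
#' @param include_termini Passed to [charged_groups()].
#' @return A `contact_occupancy`: symmetric group-pair matrix of
#'   fractions, `NA` for same-sign pairs and the diagonal.
#' @export
saltbridge_occupancy <- function(traj, topology, cutoff = 0.35,
                                 mode = c("min", "centroid"),
                                 include_termini = FALSE) {
  mode <- match.arg(mode)
  groups <- charged_groups(topology, include_termini = include_termini)
  ng <- nrow(groups)
  pr <- which(outer(groups$sign, groups$sign, `*`) < 0 &
                upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
  .occupancy_matrix(traj, groups, pr, cutoff, "saltbridge", mode)
}

#' Hydrogen-bond-style occupancy between arbitrary atom groups
#'
#' Distance-only criterion (default 0.30 nm) applied to every
#' donor-acceptor group pair; with identical groups and cutoff this
#' coincides with [saltbridge_occupancy()].
#'
#' @param traj A `reg_traj`.
#' @param donors,acceptors Data frames in the [charged_groups()] layout
#'   (`author_number`, `label`, list-column `atoms`).
#' @param cutoff Distance cutoff, nm.
#' @param mode `"min"` or `"centroid"`.
#' @return A `contact_occupancy` over the union of the two group sets.
#' @export
hbond_occupancy <- function(traj, donors, acceptors, cutoff = 0.30,
                            mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  donors$role <- "donor"; acceptors$role <- "acceptor"
  groups <- rbind(donors[, c("author_number", "code", "label", "sign",
                             "atoms", "role")],
                  acceptors[, c("author_number", "code", "label", "sign",
                                "atoms", "role")])
  dup <- duplicated(groups$label)
  groups <- groups[!dup, , drop = FALSE]
  nd <- match(donors$label, groups$label)
  na_ <- match(acceptors$label, groups$label)
  pr <- unique(t(apply(expand.grid(nd, na_), 1L, sort)))
  pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]
  .occupancy_matrix(traj, groups, pr, cutoff, "hbond", mode)
}

#' Signed occupancy difference between two conditions
#'
#' Pairs are aligned by group label (phosphorylated labels are matched to
#' their unmodified counterparts by author number).
#'
#' @param cond,control `contact_occupancy` matrices.
#' @return Signed matrix (condition minus control) over the shared pairs.
#' @export
occupancy_difference <- function(cond, control) {
  strip <- function(x) sub("^p", "", x)
  rc <- strip(rownames(cond)); rk <- strip(rownames(control))
  common <- intersect(rc, rk)
  ci <- match(common, rc); ki <- match(common, rk)
  out <- unclass(cond)[ci, ci] - unclass(control)[ki, ki]
  dimnames(out) <- list(common, common)
  out
}

#' Per-frame contact mask for one group pair
#'
#' @param traj A `reg_traj`.
#' @param topology A `reg_topology`.
#' @param pair Length-2 character vector of group labels.
#' @param cutoff Distance cutoff, nm.
#' @return Logical vector, one entry per frame.
#' @export
contact_mask <- function(traj, topology, pair, cutoff = 0.35) {
  groups <- charged_groups(topology)
  ga <- groups[groups$label == pair[1L], ]
  gb <- groups[groups$label == pair[2L], ]
  if (nrow(ga) != 1L || nrow(gb) != 1L)
    stop("unknown group label in ", pair[1L], "-", pair[2L])
  d <- .pair_min_series(traj, .group_atom_idx(traj, ga),
                        .group_atom_idx(traj, gb))
  d < cutoff
}

#' Mean occupancy reductions of a contact matrix
#'
#' The two reductions in use: the mean over all eligible pairs and the
#' mean over observed pairs only (occupancy > 0).
#'
#' @param occ A `contact_occupancy`.
#' @return Named numeric: `mean_all_pairs`, `mean_observed_pairs`
#'   (percent).
#' @export
occupancy_mean <- function(occ) {
  v <- occ[upper.tri(occ)]
  v <- v[!is.na(v)]
  c(mean_all_pairs = 100 * mean(v),
    mean_observed_pairs = 100 * mean(v[v > 0]))
}

#' Top pairs by absolute occupancy change
#'
#' @param diff Matrix from [occupancy_difference()].
#' @param k Number of pairs to report.
#' @return Data frame `pair`, `delta`, sorted by `|delta|`.
#' @export
top_occupancy_changes <- function(diff, k = 10L) {
  ut <- which(upper.tri(diff) & !is.na(diff), arr.ind = TRUE)
  d <- diff[ut]
  ord <- order(abs(d), decreasing = TRUE)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    pair = paste(rownames(diff)[ut[ord, 1L]],
                 colnames(diff)[ut[ord, 2L]], sep = "-"),
    delta = d[ord], stringsAsFactors = FALSE)
}
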