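# Dihedral featurization, time-lagged independent component analysis,
# free-energy surfaces and agglomerative cluster-model selection.

#' Circular dihedral features
#'
#' Maps each defined (phi, psi) angle to (cos, sin) pairs, giving a
#' periodicity-free fingerprint matrix for dimensionality reduction.
#' Undefined terminal angles (first phi, last psi) are dropped.
#'
#' @param dihedrals List with `phi`, `psi` matrices (`frames x residues`,
#'   degrees) from [compute_dihedrals()], or a `reg_traj`.
#' @return `frames x features` numeric matrix, entries in `[-1, 1]`.
#' @export
featurize_dihedrals <- function(dihedrals) {
  if (inherits(dihedrals, "reg_traj"))
    dihedrals <- compute_dihedrals(dihedrals)
  ang <- cbind(dihedrals$phi, dihedrals$psi)
  ang <- ang[, colSums(is.na(ang)) == 0L, drop = FALSE]
  rad <- ang * pi / 180
  cbind(cos(rad), sin(rad))
}

#' Fit a tICA model
#'
#' Mean-free instantaneous and time-lagged covariances with reversible
#' (symmetrized) estimation, then the generalized eigenproblem
#' `C(tau) v = lambda C(0) v` solved through a ridge-regularized Cholesky
#' whitening.  Eigenvalues are real and sorted descending; components are
#' normalized so the projected coordinates have identity instantaneous
#' covariance.
#'
#' @param features `frames x features` matrix (e.g.
#'   [featurize_dihedrals()]).
#' @param lag Lag time tau in frames.
#' @param n_components Number of components to retain (default 2).
#' @param eps Ridge added to `C(0)` (relative to its trace); 0 fails
#'   explicitly on singular `C(0)`.
#' @return A `tica_model`: eigenvalues, implied timescales
#'   (`-tau / log(lambda)`), component matrix, means, and the projected
#'   coordinates.
#' @export
fit_tica <- function(features, lag = 100L, n_components = 2L,
                     eps = 1e-8) {
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n > lag + 2L)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  a <- xc[seq_len(n - lag), , drop = FALSE]
  b <- xc[(lag + 1L):n, , drop = FALSE]
  m <- nrow(a)
  c0 <- (crossprod(a) + crossprod(b)) / (2 * m)
  ct <- (crossprod(a, b) + crossprod(b, a)) / (2 * m)
  d <- ncol(x)
  ridge <- eps * mean(diag(c0))
  l <- tryCatch(chol(c0 + diag(ridge, d)), error = function(e)
    stop("singular instantaneous covariance; increase eps"))
  linv <- backsolve(l, diag(d))
  w <- t(linv) %*% ct %*% linv
  e <- eigen((w + t(w)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- linv %*% e$vectors[, ord, drop = FALSE]
  nc <- min(n_components, d)
  comp <- vecs[, seq_len(nc), drop = FALSE]
  ts <- rep(NA_real_, length(vals))
  ok <- vals > 0 & vals < 1
  ts[ok] <- -lag / log(vals[ok])
  structure(list(
    lag = lag, means = mu, eigenvalues = vals,
    timescales = ts, components = comp,
    projection = xc %*% comp,
    c0 = c0, ctau = ct),
    class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: lag %d, top eigenvalues %s\n", x$lag,
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 4L)),
                    collapse = ", ")))
  invisible(x)
}

#' Project new features onto a fitted tICA model
#'
#' @param model A `tica_model`.
#' @param features Feature matrix with the training dimensionality.
#' @return Projected coordinates.
#' @export
tica_transform <- function(model, features) {
  sweep(as.matrix(features), 2L, model$means) %*% model$components
}

#' Free-energy surface over a 2-D projection
#'
#' 2-D Gaussian KDE of the projected samples;
#' `F = -kT log(rho / rho_max)`, so the minimum is exactly zero.
#'
#' @param projection `frames x 2` matrix (e.g. `tica$projection`).
#' @param grid_size Grid points per axis.
#' @param kT Thermal energy unit (1 = report in kT at the simulation
#'   temperature, 298 K convention).
#' @param bandwidth Optional KDE bandwidth (per axis); default
#'   `MASS::bandwidth.nrd`.
#' @return A `free_energy_surface`: `x`, `y` grid vectors and `F` matrix
#'   (kT), with `Inf` where the density underflows.
#' @export
free_energy_surface <- function(projection, grid_size = 100L, kT = 1,
                                bandwidth = NULL) {
  p <- as.matrix(projection)
  stopifnot(ncol(p) >= 2L)
  h <- if (is.null(bandwidth))
    c(MASS::bandwidth.nrd(p[, 1L]), MASS::bandwidth.nrd(p[, 2L])) else
      rep_len(bandwidth, 2L)
  kd <- MASS::kde2d(p[, 1L], p[, 2L], h = h, n = grid_size)
  f <- -kT * log(kd$z / max(kd$z))
  structure(list(x = kd$x, y = kd$y, F = f, kT = kT),
            class = "free_energy_surface")
}

# pairwise euclidean distance matrix
.dist_matrix <- function(x) as.matrix(stats::dist(x))

#' Mean silhouette score of a clustering
#'
#' @param x `n x d` data matrix or a precomputed distance matrix
#'   (class `dist`).
#' @param labels Integer cluster labels.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  dm <- if (inherits(x, "dist")) as.matrix(x) else .dist_matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette needs at least 2 clusters")
  n <- length(labels)
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1L) { s[i] <- 0; next }
    di <- dm[i, ]
    a <- sum(di[labels == li]) / (sizes[li] - 1L)
    b <- min(vapply(seq_len(k)[-li], function(c)
      mean(di[labels == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the worst ratio of summed within-cluster scatter
#' to centroid separation; lower is better.
#'
#' @param x `n x d` data matrix.
#' @param labels Integer cluster labels.
#' @return Non-negative index.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  cent <- matrix(NA_real_, k, ncol(x))
  for (c in seq_len(k))
    cent[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  scat <- vapply(seq_len(k), function(c) {
    xi <- x[labels == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cent[c, ])^2)))
  }, numeric(1))
  r <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    r[i, j] <- (scat[i] + scat[j]) /
      sqrt(sum((cent[i, ] - cent[j, ])^2))
  }
  mean(apply(r, 1L, max))
}

#' Agglomerative cluster scan with model selection
#'
#' Hierarchical (Ward by default) clustering of the projected coordinates
#' cut at each candidate k; silhouette score and Davies-Bouldin index are
#' computed per k, the selected k maximizes the silhouette (the DB
#' optimum is reported alongside), and clusters below `min_population`
#' frames are dropped from the retained list.
#'
#' @param projection `frames x d` matrix.
#' @param ks Candidate cluster counts (default 2:10).
#' @param linkage `stats::hclust` method (default `"ward.D2"`).
#' @param min_population Minimum frames for a cluster to be retained
#'   (default 10).
#' @return A `cluster_scan`: per-k table (`k`, `silhouette`, `db`),
#'   `selected_k` (max silhouette), `db_selected_k` (min DB), `labels`
#'   for the selected k, `retained` cluster ids, and `medoids` (frame
#'   index per retained cluster).
#' @export
cluster_scan <- function(projection, ks = 2:10, linkage = "ward.D2",
                         min_population = 10L) {
  x <- as.matrix(projection)
  n <- nrow(x)
  ks <- ks[ks >= 2L & ks < n]
  stopifnot(length(ks) > 0L)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = linkage)
  dm <- as.matrix(d)
  tab <- data.frame(k = ks, silhouette = NA_real_, db = NA_real_)
  lab_by_k <- list()
  for (i in seq_along(ks)) {
    lab <- stats::cutree(hc, k = ks[i])
    lab_by_k[[i]] <- lab
    tab$silhouette[i] <- silhouette_score(d, lab)
    tab$db[i] <- davies_bouldin(x, lab)
  }
  sel <- which.max(tab$silhouette)
  labels <- lab_by_k[[sel]]
  sizes <- tabulate(labels)
  retained <- which(sizes >= min_population)
  medoids <- vapply(retained, function(c) {
    idx <- which(labels == c)
    idx[which.min(rowSums(dm[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(
    table = tab,
    selected_k = ks[sel],
    db_selected_k = ks[which.min(tab$db)],
    labels = labels,
    retained = retained,
    medoids = stats::setNames(medoids, retained),
    linkage = linkage,
    min_population = min_population),
    class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("cluster_scan: selected k=%d (silhouette %.3f), DB optimum k=%d; %d retained cluster(s)\n",
              x$selected_k,
              x$table$silhouette[x$table$k == x$selected_k],
              x$db_selected_k, length(x$retained)))
  invisible(x)
}

#' Representative frame (medoid) per retained cluster
#'
#' The medoid minimizes the summed in-cluster distance in projected
#' space; ties break to the lowest frame index.
#'
#' @param scan A `cluster_scan`.
#' @param traj Optional `reg_traj`; if given, returns the medoid frames
#'   as a trajectory instead of indices.
#' @return Named integer vector of frame indices (or a `reg_traj`).
#' @export
representatives <- function(scan, traj = NULL) {
  if (is.null(traj)) return(scan$medoids)
  select_atoms(traj, frames = as.integer(scan$medoids))
}

#' Smoothed cluster-occupancy series
#'
#' Rolling per-label occupancy of the cluster assignment over time;
#' window 1 returns the raw one-hot assignment.
#'
#' @param labels Integer cluster labels per frame.
#' @param window Rolling window length.
#' @return `windows x clusters` matrix of occupancies (rows sum to 1).
#' @export
state_path <- function(labels, window = 1L) {
  labels <- as.integer(labels)
  lev <- sort(unique(labels))
  onehot <- outer(labels, lev, `==`) * 1
  colnames(onehot) <- lev
  if (window == 1L) return(onehot)
  out <- apply(onehot, 2L, function(col)
    as.numeric(stats::filter(col, rep(1 / window, window), sides = 2L)))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  colnames(out) <- lev
  out
}
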