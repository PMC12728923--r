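# Conformational clustering: GROMOS neighbour-count clustering of
# structures under a pairwise-RMSD cutoff, and density-peak clustering in
# collective-variable feature space.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares fits `Y` onto `X` with a proper rotation (determinant +1;
#' mirror images are never produced).
#'
#' @param X,Y `n x 3` coordinate matrices, `n >= 3`, not collinear.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (nm) and `yfit` (= `Y %*% rotation + translation`, the fitted copy).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3 || ncol(Y) != 3)
    stop("kabsch_superpose: X and Y must be matching n x 3 matrices")
  if (nrow(X) < 3) stop("kabsch_superpose: need at least 3 particles")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Yc, Xc))   # 3x3
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("kabsch_superpose: degenerate (collinear) particle set")
  s <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, s))
  R <- sv$u %*% D %*% t(sv$v)
  translation <- cx - as.numeric(cy %*% R)
  yfit <- sweep(Y %*% R, 2, translation, "+")
  rmsd <- sqrt(mean(rowSums((yfit - X)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd, yfit = yfit)
}

#' Cluster assignment container
#' @param labels Per-item integer labels (1-based; -1 = unassigned).
#' @param representatives Representative item per cluster (by label order).
#' @param parameters List of parameters used.
#' @return An object of class `cluster_assignment` with `labels`, `sizes`
#'   (descending, names = cluster label), `representatives`, `parameters`.
#' @keywords internal
new_cluster_assignment <- function(labels, representatives, parameters) {
  tab <- table(labels[labels > 0])
  sizes <- sort(as.integer(tab), decreasing = TRUE)
  names(sizes) <- names(tab)[order(as.integer(tab), decreasing = TRUE)]
  structure(list(labels = labels, sizes = sizes,
                 representatives = representatives,
                 parameters = parameters),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d clusters over %d items\n",
              length(x$sizes), length(x$labels)))
  cat("  sizes:", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (length(x$sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' GROMOS (neighbour-count) clustering of trajectory frames
#'
#' Every frame is superposed on a common reference (frame 1) over the fit
#' selection, pairwise RMSD is computed over the measure selection, and
#' the greedy neighbour-count algorithm runs: repeatedly take the
#' unassigned frame with the most unassigned neighbours within the cutoff
#' as a cluster centre (ties broken by lowest frame index), assign it and
#' its neighbours, remove them, repeat.  Cluster labels are ordered by
#' discovery; the representative of a cluster is its centre.
#'
#' Superposing on a receptor fit selection (rather than mutually fitting
#' every pair) makes the RMSD measure the *relative pose* of the ligand on
#' the receptor, which is what separates binding orientations of a
#' two-chain complex.  Pairwise mutual fitting is available via
#' `mutual_fit = TRUE` for single-chain use.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param fit_sel Region used for superposition (e.g. the receptor core).
#' @param rmsd_sel Region over which RMSD is measured (e.g. the ligand).
#' @param cutoff RMSD cutoff in nm (> 0).
#' @param mutual_fit Superpose every frame pair before the pair's RMSD.
#' @return A `cluster_assignment`.
#' @export
gromos_cluster <- function(traj, regions, fit_sel, rmsd_sel, cutoff,
                           mutual_fit = FALSE) {
  if (cutoff <= 0) stop("gromos_cluster: cutoff must be > 0")
  ifit <- region_indices(traj, regions, fit_sel)
  imeas <- region_indices(traj, regions, rmsd_sel)
  nf <- n_frames(traj)
  meas <- vector("list", nf)
  ref <- frame_coords(traj, 1)[ifit, , drop = FALSE]
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(ref, xyz[ifit, , drop = FALSE])
    meas[[f]] <- sweep(xyz[imeas, , drop = FALSE] %*% fit$rotation, 2,
                       fit$translation, "+")
  }
  rmsd_mat <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    r <- if (mutual_fit) kabsch_superpose(meas[[i]], meas[[j]])$rmsd
    else sqrt(mean(rowSums((meas[[i]] - meas[[j]])^2)))
    rmsd_mat[i, j] <- r; rmsd_mat[j, i] <- r
  }
  gromos_from_rmsd(rmsd_mat, cutoff,
                   parameters = list(cutoff = cutoff, fit_sel = fit_sel,
                                     rmsd_sel = rmsd_sel,
                                     mutual_fit = mutual_fit))
}

#' GROMOS clustering from a precomputed distance matrix
#'
#' @param rmsd_mat Symmetric pairwise distance matrix.
#' @param cutoff Neighbour cutoff (same units as the matrix).
#' @param parameters Metadata stored in the result.
#' @return A `cluster_assignment`.
#' @export
gromos_from_rmsd <- function(rmsd_mat, cutoff, parameters = list()) {
  nf <- nrow(rmsd_mat)
  adj <- rmsd_mat < cutoff
  diag(adj) <- FALSE
  labels <- integer(nf)
  reps <- integer(0)
  alive <- rep(TRUE, nf)
  id <- 0L
  while (any(alive)) {
    counts <- rowSums(adj[, alive, drop = FALSE])
    counts[!alive] <- -1L
    centre <- which.max(counts)          # ties -> lowest index
    members <- which(alive & (adj[centre, ] | seq_len(nf) == centre))
    id <- id + 1L
    labels[members] <- id
    reps[id] <- centre
    alive[members] <- FALSE
  }
  new_cluster_assignment(labels, reps,
                         c(parameters, list(algorithm = "gromos")))
}

#' Density-peak clustering in feature space
#'
#' Features are standardised per column; the local density of item `i` is
#' a Gaussian kernel sum `rho_i = sum_j exp(-(d_ij/d_c)^2)` with `d_c` the
#' `dc_percentile` of all pairwise distances; `delta_i` is the distance to
#' the nearest item of higher density (for the global density maximum, the
#' largest pairwise distance).  Cluster centres are the decision-graph
#' outliers: by default the items before the largest multiplicative gap
#' in the sorted product `gamma = rho * delta` (examining at most
#' `max_centers` candidates), which picks the centre count automatically
#' and is robust to blobs of unequal density.  Explicit
#' `rho_percentile`/`delta_percentile` thresholds (centre iff above both)
#' can be supplied instead.  Every non-centre joins the cluster of its
#' nearest higher-density neighbour, in decreasing density order.
#'
#' @param features Numeric matrix (items x features), >= 10 items.
#' @param dc_percentile Kernel-scale percentile of pairwise distances
#'   (default 2).
#' @param rho_percentile,delta_percentile Optional centre thresholds
#'   (percentiles of `rho` and `delta`); when both are given they replace
#'   the gamma-gap rule.
#' @param max_centers Largest centre count the gamma-gap rule considers.
#' @return A `cluster_assignment` with `rho` and `delta` attached in
#'   `parameters`.
#' @export
density_peak_cluster <- function(features, dc_percentile = 2,
                                 rho_percentile = NULL,
                                 delta_percentile = NULL,
                                 max_centers = 20) {
  X <- as.matrix(features)
  if (nrow(X) < 10) stop("density_peak_cluster: need >= 10 items")
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  n <- nrow(X)
  dmat <- as.matrix(stats::dist(X))
  dvec <- dmat[lower.tri(dmat)]
  if (all(dvec == 0))                       # all items identical
    return(new_cluster_assignment(rep(1L, n), 1L,
                                  list(algorithm = "density_peak",
                                       degenerate = TRUE)))
  dc <- stats::quantile(dvec[dvec > 0], dc_percentile / 100, names = FALSE)
  rho <- rowSums(exp(-(dmat / dc)^2)) - 1   # exclude self
  ord <- order(rho, decreasing = TRUE)
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(dmat)
  nn_higher[ord[1]] <- ord[1]
  for (k in 2:n) {
    i <- ord[k]
    higher <- ord[1:(k - 1)]
    j <- higher[which.min(dmat[i, higher])]
    delta[i] <- dmat[i, j]
    nn_higher[i] <- j
  }
  if (!is.null(rho_percentile) && !is.null(delta_percentile)) {
    centres <- which(rho >= stats::quantile(rho, rho_percentile / 100) &
                       delta >= stats::quantile(delta, delta_percentile / 100))
  } else {
    gam <- rho * delta
    gord <- order(gam, decreasing = TRUE)
    m <- min(max_centers, n - 1L)
    gs <- gam[gord[1:(m + 1L)]] + 1e-12
    k <- which.max(gs[1:m] / gs[2:(m + 1L)])
    centres <- gord[1:k]
  }
  if (length(centres) == 0L) centres <- ord[1]
  labels <- integer(n)
  labels[centres] <- seq_along(centres)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (labels[i] == 0L) labels[i] <- labels[nn_higher[i]]
  }
  new_cluster_assignment(labels, centres,
                         list(algorithm = "density_peak", dc = dc,
                              rho = rho, delta = delta,
                              dc_percentile = dc_percentile,
                              rho_percentile = rho_percentile,
                              delta_percentile = delta_percentile))
}
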