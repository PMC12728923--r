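# Ensemble comparison in PCA space: global per-frame descriptors, a
# pooled 2-component embedding, centroid distances and Jensen-Shannon
# divergence between ensembles.

#' Global per-frame binding descriptors
#'
#' The three global descriptors summarising a binding conformation:
#' (i) the receptor-ligand centre-of-mass distance (nm), (ii) the total
#' number of intermolecular residue contacts, (iii) the inter-chain
#' orientation angle (degrees, from N-to-C terminal axis vectors).
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()] defining `receptor_sel`, `ligand_sel`
#'   and the four axis anchors.
#' @param receptor_sel,ligand_sel COM selections (default `"RECEPTOR"`,
#'   `"LIGAND"`).
#' @param anchors Character vector of 4 region names:
#'   receptor N/C anchors then ligand N/C anchors.
#' @param cutoff Contact cutoff (nm) for the total-contacts descriptor.
#' @param label Ensemble label.
#' @return An object of class `descriptor_ensemble`: data frame
#'   `descriptors` (`com_distance`, `total_contacts`,
#'   `orientation_angle`), `label`, and (after [pca_embed()]) the PC
#'   `projection`.
#' @export
compute_descriptors <- function(traj, regions, receptor_sel = "RECEPTOR",
                                ligand_sel = "LIGAND",
                                anchors = c("NANCH_R", "CANCH_R",
                                            "NANCH_L", "CANCH_L"),
                                cutoff = 0.5, label = "ensemble") {
  d <- com_distance(traj, regions, receptor_sel, ligand_sel)
  contacts <- contact_trace(traj, regions, ligand_sel, receptor_sel,
                            cutoff = cutoff)
  ang <- orientation_angle(traj, regions, anchors[1], anchors[2],
                           anchors[3], anchors[4])
  structure(list(label = label,
                 descriptors = data.frame(
                   com_distance = as.numeric(d),
                   total_contacts = as.numeric(contacts),
                   orientation_angle = as.numeric(ang)),
                 projection = NULL),
            class = "descriptor_ensemble")
}

#' @export
print.descriptor_ensemble <- function(x, ...) {
  cat(sprintf("descriptor_ensemble '%s': %d frames%s\n", x$label,
              nrow(x$descriptors),
              if (is.null(x$projection)) "" else " (embedded)"))
  invisible(x)
}

#' Embed descriptor ensembles in a common 2D PCA space
#'
#' All frames of all ensembles are pooled, each feature is standardised
#' with the pooled mean and SD (zero-variance features are dropped with a
#' warning), the covariance matrix is eigendecomposed, and frames are
#' projected on the top two components.  The sign of each component is
#' fixed deterministically: the loading of largest magnitude is made
#' positive.
#'
#' @param ensembles List of [compute_descriptors()] results (>= 2 frames
#'   pooled).
#' @return List with `ensembles` (each with its `projection` filled),
#'   `loadings` (features x 2), `explained_variance` (fraction per
#'   retained component), `center`, `scale`.
#' @export
pca_embed <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  X <- do.call(rbind, lapply(ensembles, function(e) e$descriptors))
  if (nrow(X) < 2) stop("pca_embed: need at least 2 frames pooled")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  drop <- sdv == 0
  if (any(drop)) {
    warning("pca_embed: dropping zero-variance feature(s): ",
            paste(names(X)[drop], collapse = ", "))
    if (sum(!drop) < 2)
      stop("pca_embed: fewer than 2 informative features")
  }
  Z <- sweep(sweep(as.matrix(X[, !drop, drop = FALSE]), 2, mu[!drop]), 2,
             sdv[!drop], "/")
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  W <- eg$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {                      # deterministic sign convention
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  rownames(W) <- colnames(X)[!drop]
  colnames(W) <- c("PC1", "PC2")
  offsets <- c(0, cumsum(vapply(ensembles, function(e)
    nrow(e$descriptors), numeric(1))))
  proj <- Z %*% W
  for (i in seq_along(ensembles))
    ensembles[[i]]$projection <-
      proj[(offsets[i] + 1):offsets[i + 1], , drop = FALSE]
  list(ensembles = ensembles, loadings = W,
       explained_variance = eg$values[1:2] / sum(eg$values),
       center = mu[!drop], scale = sdv[!drop])
}

#' Euclidean distance between ensemble centroids in PC space
#'
#' @param emb_a,emb_b Embedded ensembles (with `projection`), or plain
#'   projection matrices.
#' @return Scalar distance between the mean PC vectors.
#' @export
centroid_distance <- function(emb_a, emb_b) {
  pa <- if (inherits(emb_a, "descriptor_ensemble")) emb_a$projection else emb_a
  pb <- if (inherits(emb_b, "descriptor_ensemble")) emb_b$projection else emb_b
  if (is.null(pa) || nrow(pa) == 0 || is.null(pb) || nrow(pb) == 0)
    stop("centroid_distance: empty or unembedded ensemble")
  sqrt(sum((colMeans(pa) - colMeans(pb))^2))
}

#' Jensen-Shannon divergence between two ensembles in PC space
#'
#' Both ensembles are histogrammed on shared 2D bin edges spanning their
#' pooled range; `JSD = KL(P||M)/2 + KL(Q||M)/2` with `M = (P + Q)/2`,
#' logarithm base 2 so the value lies in `[0, 1]` (0 for identical
#' histograms, 1 for disjoint supports).  Empty bins contribute zero by
#' the `0 log 0 = 0` convention.
#'
#' @param emb_a,emb_b Embedded ensembles or projection matrices.
#' @param bins 2D histogram bin counts (default `c(30, 30)`).
#' @return Scalar in `[0, 1]`.
#' @export
jsd <- function(emb_a, emb_b, bins = c(30, 30)) {
  pa <- if (inherits(emb_a, "descriptor_ensemble")) emb_a$projection else emb_a
  pb <- if (inherits(emb_b, "descriptor_ensemble")) emb_b$projection else emb_b
  if (is.null(pa) || nrow(pa) == 0 || is.null(pb) || nrow(pb) == 0)
    stop("jsd: empty or unembedded ensemble")
  pooled <- rbind(pa, pb)
  mk_edges <- function(v, nb) {
    r <- range(v)
    pad <- max(diff(r), 1e-12) * 1e-6
    seq(r[1] - pad, r[2] + pad, length.out = nb + 1)
  }
  ex <- mk_edges(pooled[, 1], bins[1])
  ey <- mk_edges(pooled[, 2], bins[2])
  hist2 <- function(m) {
    ix <- findInterval(m[, 1], ex, rightmost.closed = TRUE)
    iy <- findInterval(m[, 2], ey, rightmost.closed = TRUE)
    tab <- table(factor(ix, levels = seq_len(bins[1])),
                 factor(iy, levels = seq_len(bins[2])))
    as.numeric(tab) / nrow(m)
  }
  jsd_hist(hist2(pa), hist2(pb))
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' @param p,q Non-negative vectors of equal length; normalised internally.
#' @return Scalar in `[0, 1]` (base-2 logarithm).
#' @export
jsd_hist <- function(p, q) {
  if (length(p) != length(q)) stop("jsd_hist: length mismatch")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}
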