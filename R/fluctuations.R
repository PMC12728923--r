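# RMSD with subset fitting, per-residue RMSF, and centre-of-mass tracking
# of the ligand core.

#' RMSD series with subset fitting
#'
#' Per frame: superpose the frame on the reference over the fit selection
#' (e.g. the innermost residues of a helix, declared as a region), then
#' measure RMSD over the measure selection.  The reference is either the
#' first frame or the mean structure (computed after aligning all frames
#' to frame 1 over the fit selection).
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param fit_sel Region used for superposition.
#' @param measure_sel Region over which RMSD is measured (defaults to
#'   `fit_sel`).
#' @param reference `"first_frame"` (default) or `"mean_structure"`.
#' @return A [cv_series()] in nm.
#' @export
rmsd_series <- function(traj, regions, fit_sel, measure_sel = fit_sel,
                        reference = c("first_frame", "mean_structure")) {
  reference <- match.arg(reference)
  ifit <- region_indices(traj, regions, fit_sel)
  imeas <- region_indices(traj, regions, measure_sel)
  nf <- n_frames(traj)
  if (reference == "first_frame") {
    ref_fit <- frame_coords(traj, 1)[ifit, , drop = FALSE]
    ref_meas <- frame_coords(traj, 1)[imeas, , drop = FALSE]
  } else {
    aligned <- align_frames(traj, ifit)
    mean_all <- apply(aligned, c(1, 2), mean)
    ref_fit <- mean_all[ifit, , drop = FALSE]
    ref_meas <- mean_all[imeas, , drop = FALSE]
  }
  vals <- vapply(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(ref_fit, xyz[ifit, , drop = FALSE])
    moved <- sweep(xyz[imeas, , drop = FALSE] %*% fit$rotation, 2,
                   fit$translation, "+")
    sqrt(mean(rowSums((moved - ref_meas)^2)))
  }, numeric(1))
  cv_series(vals, name = paste0("rmsd(", measure_sel, "|fit ", fit_sel, ")"),
            unit = "nm", time = traj$time)
}

# Align all frames to frame 1 over the given fit indices; returns the
# full coordinate array.
align_frames <- function(traj, ifit) {
  nf <- n_frames(traj)
  out <- traj$coords
  ref <- frame_coords(traj, 1)[ifit, , drop = FALSE]
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    fit <- kabsch_superpose(ref, xyz[ifit, , drop = FALSE])
    out[, , f] <- sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Two-pass procedure: all frames are superposed on the fit selection to
#' frame 1, the mean structure is computed, frames are re-superposed to
#' the mean, and `RMSF_i = sqrt(<|x_i - xbar_i|^2>)` per particle; the
#' per-residue value averages that over the residue's (backbone)
#' particles.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param regions A [region_set()].
#' @param sel Region whose residues are reported.
#' @param fit_sel Region used for superposition (defaults to `sel`).
#' @return Data frame with `chain`, `residue` and `rmsf` (nm).
#' @export
rmsf <- function(traj, regions, sel, fit_sel = sel) {
  if (n_frames(traj) < 2) stop("rmsf: need at least 2 frames")
  ifit <- region_indices(traj, regions, fit_sel)
  isel <- region_indices(traj, regions, sel)
  aligned <- align_frames(traj, ifit)
  mean1 <- apply(aligned[, , , drop = FALSE], c(1, 2), mean)
  # second pass: re-superpose every frame onto the mean over fit_sel
  nf <- n_frames(traj)
  ref <- mean1[ifit, , drop = FALSE]
  dev2 <- matrix(0, length(isel), nf)
  realigned <- aligned
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(ref, aligned[ifit, , f])
    realigned[, , f] <- sweep(aligned[, , f] %*% fit$rotation, 2,
                              fit$translation, "+")
  }
  xbar <- apply(realigned, c(1, 2), mean)
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((realigned[isel, , f] - xbar[isel, ])^2)
  per_particle <- sqrt(rowMeans(dev2))
  p <- traj$topology$particles[isel, ]
  agg <- stats::aggregate(per_particle,
                          by = list(chain = p$chain_id,
                                    residue = p$residue_index), FUN = mean)
  names(agg)[3] <- "rmsf"
  agg[order(agg$chain, agg$residue), , drop = FALSE]
}

#' Track the centre of mass of a core selection
#'
#' Geometric centre of the core selection at `n_samples` uniformly spaced
#' eligible frames (all frames, or only bound frames when a mask is
#' given) — the dot-cloud picture of where the ligand sits on the
#' receptor.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param core_sel Region name of the tracked core.
#' @param n_samples Number of uniformly spaced samples (default 150).
#' @param bound Optional logical per-frame mask restricting eligibility.
#' @return Matrix `n x 3` of centre positions (nm) with the sampled frame
#'   indices as rownames; fewer rows than `n_samples` (with a warning) if
#'   not enough eligible frames.
#' @export
com_track <- function(traj, regions, core_sel, n_samples = 150,
                      bound = NULL) {
  idx <- region_indices(traj, regions, core_sel)
  eligible <- seq_len(n_frames(traj))
  if (!is.null(bound)) {
    if (length(bound) != n_frames(traj))
      stop("com_track: bound mask length != frame count")
    eligible <- eligible[bound]
  }
  if (length(eligible) == 0L) {
    warning("com_track: no eligible frames")
    return(matrix(numeric(0), 0, 3))
  }
  if (length(eligible) < n_samples) {
    warning("com_track: only ", length(eligible),
            " eligible frames; taking all")
    take <- eligible
  } else {
    take <- eligible[unique(round(seq(1, length(eligible),
                                      length.out = n_samples)))]
  }
  out <- t(vapply(take, function(f)
    colMeans(frame_coords(traj, f)[idx, , drop = FALSE]), numeric(3)))
  rownames(out) <- take
  out
}
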