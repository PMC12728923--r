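# Residue-residue contact-frequency maps, thresholded hotspot maps, and
# difference maps between conformational ensembles.
#
# Conventions: strict inequalities throughout — a pair is in contact iff
# its minimum interparticle distance is < cutoff, and a frequency survives
# thresholding iff it is > tau.

#' Residue contact-frequency map between two chains
#'
#' For every frame and residue pair (receptor x ligand), a contact is
#' registered iff any interparticle distance is strictly below the cutoff
#' (0.4 nm is the usual atomistic choice, 0.5 nm the coarse-grained one).
#' Frequencies divide contact-frame counts by either all frames or only
#' bound frames.
#'
#' @param traj A [trajectory()].
#' @param receptor_chain,ligand_chain Chain identifiers.
#' @param cutoff Contact cutoff in nm.
#' @param denominator `"all_frames"` (default) or `"bound_frames"`.
#' @param bound Logical per-frame bound mask, required for
#'   `denominator = "bound_frames"` (e.g. `classify_bound(...)$bound`).
#' @return An object of class `contact_map`: `receptor_res`, `ligand_res`
#'   (residue indices), `mat` (fractions in `[0, 1]`, rows = receptor
#'   residues), `cutoff`, `n_frames`, `denominator`.
#' @export
contact_frequency <- function(traj, receptor_chain = "R",
                              ligand_chain = "L", cutoff = 0.5,
                              denominator = c("all_frames", "bound_frames"),
                              bound = NULL) {
  denominator <- match.arg(denominator)
  ia <- chain_indices(traj, receptor_chain)
  ib <- chain_indices(traj, ligand_chain)
  p <- traj$topology$particles
  res_a <- unique(p$residue_index[ia])
  res_b <- unique(p$residue_index[ib])
  ga <- match(p$residue_index[ia], res_a)
  gb <- match(p$residue_index[ib], res_b)
  frames <- seq_len(n_frames(traj))
  if (denominator == "bound_frames") {
    if (is.null(bound)) stop("contact_frequency: bound mask required")
    if (length(bound) != n_frames(traj))
      stop("contact_frequency: bound mask length != frame count")
    frames <- frames[bound]
    if (length(frames) == 0L)
      stop("contact_frequency: no bound frames in denominator")
  }
  acc <- matrix(0, length(res_a), length(res_b))
  one_per_res <- length(ga) == length(res_a) && length(gb) == length(res_b)
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    d <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    contact <- d < cutoff
    if (one_per_res) {                 # 1 particle per residue: direct
      acc <- acc + contact
    } else if (any(contact)) {
      hit <- unique(cbind(ga[row(d)[contact]], gb[col(d)[contact]]))
      acc[hit] <- acc[hit] + 1
    }
  }
  structure(list(receptor_res = res_a, ligand_res = res_b,
                 mat = acc / length(frames), cutoff = cutoff,
                 n_frames = length(frames), denominator = denominator),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map: %d x %d residues, cutoff %.3g nm, %d frames (%s), %d nonzero\n",
    length(x$receptor_res), length(x$ligand_res), x$cutoff, x$n_frames,
    x$denominator, sum(x$mat > 0)))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  graphics::image(x$receptor_res, x$ligand_res, x$mat,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "receptor residue", ylab = "ligand residue",
                  main = sprintf("contact frequency (cutoff %.2g nm)",
                                 x$cutoff), ...)
  invisible(x)
}

#' Threshold a contact map
#'
#' Zeroes every frequency `<= tau`; survivors are unchanged.
#'
#' @param map A [contact_frequency()] result.
#' @param tau Threshold in `[0, 1)` (e.g. 0.10 or 0.25).
#' @return The map with sub-threshold entries zeroed; the survivor count
#'   is attached as `n_surviving`.
#' @export
threshold_map <- function(map, tau) {
  if (tau < 0 || tau >= 1) stop("threshold_map: tau must be in [0, 1)")
  out <- map
  out$mat[out$mat <= tau] <- 0
  out$tau <- tau
  out$n_surviving <- sum(out$mat > 0)
  out
}

#' Difference map between two contact maps
#'
#' Both maps are thresholded at `tau`, then subtracted
#' (`delta = A - B`).  Positive entries mark contacts enriched in the
#' first ensemble, negative entries contacts enriched in the second.
#'
#' @param map_a,map_b [contact_frequency()] results over identical residue
#'   axes.
#' @param tau Threshold applied to both maps before subtraction.
#' @return An object of class `delta_contact_map` with the signed `mat`.
#' @export
delta_map <- function(map_a, map_b, tau = 0.10) {
  if (!identical(map_a$receptor_res, map_b$receptor_res) ||
      !identical(map_a$ligand_res, map_b$ligand_res))
    stop("delta_map: residue axes differ")
  ta <- threshold_map(map_a, tau)
  tb <- threshold_map(map_b, tau)
  structure(list(receptor_res = map_a$receptor_res,
                 ligand_res = map_a$ligand_res,
                 mat = ta$mat - tb$mat, tau = tau),
            class = "delta_contact_map")
}

#' @export
print.delta_contact_map <- function(x, ...) {
  cat(sprintf(
    "delta_contact_map: %d enriched in A, %d in B (tau %.2g)\n",
    sum(x$mat > 0), sum(x$mat < 0), x$tau))
  invisible(x)
}

#' Hotspot residues of a contact map
#'
#' Residues participating in at least one contact surviving the
#' threshold, per chain, sorted by their peak surviving frequency.
#'
#' @param map A [contact_frequency()] result.
#' @param tau Persistence threshold in `[0, 1)`.
#' @return List with data frames `receptor` and `ligand` (`residue`,
#'   `peak_frequency`), each sorted by decreasing peak frequency.
#' @export
hotspots <- function(map, tau = 0.10) {
  m <- threshold_map(map, tau)$mat
  mk <- function(res, peak) {
    keep <- peak > 0
    df <- data.frame(residue = res[keep], peak_frequency = peak[keep])
    df[order(-df$peak_frequency, df$residue), , drop = FALSE]
  }
  list(receptor = mk(map$receptor_res, apply(m, 1, max)),
       ligand = mk(map$ligand_res, apply(m, 2, max)))
}
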