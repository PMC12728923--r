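# Collective variables: the per-frame scalars that binding landscapes and
# contact traces are built from.  All distances are in nm.

#' Rational switching function parameters
#'
#' Parameters of the smooth contact indicator
#' \deqn{s(r) = \frac{1 - x^n}{1 - x^m}, \quad x = (r - d_0)/r_0,}
#' the standard PLUMED-style rational switch.  Defaults follow the common
#' coarse-grained choice: `d0 = 0` nm, switching distance `r0 = 0.9` nm,
#' exponents `n = 6`, `m = 12`.
#'
#' @param d0 Reference distance offset (nm).
#' @param r0 Switching distance (nm, > 0).
#' @param n,m Positive integer exponents with `m > n`.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(d0 = 0, r0 = 0.9, n = 6L, m = 12L) {
  if (r0 <= 0) stop("switching_params: r0 must be > 0")
  n <- as.integer(n); m <- as.integer(m)
  if (n <= 0L || m <= n) stop("switching_params: need m > n > 0")
  structure(list(d0 = d0, r0 = r0, n = n, m = m), class = "switching_params")
}

#' Evaluate the rational switching function
#'
#' Continuous at `x = 1` through the analytic limit `n/m` (a guarded
#' first-order expansion is used within `|x - 1| < 1e-6` to avoid 0/0).
#' Distances below `d0` clamp to `x = 0` and return 1.
#'
#' @param r Distances (nm), vectorised.
#' @param p A [switching_params()].
#' @return Values in `(0, 1]`, monotone non-increasing in `r` beyond `d0`.
#' @export
switching_value <- function(r, p = switching_params()) {
  if (any(r < 0)) stop("switching_value: r must be >= 0")
  x <- pmax((r - p$d0) / p$r0, 0)
  s <- numeric(length(x))
  near1 <- abs(x - 1) < 1e-6
  xr <- x[!near1]
  s[!near1] <- (1 - xr^p$n) / (1 - xr^p$m)
  if (any(near1)) {
    h <- x[near1] - 1
    s[near1] <- (p$n / p$m) * (1 + (p$n - p$m) / 2 * h)
  }
  s
}

#' Per-frame collective-variable series
#'
#' @param values Numeric vector, one scalar per frame.
#' @param name,unit Metadata strings.
#' @param time Frame times (ns), optional.
#' @return An object of class `cv_series` (a numeric vector with metadata
#'   attributes; ordinary arithmetic applies).
#' @export
cv_series <- function(values, name = "cv", unit = "", time = NULL) {
  if (!all(is.finite(values))) stop("cv_series: non-finite values")
  structure(as.numeric(values), name = name, unit = unit, time = time,
            class = c("cv_series", "numeric"))
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series '%s' [%s]: %d frames, range %.4g .. %.4g\n",
              attr(x, "name"), attr(x, "unit"), length(x),
              min(x), max(x)))
  invisible(x)
}

# All cross-pair distances between two coordinate blocks (rows = particles).
cross_distances <- function(a, b) {
  # |a_i - b_j| via the expanded square; clamp tiny negatives from rounding
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

sel_pair <- function(traj, regions, sel_a, sel_b, disjoint = FALSE) {
  ia <- region_indices(traj, regions, sel_a)
  ib <- region_indices(traj, regions, sel_b)
  if (disjoint && length(intersect(ia, ib)))
    stop("selections '", sel_a, "' and '", sel_b,
         "' overlap; cross-pair sums are undefined for self-pairs")
  list(a = ia, b = ib)
}

#' Coordination number between two selections
#'
#' Smooth interchain contact count: the double sum of the switching
#' function over every cross pair,
#' \eqn{c = \sum_{i \in A}\sum_{j \in B} s(r_{ij})}.  A continuous,
#' differentiable surrogate for the number of contacts between (by
#' default, backbone) particles of the two binding partners.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param sel_a,sel_b Region names (must not overlap).
#' @param params A [switching_params()].
#' @return A [cv_series()] with values in `[0, |A| * |B|]`.
#' @export
coordination_number <- function(traj, regions, sel_a, sel_b,
                                params = switching_params()) {
  s <- sel_pair(traj, regions, sel_a, sel_b, disjoint = TRUE)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    sum(switching_value(cross_distances(xyz[s$a, , drop = FALSE],
                                        xyz[s$b, , drop = FALSE]), params))
  }, numeric(1))
  cv_series(vals, name = paste0("coord(", sel_a, ",", sel_b, ")"),
            unit = "contacts", time = traj$time)
}

#' Centre-of-mass distance between two selections
#'
#' Euclidean distance between the unweighted geometric centres of the two
#' selections, per frame (beads carry no masses; uniform weighting).
#'
#' @inheritParams coordination_number
#' @return A [cv_series()] in nm.
#' @export
com_distance <- function(traj, regions, sel_a, sel_b) {
  s <- sel_pair(traj, regions, sel_a, sel_b)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    sqrt(sum((colMeans(xyz[s$a, , drop = FALSE]) -
                colMeans(xyz[s$b, , drop = FALSE]))^2))
  }, numeric(1))
  cv_series(vals, name = paste0("comdist(", sel_a, ",", sel_b, ")"),
            unit = "nm", time = traj$time)
}

#' Minimum interparticle distance between two selections
#'
#' @inheritParams coordination_number
#' @return A [cv_series()] in nm.
#' @export
min_distance <- function(traj, regions, sel_a, sel_b) {
  s <- sel_pair(traj, regions, sel_a, sel_b)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    min(cross_distances(xyz[s$a, , drop = FALSE], xyz[s$b, , drop = FALSE]))
  }, numeric(1))
  cv_series(vals, name = paste0("mindist(", sel_a, ",", sel_b, ")"),
            unit = "nm", time = traj$time)
}

#' Minimum interchain distance (all particles of two chains)
#'
#' Convenience wrapper for the global bound/unbound criterion: the minimum
#' distance between any particle of the receptor chain and any particle of
#' the ligand chain, per frame.
#'
#' @param traj A [trajectory()].
#' @param chain_a,chain_b Chain identifiers.
#' @return A [cv_series()] in nm.
#' @export
min_interchain_distance <- function(traj, chain_a, chain_b) {
  ia <- chain_indices(traj, chain_a)
  ib <- chain_indices(traj, chain_b)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    min(cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
  cv_series(vals, name = paste0("mindist(", chain_a, ",", chain_b, ")"),
            unit = "nm", time = traj$time)
}

#' Inter-chain orientation angle
#'
#' Angle between the two molecular axes, each defined by the vector from
#' the centre of an N-terminal anchor selection to the centre of a
#' C-terminal anchor selection.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param n_anchor_a,c_anchor_a Region names anchoring chain A's axis.
#' @param n_anchor_b,c_anchor_b Region names anchoring chain B's axis.
#' @return A [cv_series()] in degrees, range `[0, 180]`.
#' @export
orientation_angle <- function(traj, regions, n_anchor_a, c_anchor_a,
                              n_anchor_b, c_anchor_b) {
  ina <- region_indices(traj, regions, n_anchor_a)
  ica <- region_indices(traj, regions, c_anchor_a)
  inb <- region_indices(traj, regions, n_anchor_b)
  icb <- region_indices(traj, regions, c_anchor_b)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    va <- colMeans(xyz[ica, , drop = FALSE]) - colMeans(xyz[ina, , drop = FALSE])
    vb <- colMeans(xyz[icb, , drop = FALSE]) - colMeans(xyz[inb, , drop = FALSE])
    na_ <- sqrt(sum(va^2)); nb_ <- sqrt(sum(vb^2))
    if (na_ < 1e-12 || nb_ < 1e-12)
      stop("orientation_angle: zero-length axis vector at frame ", f)
    acos(min(1, max(-1, sum(va * vb) / (na_ * nb_)))) * 180 / pi
  }, numeric(1))
  cv_series(vals, name = "orientation_angle", unit = "deg", time = traj$time)
}

#' N-terminus to N-terminus distance
#'
#' Specialisation of [com_distance()] to the two N-terminal selections —
#' the orientation-sensitive axis used when the centre-of-mass distance
#' alone is degenerate between binding poses.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()] defining both N-terminal selections.
#' @param nterm_a,nterm_b Region names of the two N-terminal selections.
#' @return A [cv_series()] in nm.
#' @export
nterm_nterm_distance <- function(traj, regions, nterm_a = "NTERM_A",
                                 nterm_b = "NTERM_B") {
  out <- com_distance(traj, regions, nterm_a, nterm_b)
  attr(out, "name") <- paste0("ntermdist(", nterm_a, ",", nterm_b, ")")
  out
}
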