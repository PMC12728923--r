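# Bound/unbound segmentation and CRS1/CRS2 engagement-order statistics:
# the analyses behind the two-step recognition model.

#' Segment a minimum-distance series into bound and unbound regimes
#'
#' A frame is bound iff the minimum interchain distance is strictly below
#' the threshold (default 0.5 nm, the usual 5 A coarse-grained binding
#' criterion).
#'
#' @param min_dist A [cv_series()] (or numeric vector) of minimum
#'   distances in nm.
#' @param threshold Bound threshold in nm (> 0).
#' @return An object of class `bound_segmentation`: list with per-frame
#'   logical `bound`, scalar `fraction`, and `segments` (data frame
#'   `start`, `end`, `bound` of maximal runs partitioning the frames).
#' @export
classify_bound <- function(min_dist, threshold = 0.5) {
  if (threshold <= 0) stop("classify_bound: threshold must be > 0")
  v <- as.numeric(min_dist)
  if (length(v) == 0L) stop("classify_bound: empty series")
  bound <- v < threshold
  r <- rle(bound)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  structure(list(bound = bound,
                 fraction = mean(bound),
                 threshold = threshold,
                 segments = data.frame(start = start, end = end,
                                       bound = r$values)),
            class = "bound_segmentation")
}

#' @export
print.bound_segmentation <- function(x, ...) {
  cat(sprintf(
    "bound_segmentation: %d frames, bound fraction %.3f (< %.3g nm), %d segments\n",
    length(x$bound), x$fraction, x$threshold, nrow(x$segments)))
  invisible(x)
}

#' Per-frame residue-contact count against a receptor region
#'
#' Counts, for every frame, the number of (ligand residue, region residue)
#' pairs whose minimum interparticle distance is strictly below the
#' cutoff; each residue pair counts once per frame.
#'
#' @param traj A [trajectory()].
#' @param regions A [region_set()].
#' @param ligand_sel Ligand region name.
#' @param receptor_region Receptor region name.
#' @param cutoff Contact cutoff in nm (default 0.5).
#' @return An integer-valued [cv_series()].
#' @export
contact_trace <- function(traj, regions, ligand_sel, receptor_region,
                          cutoff = 0.5) {
  ia <- region_indices(traj, regions, ligand_sel)
  ib <- region_indices(traj, regions, receptor_region)
  p <- traj$topology$particles
  ra <- p$residue_index[ia]
  rb <- p$residue_index[ib]
  ga <- match(ra, unique(ra))   # particle -> residue group
  gb <- match(rb, unique(rb))
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    d <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    contact <- d < cutoff
    if (!any(contact)) return(0)
    # residue-pair contact iff any particle pair of the block is in contact
    pairs <- unique(cbind(ga[row(d)[contact]], gb[col(d)[contact]]))
    nrow(pairs)
  }, numeric(1))
  cv_series(vals, name = paste0("contacts(", ligand_sel, ",",
                                receptor_region, ")"),
            unit = "pairs", time = traj$time)
}

#' z-scored time-lag cross-correlation between two contact traces
#'
#' Both traces are standardised to zero mean and unit variance; the
#' correlation at lag `l` is `c(l) = sum_t z1(t) z2(t - l) / (N - |l|)`.
#' With trace 1 = CRS1 and trace 2 = CRS2 engagement, a *negative* lag at
#' the correlation maximum means CRS1 engagement precedes CRS2 (trace 2
#' repeats trace 1 after a delay).  This sign convention is recorded in
#' the result.
#'
#' @param trace1,trace2 Numeric vectors (e.g. [contact_trace()] outputs) of
#'   equal length `N > 2 * max_lag`.
#' @param max_lag Largest lag magnitude examined (frames).
#' @param tol Lag tolerance for the ordering call (frames): peak lags in
#'   `[-tol, tol]` are called simultaneous.
#' @return An object of class `lag_correlation`: list with `lags`,
#'   `correlation`, `peak_lag`, `peak_value`, `call` (one of
#'   `"CRS1_first"`, `"CRS2_first"`, `"simultaneous"`) and the sign
#'   convention string.
#' @export
lagged_xcorr <- function(trace1, trace2, max_lag, tol = 1) {
  x <- as.numeric(trace1); y <- as.numeric(trace2)
  n <- length(x)
  if (length(y) != n) stop("lagged_xcorr: traces must have equal length")
  if (n <= 2 * max_lag)
    stop("lagged_xcorr: need length > 2 * max_lag")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("lagged_xcorr: constant trace; correlation undefined")
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  lags <- seq.int(-max_lag, max_lag)
  corr <- vapply(lags, function(l) {
    if (l >= 0) {
      t <- (1 + l):n
      sum(zx[t] * zy[t - l]) / (n - l)
    } else {
      t <- 1:(n + l)
      sum(zx[t] * zy[t - l]) / (n + l)
    }
  }, numeric(1))
  ip <- which.max(corr)
  peak_lag <- lags[ip]
  call <- if (peak_lag < -tol) "CRS1_first"
  else if (peak_lag > tol) "CRS2_first"
  else "simultaneous"
  structure(list(lags = lags, correlation = corr, peak_lag = peak_lag,
                 peak_value = corr[ip], call = call, tol = tol,
                 sign_convention =
                   "negative peak lag => trace1 (CRS1) precedes trace2 (CRS2)"),
            class = "lag_correlation")
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat(sprintf("lag_correlation: peak %.3f at lag %d -> %s\n",
              x$peak_value, x$peak_lag, x$call))
  cat("  ", x$sign_convention, "\n")
  invisible(x)
}

#' First persistent engagement order of two contact traces
#'
#' The engagement frame of a trace is the first index at which it stays
#' strictly positive for at least `persistence` consecutive frames
#' (de-emphasising fleeting contacts).  The earlier engagement wins; equal
#' frames give `"simultaneous"`; traces that never engage give
#' `"no_binding"`.
#'
#' @param trace1,trace2 Numeric contact-count traces (CRS1, CRS2).
#' @param persistence Minimum run length in frames (>= 1; default 5).
#' @return List with `call` (`"CRS1_first"`, `"CRS2_first"`,
#'   `"simultaneous"`, `"no_binding"`) and per-trace engagement frames
#'   (`NA` if never engaged).
#' @export
first_engagement <- function(trace1, trace2, persistence = 5) {
  if (persistence < 1) stop("first_engagement: persistence must be >= 1")
  engage_frame <- function(tr) {
    r <- rle(as.numeric(tr) > 0)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    ok <- r$values & r$lengths >= persistence
    if (!any(ok)) NA_integer_ else start[which(ok)[1]]
  }
  f1 <- engage_frame(trace1)
  f2 <- engage_frame(trace2)
  call <- if (is.na(f1) && is.na(f2)) "no_binding"
  else if (is.na(f2) || (!is.na(f1) && f1 < f2)) "CRS1_first"
  else if (is.na(f1) || f2 < f1) "CRS2_first"
  else "simultaneous"
  list(call = call, frame1 = f1, frame2 = f2, persistence = persistence)
}

#' Combined engagement-order report for two contact traces
#'
#' Runs [first_engagement()] and [lagged_xcorr()] together.  By default
#' `max_lag` spans the whole trace (`(N - 1) / 2 - 1`): when the first
#' site engages as a transient pulse and the second as a late plateau,
#' the correlation maximum sits at a lag comparable to the trace length,
#' and a short window would truncate it.
#'
#' @param trace1,trace2 Contact-count traces (CRS1, CRS2).
#' @param persistence Persistence filter for [first_engagement()].
#' @param max_lag Optional fixed lag window (frames).
#' @param tol Lag tolerance for the ordering call.
#' @return List with `first_engagement`, `xcorr`, and the two ordering
#'   calls (`fe_call`, `lag_call`).
#' @export
engagement_order <- function(trace1, trace2, persistence = 5,
                             max_lag = NULL, tol = 1) {
  fe <- first_engagement(trace1, trace2, persistence)
  n <- length(trace1)
  if (is.null(max_lag)) max_lag <- (n - 1L) %/% 2L - 1L
  max_lag <- min(max_lag, (n - 1L) %/% 2L - 1L)
  xc <- lagged_xcorr(trace1, trace2, max_lag, tol = tol)
  list(first_engagement = fe, xcorr = xc,
       fe_call = fe$call, lag_call = xc$call)
}
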