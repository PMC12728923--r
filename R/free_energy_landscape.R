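# Two-dimensional free-energy landscapes by Boltzmann inversion of the
# (distance, coordination) histogram, with basin detection.

KB_KJ <- 0.008314462618  # Boltzmann constant, kJ/mol/K

#' Build a 2D free-energy landscape
#'
#' Bins the two collective-variable series into a 2D histogram, normalises
#' to a probability `P`, and Boltzmann-inverts: `F = -kT log P` on occupied
#' bins, shifted so the minimum occupied free energy is zero.  Empty bins
#' are masked (`NA`), never assigned zero energy.  No smoothing is applied,
#' so the free-energy difference between any two occupied bins is exactly
#' `-kT log` of their count ratio.
#'
#' @param d,coord Equal-length [cv_series()] (or numeric vectors): the
#'   distance-like and coordination-like axes.
#' @param bins Integer bin counts `c(nd, ncoord)` (>= 2 each).
#' @param temperature Temperature in K (used only for `units = "kJ/mol"`).
#' @param units `"kBT"` (default) or `"kJ/mol"`.
#' @param edges Optional list `(d, coord)` of bin-edge vectors, e.g. to
#'   share edges across compared ensembles; by default edges span the
#'   observed ranges padded by 5%.
#' @return An object of class `fel_grid`: bin edges and centres, `counts`,
#'   `P`, `F` matrices (rows = d bins, cols = coord bins), `temperature`,
#'   `units`.
#' @export
build_fel <- function(d, coord, bins = c(60, 60), temperature = 303,
                      units = c("kBT", "kJ/mol"), edges = NULL) {
  units <- match.arg(units)
  x <- as.numeric(d); y <- as.numeric(coord)
  if (length(x) != length(y)) stop("build_fel: series lengths differ")
  if (any(bins < 2)) stop("build_fel: need >= 2 bins per axis")
  pad_edges <- function(v, nb) {
    r <- range(v)
    pad <- max(diff(r), 1e-12) * 0.05
    seq(r[1] - pad, r[2] + pad, length.out = nb + 1)
  }
  if (is.null(edges))
    edges <- list(d = pad_edges(x, bins[1]), coord = pad_edges(y, bins[2]))
  ix <- findInterval(x, edges$d, rightmost.closed = TRUE)
  iy <- findInterval(y, edges$coord, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= length(edges$d) - 1 &
    iy >= 1 & iy <= length(edges$coord) - 1
  if (!all(keep))
    warning("build_fel: ", sum(!keep), " frames outside the bin edges dropped")
  nd <- length(edges$d) - 1; nc <- length(edges$coord) - 1
  counts <- matrix(0, nd, nc)
  tab <- table(factor(ix[keep], levels = 1:nd),
               factor(iy[keep], levels = 1:nc))
  counts[] <- as.numeric(tab)
  if (sum(counts > 0) == 1L)
    warning("build_fel: degenerate landscape (all frames in one bin)")
  P <- counts / sum(counts)
  kT <- if (units == "kBT") 1 else KB_KJ * temperature
  F_ <- matrix(NA_real_, nd, nc)
  occ <- counts > 0
  F_[occ] <- -kT * log(P[occ])
  F_ <- F_ - min(F_[occ])
  structure(list(d_edges = edges$d, coord_edges = edges$coord,
                 d_centers = (edges$d[-1] + edges$d[-(nd + 1)]) / 2,
                 coord_centers = (edges$coord[-1] + edges$coord[-(nc + 1)]) / 2,
                 counts = counts, P = P, F = F_, n = sum(counts),
                 temperature = temperature, units = units),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid: %d x %d bins, %d frames, %d occupied, F in %s (max %.3g)\n",
              nrow(x$F), ncol(x$F), x$n, sum(x$counts > 0), x$units,
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fel_grid <- function(x, basins = NULL, ...) {
  graphics::image(x$d_centers, x$coord_centers, x$F,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = "distance", ylab = "coordination",
                  main = paste0("free energy (", x$units, ")"), ...)
  if (!is.null(basins)) {
    idx <- which(basins$labels > 0, arr.ind = TRUE)
    graphics::points(x$d_centers[idx[, 1]], x$coord_centers[idx[, 2]],
                     pch = ".", cex = 2)
  }
  invisible(x)
}

neighbours8 <- function(i, j, nr, nc) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  cbind(ii[ok], jj[ok])
}

#' Locate free-energy basins on a landscape
#'
#' Local minima are occupied bins whose free energy does not exceed any of
#' their (up to 8) occupied neighbours.  Each basin is the connected
#' occupied component around a minimum with `F <= F_min + depth`;
#' components that touch are merged into the deeper minimum.  Empty bins
#' are treated as infinite-energy barriers.
#'
#' @param grid A [build_fel()] result.
#' @param depth Basin depth in the grid's energy units (default 3 kT).
#' @return An object of class `fel_basins`: `labels` matrix (0 = no
#'   basin), and `summary` data frame (basin id, minimum free energy, bin
#'   count, frame count, probability mass) ordered by increasing minimum.
#' @export
find_basins <- function(grid, depth = 3) {
  F_ <- grid$F
  nr <- nrow(F_); nc <- ncol(F_)
  occ <- !is.na(F_)
  labels <- matrix(0L, nr, nc)
  # local minima among occupied bins
  minima <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!occ[i, j]) next
    nb <- neighbours8(i, j, nr, nc)
    fn <- F_[nb]
    if (all(fn[!is.na(fn)] >= F_[i, j]))
      minima[[length(minima) + 1L]] <- c(i, j)
  }
  if (length(minima) == 0L)                      # flat/degenerate grid
    minima <- list(which(occ, arr.ind = TRUE)[1, ])
  ord <- order(vapply(minima, function(m) F_[m[1], m[2]], numeric(1)))
  next_id <- 0L
  for (m in minima[ord]) {
    if (labels[m[1], m[2]] != 0L) next           # swallowed by deeper basin
    lim <- F_[m[1], m[2]] + depth
    # BFS over occupied neighbours within the depth contour
    comp <- matrix(m, ncol = 2)
    seen <- matrix(FALSE, nr, nc); seen[m[1], m[2]] <- TRUE
    queue <- list(m); touched <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(nb <- neighbours8(cur[1], cur[2], nr, nc)))) {
        i <- nb[r, 1]; j <- nb[r, 2]
        if (seen[i, j] || !occ[i, j] || F_[i, j] > lim) next
        seen[i, j] <- TRUE
        if (labels[i, j] != 0L && touched == 0L) touched <- labels[i, j]
        comp <- rbind(comp, c(i, j))
        queue[[length(queue) + 1L]] <- c(i, j)
      }
    }
    id <- if (touched != 0L) touched else (next_id <- next_id + 1L)
    for (r in seq_len(nrow(comp)))
      if (labels[comp[r, 1], comp[r, 2]] == 0L)
        labels[comp[r, 1], comp[r, 2]] <- id
  }
  ids <- sort(unique(labels[labels > 0]))
  summ <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    data.frame(basin = id, f_min = min(F_[sel]),
               n_bins = sum(sel), n_frames = sum(grid$counts[sel]),
               probability = sum(grid$P[sel]))
  }))
  summ <- summ[order(summ$f_min), , drop = FALSE]
  structure(list(labels = labels, summary = summ, depth = depth),
            class = "fel_basins")
}

#' @export
print.fel_basins <- function(x, ...) {
  cat(sprintf("fel_basins: %d basins (depth %.3g)\n", nrow(x$summary), x$depth))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Frames belonging to a basin
#'
#' @param grid A [build_fel()] result.
#' @param basins A [find_basins()] result for that grid.
#' @param basin Basin id (as in `basins$summary$basin`).
#' @param d,coord The series the grid was built from.
#' @return Integer frame indices whose `(d, coord)` bin carries the basin
#'   label; deterministic.
#' @export
basin_frames <- function(grid, basins, basin, d, coord) {
  if (!basin %in% basins$summary$basin)
    stop("basin_frames: unknown basin id ", basin)
  ix <- findInterval(as.numeric(d), grid$d_edges, rightmost.closed = TRUE)
  iy <- findInterval(as.numeric(coord), grid$coord_edges,
                     rightmost.closed = TRUE)
  nd <- nrow(grid$F); nc <- ncol(grid$F)
  ok <- ix >= 1 & ix <= nd & iy >= 1 & iy <= nc
  out <- which(ok)
  out[basins$labels[cbind(ix[out], iy[out])] == basin]
}

#' Free-energy difference between two basins
#'
#' `-kT log` of the ratio of the basins' probability masses; for a mixture
#' with pose weights `w_i`, this recovers `-kT log(w_i / w_j)` as the
#' frame count grows.
#'
#' @param grid A [build_fel()] result.
#' @param basins A [find_basins()] result.
#' @param a,b Basin ids.
#' @return Free-energy difference `F_a - F_b` in the grid's units.
#' @export
basin_delta_f <- function(grid, basins, a, b) {
  s <- basins$summary
  pa <- s$probability[s$basin == a]
  pb <- s$probability[s$basin == b]
  if (!length(pa) || !length(pb)) stop("basin_delta_f: unknown basin id")
  kT <- if (grid$units == "kBT") 1 else KB_KJ * grid$temperature
  -kT * log(pa / pb)
}
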