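# Shared fixtures and independent brute-force oracles.

# Minimal topology: n beads, one residue per bead, optionally split over
# two chains.
tiny_topology <- function(n, chains = c("A")) {
  chain <- rep(chains, length.out = n)
  chain <- sort(chain)
  resid <- stats::ave(seq_len(n), chain, FUN = seq_along)
  topology(data.frame(
    particle_id = seq_len(n) - 1L, name = "BB",
    residue_index = as.integer(resid), residue_name = "BEA",
    chain_id = chain, stringsAsFactors = FALSE))
}

# Trajectory from a list of coordinate matrices.
tiny_traj <- function(frames, chains = c("A")) {
  n <- nrow(frames[[1]])
  coords <- array(unlist(frames), c(n, 3, length(frames)))
  trajectory(tiny_topology(n, chains), coords)
}

two_region_set <- function(n_a, n_b) {
  region_set(list(A = list(chain = "A", ranges = list(c(1, n_a))),
                  B = list(chain = "B", ranges = list(c(1, n_b)))))
}

# Two-chain trajectory from per-frame coordinate matrices for chains A, B.
two_chain_traj <- function(frames_a, frames_b) {
  n_a <- nrow(frames_a[[1]]); n_b <- nrow(frames_b[[1]])
  top <- topology(data.frame(
    particle_id = seq_len(n_a + n_b) - 1L, name = "BB",
    residue_index = c(seq_len(n_a), seq_len(n_b)),
    residue_name = "BEA",
    chain_id = rep(c("A", "B"), c(n_a, n_b)), stringsAsFactors = FALSE))
  frames <- Map(rbind, frames_a, frames_b)
  coords <- array(unlist(frames), c(n_a + n_b, 3, length(frames)))
  trajectory(top, coords)
}

random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 2))
}

# --- independent oracles ----------------------------------------------------

brute_switch <- function(r, d0, r0, n, m) {
  x <- max((r - d0) / r0, 0)
  if (abs(x - 1) < 1e-12) return(n / m)
  (1 - x^n) / (1 - x^m)
}

brute_coordination <- function(a, b, d0, r0, n, m) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt(sum((a[i, ] - b[j, ])^2))
    s <- s + brute_switch(r, d0, r0, n, m)
  }
  s
}

brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# Straightforward reference GROMOS clustering from a distance matrix:
# recompute neighbour lists from scratch every round.
reference_gromos <- function(dmat, cutoff) {
  n <- nrow(dmat)
  labels <- rep(0L, n)
  id <- 0L
  remaining <- seq_len(n)
  while (length(remaining)) {
    best <- NULL; best_n <- -1L
    for (i in remaining) {
      nb <- remaining[dmat[i, remaining] < cutoff & remaining != i]
      if (length(nb) > best_n) { best <- i; best_n <- length(nb) }
    }
    members <- c(best, remaining[dmat[best, remaining] < cutoff &
                                   remaining != best])
    id <- id + 1L
    labels[members] <- id
    remaining <- setdiff(remaining, members)
  }
  labels
}

# Shared small mixture simulation, memoised across tests in one session.
get_mixture_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cx <- toy_complex()
      poses <- default_poses(cx)
      spec <- mixture_spec(poses, c(A = 0.6, B = 0.3), 0.1,
                           n_frames = 2000L, seed = 4242L)
      cache <<- c(sample_mixture(spec, cx), list(complex = cx, poses = poses))
    }
    cache
  }
})
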