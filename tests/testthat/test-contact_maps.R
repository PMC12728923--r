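test_that("single-frame contact maps follow the strict cutoff rule", {
  a <- matrix(c(0, 0, 0, 2, 2, 2), 2, byrow = TRUE)
  b <- matrix(c(0.3, 0, 0), 1)
  traj <- two_chain_traj(list(a), list(b))
  m <- contact_frequency(traj, "A", "B", cutoff = 0.4)
  expect_equal(m$mat[1, 1], 1)
  expect_equal(sum(m$mat), 1)
  # a pair exactly at the cutoff is not a contact
  b2 <- matrix(c(0.4, 0, 0), 1)
  m2 <- contact_frequency(two_chain_traj(list(a), list(b2)), "A", "B",
                          cutoff = 0.4)
  expect_equal(sum(m2$mat), 0)
})

test_that("contact frequencies match brute-force enumeration and bounds", {
  set.seed(24)
  frames_a <- replicate(6, matrix(runif(15, 0, 1.5), 5), simplify = FALSE)
  frames_b <- replicate(6, matrix(runif(9, 0, 1.5), 3), simplify = FALSE)
  traj <- two_chain_traj(frames_a, frames_b)
  m <- contact_frequency(traj, "A", "B", cutoff = 0.5)
  manual <- matrix(0, 5, 3)
  for (f in 1:6) for (i in 1:5) for (j in 1:3)
    if (sqrt(sum((frames_a[[f]][i, ] - frames_b[[f]][j, ])^2)) < 0.5)
      manual[i, j] <- manual[i, j] + 1
  expect_equal(m$mat, manual / 6, tolerance = 1e-12)
  expect_true(all(m$mat >= 0 & m$mat <= 1))
  # bound-frames denominator never lowers a frequency
  bound <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  mb <- contact_frequency(traj, "A", "B", cutoff = 0.5,
                          denominator = "bound_frames", bound = bound)
  expect_true(all(mb$mat >= m$mat - 1e-12))
  expect_error(contact_frequency(traj, "A", "B", 0.5, "bound_frames",
                                 bound = rep(FALSE, 6)), "no bound frames")
})

test_that("thresholding zeroes weak contacts with a strict boundary", {
  a <- matrix(0, 1, 3)
  traj <- two_chain_traj(list(a), list(matrix(1, 1, 3)))
  m <- contact_frequency(traj, "A", "B", cutoff = 3)
  m$mat <- matrix(c(0.05, 0.10, 0.15), 1)
  m$ligand_res <- 1:3
  t1 <- threshold_map(m, 0.10)
  expect_equal(as.numeric(t1$mat), c(0, 0, 0.15))   # strict >
  expect_equal(t1$n_surviving, 1)
  t0 <- threshold_map(m, 0)
  expect_equal(as.numeric(t0$mat), c(0.05, 0.10, 0.15))
  expect_error(threshold_map(m, 1), "tau")
})

test_that("delta maps are antisymmetric and zero for identical inputs", {
  set.seed(25)
  mk <- function(mat) {
    structure(list(receptor_res = seq_len(nrow(mat)),
                   ligand_res = seq_len(ncol(mat)), mat = mat,
                   cutoff = 0.5, n_frames = 100,
                   denominator = "all_frames"), class = "contact_map")
  }
  A <- mk(matrix(runif(20), 4))
  B <- mk(matrix(runif(20), 4))
  expect_true(all(delta_map(A, A, 0.1)$mat == 0))
  dab <- delta_map(A, B, 0.1)$mat
  dba <- delta_map(B, A, 0.1)$mat
  expect_equal(dab, -dba, tolerance = 1e-12)
  C <- mk(matrix(runif(10), 2))
  expect_error(delta_map(A, C, 0.1), "axes")
})

test_that("hotspots report exactly the designed sticky residues", {
  fx <- get_mixture_fixture()
  cx <- fx$complex
  onlyA <- which(fx$labels == "A")
  sub <- trajectory(cx$topology, fx$trajectory$coords[, , onlyA])
  m <- contact_frequency(sub, "R", "L", cutoff = 0.5)
  hs <- hotspots(m, tau = 0.25)
  # ground truth: contacts of the exact noiseless pose-A placement
  lig0 <- with(fx$poses$A, {
    ref <- cx$ref_coords[cx$ligand_idx, ]
    sweep(ref %*% t(rotation), 2, com, "+")
  })
  rec <- cx$ref_coords[cx$receptor_idx, ]
  dmat <- as.matrix(dist(rbind(rec, lig0)))[1:91, 92:131]
  # jitter (sigma 0.03 nm) lets designed near-misses cross the cutoff in a
  # fraction of frames, so the recovered set is sandwiched between the
  # noiseless sets at cutoff -/+ ~2 jitter sd
  core_rec <- which(apply(dmat, 1, min) < 0.44)
  wide_rec <- which(apply(dmat, 1, min) < 0.56)
  core_lig <- which(apply(dmat, 2, min) < 0.44)
  wide_lig <- which(apply(dmat, 2, min) < 0.56)
  expect_true(all(core_rec %in% hs$receptor$residue))
  expect_true(all(hs$receptor$residue %in% wide_rec))
  expect_true(all(core_lig %in% hs$ligand$residue))
  expect_true(all(hs$ligand$residue %in% wide_lig))
  # designed interface sits on the CRS2 loop ring
  expect_true(all(hs$receptor$residue %in% 72:91))
  # a contact-free map gives empty hotspot lists
  far <- two_chain_traj(list(matrix(0, 2, 3)), list(matrix(5, 2, 3)))
  m0 <- contact_frequency(far, "A", "B", cutoff = 0.5)
  hs0 <- hotspots(m0, tau = 0)
  expect_equal(nrow(hs0$receptor), 0)
  expect_equal(nrow(hs0$ligand), 0)
})

test_that("pose-specific contact frequency tracks the mixture weight", {
  fx <- get_mixture_fixture()
  cx <- fx$complex
  m <- contact_frequency(fx$trajectory, "R", "L", cutoff = 0.5)
  # strongest pose-A contact should appear with frequency ~ w_A = 0.6
  subA <- which(fx$labels == "A")
  mA <- contact_frequency(
    trajectory(cx$topology, fx$trajectory$coords[, , subA]), "R", "L", 0.5)
  best <- which(mA$mat == max(mA$mat), arr.ind = TRUE)[1, ]
  f <- m$mat[best[1], best[2]]
  n <- m$n_frames
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(f - 0.6), 3 * se)
})
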