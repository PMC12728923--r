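test_that("Kabsch superposition recovers rigid motions and stays proper", {
  set.seed(20)
  X <- matrix(rnorm(60), 20)
  rig <- random_rigid()
  Y <- sweep(X %*% t(rig$R), 2, rig$t, "+")
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # noisy copy: rmsd positive but bounded by ~2 sigma
  Yn <- X + matrix(rnorm(60, sd = 0.01), 20)
  fitn <- kabsch_superpose(X, Yn)
  expect_gt(fitn$rmsd, 0)
  expect_lt(fitn$rmsd, 0.02)
  # mirror image: proper rotation enforced, rmsd stays positive
  Ym <- X %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(X, Ym)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 particles")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("gromos clustering handles degenerate and well-separated cases", {
  fx <- get_mixture_fixture()
  cx <- fx$complex
  # identical frames -> one cluster, representative = first frame
  one <- fx$trajectory$coords[, , 1]
  same <- trajectory(cx$topology, array(rep(one, 5), c(dim(one), 5)))
  ca1 <- gromos_cluster(same, cx$regions, "CORE_R", "LIGAND", cutoff = 0.9)
  expect_equal(length(ca1$sizes), 1)
  expect_equal(unname(ca1$sizes[1]), 5L)
  expect_equal(ca1$representatives[1], 1L)
  expect_error(gromos_cluster(same, cx$regions, "CORE_R", "LIGAND", 0),
               "cutoff")
})

test_that("gromos clustering matches an independent reference label-for-label", {
  set.seed(21)
  n <- 200
  # random two-blob feature geometry embedded as 4-bead frames
  centres <- matrix(c(0, 0, 0, 4, 4, 4), 2, byrow = TRUE)
  lab <- sample(1:2, n, replace = TRUE)
  anchor <- matrix(rnorm(9), 3)                              # static receptor
  frames_a <- lapply(1:n, function(i) anchor)
  frames_b <- lapply(1:n, function(i)
    matrix(centres[lab[i], ], 4, 3, byrow = TRUE) + matrix(rnorm(12, sd = 0.3), 4))
  traj <- two_chain_traj(frames_a, frames_b)
  rs <- two_region_set(3, 4)
  ca <- gromos_cluster(traj, rs, "A", "B", cutoff = 1.5)
  # reference: same rmsd definition, independent greedy implementation
  meas <- lapply(1:n, function(f) frame_coords(traj, f)[4:7, ])
  dmat <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(mean(rowSums((meas[[i]] - meas[[j]])^2)))
    dmat[i, j] <- r; dmat[j, i] <- r
  }
  ref <- reference_gromos(dmat, 1.5)
  expect_identical(as.integer(ca$labels), as.integer(ref))
  # the two designed pose groups are recovered exactly
  expect_equal(sort(unname(ca$sizes), decreasing = TRUE),
               sort(as.integer(table(lab)), decreasing = TRUE))
  expect_equal(length(unique(ca$labels[lab == 1])), 1)
  expect_equal(length(unique(ca$labels[lab == 2])), 1)
})

test_that("cluster sizes are consistent and reordering permutes labels only", {
  set.seed(22)
  n <- 60
  feats <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  perm <- sample(n)
  ca <- density_peak_cluster(feats)
  ca_p <- density_peak_cluster(feats[perm, ])
  expect_equal(sum(ca$sizes), n)
  expect_true(all(diff(as.integer(ca$sizes)) <= 0))
  # permuted input gives the same partition up to relabelling
  agree <- outer(ca$labels, ca$labels, "==")
  agree_p <- outer(ca_p$labels[order(perm)], ca_p$labels[order(perm)], "==")
  expect_identical(agree, agree_p)
})

test_that("density-peak clustering recovers blobs and tolerates scaling", {
  set.seed(23)
  blob <- function(mu, n) cbind(rnorm(n, mu[1], 0.1), rnorm(n, mu[2], 0.1))
  X <- rbind(blob(c(0, 0), 400), blob(c(10, 10), 200))
  truth <- rep(1:2, c(400, 200))
  ca <- density_peak_cluster(X)
  expect_equal(length(ca$sizes), 2)
  # <= 2% misassignment against ground truth (labels up to permutation)
  tab <- table(ca$labels, truth)
  expect_gte(sum(apply(tab, 2, max)) / 600, 0.98)
  # single blob -> single cluster
  ca1 <- density_peak_cluster(blob(c(0, 0), 100))
  expect_equal(length(ca1$sizes), 1)
  # global feature scaling is removed by standardisation
  ca10 <- density_peak_cluster(X * 10)
  expect_identical(ca10$labels, ca$labels)
  # identical items collapse to one cluster without error
  ca_id <- density_peak_cluster(matrix(1, 20, 2))
  expect_equal(length(ca_id$sizes), 1)
  expect_error(density_peak_cluster(X[1:5, ]), ">= 10")
})

test_that("both clustering modes resolve the two designed poses", {
  fx <- get_mixture_fixture()
  cx <- fx$complex
  keep <- which(fx$labels != "unbound")[1:250]
  truth <- fx$labels[keep]
  sub <- trajectory(cx$topology, fx$trajectory$coords[, , keep])
  ca_g <- gromos_cluster(sub, cx$regions, "CORE_R", "LIGAND", cutoff = 0.9)
  expect_equal(length(ca_g$sizes), 2)
  tab <- table(ca_g$labels, truth)
  expect_gte(sum(apply(tab, 2, max)) / length(keep), 0.98)
  d <- com_distance(sub, cx$regions, "RECEPTOR", "LIGAND")
  co <- coordination_number(sub, cx$regions, "RECEPTOR", "LIGAND")
  ca_d <- density_peak_cluster(cbind(co, d))
  expect_equal(length(ca_d$sizes), 2)
  tab_d <- table(ca_d$labels, truth)
  expect_gte(sum(apply(tab_d, 2, max)) / length(keep), 0.98)
})
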