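test_that("switching function matches closed forms and is continuous at x = 1", {
  p <- switching_params(0, 0.9, 6, 12)
  expect_equal(switching_value(0, p), 1)                     # r = d0
  expect_equal(switching_value(2 * 0.9, p), 63 / 4095)       # x = 2
  # analytic limit n/m at x = 1, approached from both sides
  left <- switching_value(0.9 * (1 - 1e-8), p)
  right <- switching_value(0.9 * (1 + 1e-8), p)
  expect_equal(switching_value(0.9, p), 0.5, tolerance = 1e-9)
  expect_lt(abs(left - 0.5), 1e-6)
  expect_lt(abs(right - 0.5), 1e-6)
  expect_lt(abs(left - right), 1e-6)
  # monotone non-increasing beyond d0; r < d0 clamps to 1
  r <- seq(0, 5, by = 0.01)
  expect_true(all(diff(switching_value(r, p)) <= 1e-12))
  p2 <- switching_params(d0 = 0.3, r0 = 0.9)
  expect_equal(switching_value(0.1, p2), 1)
  expect_error(switching_params(r0 = -1), "r0")
  expect_error(switching_params(n = 12, m = 6), "m > n")
})

test_that("coordination number equals the brute-force double sum", {
  p <- switching_params()
  set.seed(7)
  for (rep in 1:5) {
    a <- matrix(runif(60, 0, 3), 20)
    b <- matrix(runif(60, 0, 3) + 1, 20)
    traj <- two_chain_traj(list(a), list(b))
    rs <- two_region_set(20, 20)
    c_pkg <- coordination_number(traj, rs, "A", "B", p)
    expect_equal(as.numeric(c_pkg),
                 brute_coordination(a, b, 0, 0.9, 6, 12),
                 tolerance = 1e-10)
  }
  # single pair at r0 is the n/m limit case
  traj1 <- two_chain_traj(list(matrix(0, 1, 3)),
                          list(matrix(c(0.9, 0, 0), 1)))
  rs1 <- two_region_set(1, 1)
  expect_equal(as.numeric(coordination_number(traj1, rs1, "A", "B", p)),
               0.5, tolerance = 1e-9)
  # far-field decay
  trajf <- two_chain_traj(list(matrix(runif(30), 10)),
                          list(matrix(runif(30) + 20, 10)))
  rsf <- two_region_set(10, 10)
  expect_lt(as.numeric(coordination_number(trajf, rsf, "A", "B", p)),
            100 * 1e-3)
  # overlapping selections are rejected
  rs_over <- region_set(list(A = list(chain = "A", ranges = list(c(1, 20))),
                             AA = list(chain = "A", ranges = list(c(5, 10)))))
  expect_error(coordination_number(traj, rs_over, "A", "AA", p), "overlap")
})

test_that("com distance: 3-4-5, translation covariance, empty selection", {
  traj <- two_chain_traj(list(matrix(0, 1, 3)), list(matrix(c(3, 4, 0), 1)))
  rs <- two_region_set(1, 1)
  expect_equal(as.numeric(com_distance(traj, rs, "A", "B")), 5)
  set.seed(8)
  a <- matrix(rnorm(30), 10); b <- matrix(rnorm(15) + 4, 5)
  u <- (colMeans(b) - colMeans(a)); u <- u / sqrt(sum(u^2))
  t2 <- two_chain_traj(list(a, a), list(b, sweep(b, 2, 2 * u, "+")))
  rs2 <- two_region_set(10, 5)
  d <- as.numeric(com_distance(t2, rs2, "A", "B"))
  expect_equal(d[2] - d[1], 2, tolerance = 1e-9)
})

test_that("min distance equals brute force and is monotone under set growth", {
  set.seed(9)
  a <- matrix(rnorm(30), 10); b <- matrix(rnorm(30) + 2, 10)
  traj <- two_chain_traj(list(a), list(b))
  rs <- two_region_set(10, 10)
  expect_equal(as.numeric(min_distance(traj, rs, "A", "B")),
               brute_min_distance(a, b), tolerance = 1e-12)
  # enlarging a selection can only decrease (or keep) the minimum
  rs_sub <- region_set(list(A = list(chain = "A", ranges = list(c(1, 5))),
                            Afull = list(chain = "A", ranges = list(c(1, 10))),
                            B = list(chain = "B", ranges = list(c(1, 10)))))
  m_sub <- as.numeric(min_distance(traj, rs_sub, "A", "B"))
  m_full <- as.numeric(min_distance(traj, rs_sub, "Afull", "B"))
  expect_lte(m_full, m_sub)
})

test_that("orientation angle reproduces canonical geometries", {
  mk <- function(vb) {
    # chain A axis along +x, chain B axis along vb; anchors are single beads
    two_chain_traj(list(matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)),
                   list(matrix(c(5, 5, 5, 5 + vb), 2, byrow = TRUE)))
  }
  rs <- region_set(list(
    NA_A = list(chain = "A", ranges = list(1)),
    CA_A = list(chain = "A", ranges = list(2)),
    NA_B = list(chain = "B", ranges = list(1)),
    CA_B = list(chain = "B", ranges = list(2))))
  ang <- function(vb)
    as.numeric(orientation_angle(mk(vb), rs, "NA_A", "CA_A", "NA_B", "CA_B"))
  expect_equal(ang(c(1, 0, 0)), 0)
  expect_equal(ang(c(-1, 0, 0)), 180)
  expect_equal(ang(c(0, 1, 0)), 90)
  expect_error(ang(c(0, 0, 0)), "zero-length")
})

test_that("all CVs are invariant under a global rigid motion", {
  set.seed(10)
  a <- matrix(rnorm(30), 10); b <- matrix(rnorm(15) + 3, 5)
  rig <- random_rigid()
  move <- function(m) sweep(m %*% t(rig$R), 2, rig$t, "+")
  t1 <- two_chain_traj(list(a), list(b))
  t2 <- two_chain_traj(list(move(a)), list(move(b)))
  rs <- two_region_set(10, 5)
  p <- switching_params()
  expect_equal(as.numeric(com_distance(t1, rs, "A", "B")),
               as.numeric(com_distance(t2, rs, "A", "B")), tolerance = 1e-9)
  expect_equal(as.numeric(min_distance(t1, rs, "A", "B")),
               as.numeric(min_distance(t2, rs, "A", "B")), tolerance = 1e-9)
  expect_equal(as.numeric(coordination_number(t1, rs, "A", "B", p)),
               as.numeric(coordination_number(t2, rs, "A", "B", p)),
               tolerance = 1e-9)
  rs_anch <- region_set(list(
    NA_A = list(chain = "A", ranges = list(c(1, 2))),
    CA_A = list(chain = "A", ranges = list(c(9, 10))),
    NA_B = list(chain = "B", ranges = list(1)),
    CA_B = list(chain = "B", ranges = list(5))))
  expect_equal(
    as.numeric(orientation_angle(t1, rs_anch, "NA_A", "CA_A", "NA_B", "CA_B")),
    as.numeric(orientation_angle(t2, rs_anch, "NA_A", "CA_A", "NA_B", "CA_B")),
    tolerance = 1e-7)
})

test_that("n-terminal distance delegates to centroid geometry", {
  set.seed(11)
  a <- matrix(rnorm(63), 21); b <- matrix(rnorm(30) + 2, 10)
  traj <- two_chain_traj(list(a), list(b))
  rs <- region_set(list(NTERM_A = list(chain = "A", ranges = list(c(1, 21))),
                        NTERM_B = list(chain = "B", ranges = list(c(1, 10)))))
  v <- as.numeric(nterm_nterm_distance(traj, rs, "NTERM_A", "NTERM_B"))
  expect_equal(v, sqrt(sum((colMeans(a) - colMeans(b))^2)), tolerance = 1e-9)
  # permutation of particle order within the selections changes nothing
  perm <- sample(21); permb <- sample(10)
  traj_p <- two_chain_traj(list(a[perm, ]), list(b[permb, ]))
  expect_equal(as.numeric(nterm_nterm_distance(traj_p, rs,
                                               "NTERM_A", "NTERM_B")),
               v, tolerance = 1e-12)
})
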