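# Synthetic binding trajectories with exact ground truth.
#
# Two generators cover the two kinds of ground truth needed downstream:
#  * sample_mixture()  — i.i.d. frames from a pose mixture with known
#    weights: exact stationary statistics (free-energy differences,
#    contact frequencies, cluster populations).
#  * simulate_langevin() — overdamped rigid-body dynamics of the ligand in
#    a two-site potential with optional CRS2 gating: temporal structure
#    (dwell segments, CRS1-before-CRS2 engagement order) with an event log.
#
# The receptor is static (infinite friction), emulating a membrane-embedded
# receptor with restrained termini; this isolates ligand-association
# statistics.  Geometry is a bead model, one backbone bead per residue.

#' Derive a reproducible sub-seed from a master seed
#'
#' One master seed expands into independent per-component streams so that
#' stochastic stages can be re-run individually.  Results stay below 2^31.
#'
#' @param master Integer master seed.
#' @param salt Integer stream label.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, salt = 0L) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(salt) * 1299721) %% 2147483646 + 1)
}

#' Build the toy receptor-ligand bead complex
#'
#' A membrane-anchored receptor with a labelled two-site recognition
#' geometry and a rigid, mobile ligand:
#' \itemize{
#'   \item receptor chain `R`, 91 residues: `CRS1` = N-terminal arm
#'     (residues 1-31) rising above the core along z; `CORE_R` = residues
#'     32-91 arranged as three 20-bead rings (helical-bundle stand-in);
#'     `CRS2` = the top ring (residues 72-91), the extracellular-loop
#'     analogue.
#'   \item ligand chain `L`, 40 residues in a compact rigid cluster with
#'     subregions `BETA1` (1-10), `LOOP3` (11-20), `CTERM` (31-40) and a
#'     core `LCORE` (1-30).
#' }
#' Anchor regions (`NANCH_R`/`CANCH_R`, `NANCH_L`/`CANCH_L`) define the
#' molecular axes for orientation angles.  The ligand reference
#' configuration is centred on the origin; placements position copies of
#' it.
#'
#' @param jitter_sigma Per-bead isotropic Gaussian jitter applied to ligand
#'   beads by the mixture sampler (nm, >= 0).
#' @return An object of class `toy_complex`: list with `topology`,
#'   `ref_coords` (reference positions, receptor in place, ligand at the
#'   origin), `regions`, `receptor_idx`, `ligand_idx`, `jitter_sigma`.
#' @export
toy_complex <- function(jitter_sigma = 0.03) {
  if (jitter_sigma < 0) stop("toy_complex: jitter_sigma must be >= 0")
  # receptor N-terminal arm: residues 1 (top) .. 31 (base of arm)
  k <- 1:31
  nterm <- cbind(0.25 * cos(0.6 * k), 0.25 * sin(0.6 * k), 6.1 - 0.1 * k)
  # receptor core: three rings of 20 beads, radius 1.2 nm
  ring <- function(z) {
    a <- 2 * pi * (0:19) / 20
    cbind(1.2 * cos(a), 1.2 * sin(a), z)
  }
  core <- rbind(ring(0.5), ring(1.5), ring(2.5))
  rec <- rbind(nterm, core)
  # ligand: 5 x 4 x 2 grid, 0.35 nm spacing, centred at the origin
  g <- expand.grid(x = 0:4, y = 0:3, z = 0:1)
  lig <- as.matrix(g[, c("x", "y", "z")]) * 0.35
  lig <- sweep(lig, 2, colMeans(lig))
  nr <- nrow(rec); nl <- nrow(lig)
  top <- topology(data.frame(
    particle_id = seq_len(nr + nl) - 1L,
    name = "BB",
    residue_index = c(seq_len(nr), seq_len(nl)),
    residue_name = "BEA",
    chain_id = rep(c("R", "L"), c(nr, nl)),
    stringsAsFactors = FALSE))
  regions <- region_set(list(
    RECEPTOR = list(chain = "R", ranges = list(c(1, 91))),
    CRS1     = list(chain = "R", ranges = list(c(1, 31))),
    CORE_R   = list(chain = "R", ranges = list(c(32, 91))),
    CRS2     = list(chain = "R", ranges = list(c(72, 91))),
    NANCH_R  = list(chain = "R", ranges = list(c(1, 3))),
    CANCH_R  = list(chain = "R", ranges = list(c(89, 91))),
    LIGAND   = list(chain = "L", ranges = list(c(1, 40))),
    BETA1    = list(chain = "L", ranges = list(c(1, 10))),
    LOOP3    = list(chain = "L", ranges = list(c(11, 20))),
    CTERM    = list(chain = "L", ranges = list(c(31, 40))),
    LCORE    = list(chain = "L", ranges = list(c(1, 30))),
    NANCH_L  = list(chain = "L", ranges = list(c(1, 3))),
    CANCH_L  = list(chain = "L", ranges = list(c(38, 40)))))
  validate_regions(regions, top)
  structure(list(topology = top,
                 ref_coords = rbind(rec, lig),
                 regions = regions,
                 receptor_idx = seq_len(nr),
                 ligand_idx = nr + seq_len(nl),
                 jitter_sigma = jitter_sigma),
            class = "toy_complex")
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant fixed to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotation by `angle` about a unit axis (Rodrigues formula).
axis_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

place_ligand <- function(complex, rotation, com) {
  lig <- complex$ref_coords[complex$ligand_idx, , drop = FALSE]
  sweep(lig %*% t(rotation), 2, com, "+")
}

#' Construct a ligand pose touching a receptor region
#'
#' Positions the (rotated) ligand along `direction` from the centroid of a
#' receptor region so that the minimum ligand-receptor bead distance
#' equals `gap`.  Used to design bound poses with known contact patterns.
#'
#' @param complex A [toy_complex()].
#' @param target Receptor region name the pose should contact.
#' @param direction Length-3 approach direction (from the region centroid
#'   outwards; normalised internally).
#' @param rotation 3x3 ligand orientation matrix.
#' @param gap Target minimum bead-bead distance (nm).
#' @return List `(rotation, com)` describing the rigid placement.
#' @export
make_pose <- function(complex, target, direction, rotation = diag(3),
                      gap = 0.3) {
  rec <- complex$ref_coords[complex$receptor_idx, , drop = FALSE]
  tgt <- rec[region_indices(complex$topology, complex$regions, target), ,
             drop = FALSE]
  centre <- colMeans(tgt)
  u <- direction / sqrt(sum(direction^2))
  f <- function(s) {
    min(cross_distances(place_ligand(complex, rotation, centre + s * u),
                        rec)) - gap
  }
  # min distance along the approach axis is non-monotone: locate its
  # minimum, then solve on the outward branch where it grows towards gap
  opt <- stats::optimize(f, c(-2, 12))
  if (opt$objective > 0)
    stop("make_pose: ligand cannot reach within gap of region '", target, "'")
  s <- stats::uniroot(f, c(opt$minimum, 12), tol = 1e-10)$root
  list(rotation = rotation, com = centre + s * u)
}

#' Default two-pose geometry for the toy complex
#'
#' Pose A presents the ligand `BETA1` face to the `CRS2` loop ring (the
#' dominant-interface analogue); pose B presents `CTERM` to the `CRS1`
#' N-terminal arm.  The two poses have disjoint designed contact pairs.
#'
#' @param complex A [toy_complex()].
#' @return Named list of placements (`A`, `B`) as returned by [make_pose()].
#' @export
default_poses <- function(complex) {
  # beta1 rows sit on the low-y face of the reference grid, cterm rows on
  # the high-y face: rotate each pose so its designed face points towards
  # the receptor (-x after placement along +x).
  list(
    A = make_pose(complex, "CRS2", direction = c(1, 0, 0.15),
                  rotation = rotation_z(-pi / 2), gap = 0.3),
    B = make_pose(complex, "CRS1", direction = c(1, 0, 0),
                  rotation = rotation_z(pi / 2), gap = 0.3))
}

#' Specify a pose-mixture trajectory
#'
#' @param poses Named list of placements (`rotation`, `com`), e.g. from
#'   [default_poses()].
#' @param weights Pose weights (same length/order as `poses`).
#' @param unbound_weight Weight of the diffuse unbound state; all weights
#'   must be non-negative and sum to 1 within 1e-9.
#' @param shell Unbound-shell radii `c(r_min, r_max)` (nm) around the
#'   receptor centroid; `r_min` must exceed the receptor extent so unbound
#'   frames are genuinely unbound.
#' @param n_frames Number of i.i.d. frames.
#' @param seed Integer seed (full reproducibility).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(poses, weights, unbound_weight = 0,
                         shell = c(5.5, 7.5), n_frames = 1000L, seed = 1L) {
  w <- c(weights, unbound_weight)
  if (any(w < 0)) stop("mixture_spec: weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture_spec: weights must sum to 1 (got ", sum(w), ")")
  if (length(poses) != length(weights))
    stop("mixture_spec: one weight per pose required")
  if (shell[2] <= shell[1] || shell[1] <= 0)
    stop("mixture_spec: need r_max > r_min > 0")
  structure(list(poses = poses, weights = weights,
                 unbound_weight = unbound_weight, shell = shell,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Sample an i.i.d. pose-mixture trajectory
#'
#' Each frame independently draws a state (a designed bound pose or the
#' diffuse unbound state) with the given weights, places the rigid ligand
#' accordingly, and adds isotropic Gaussian jitter of
#' `complex$jitter_sigma` to every ligand bead.  Unbound frames place the
#' ligand with uniform random orientation and centre uniformly distributed
#' in the spherical shell.  The receptor is static.
#'
#' The per-frame state labels are exact ground truth: the free-energy
#' difference between two pose basins is `-kT log(w_i/w_j)` by
#' construction.
#'
#' @param spec A [mixture_spec()].
#' @param complex A [toy_complex()].
#' @return List with `trajectory`, `labels` (per-frame state: pose name or
#'   `"unbound"`) and `spec`.
#' @export
sample_mixture <- function(spec, complex) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(complex, "toy_complex"))
  set.seed(spec$seed)
  states <- c(names(spec$poses), "unbound")
  w <- c(spec$weights, spec$unbound_weight)
  n <- spec$n_frames
  labels <- sample(states, n, replace = TRUE, prob = w)
  rec <- complex$ref_coords[complex$receptor_idx, , drop = FALSE]
  centre <- colMeans(rec)
  np <- nrow(complex$ref_coords)
  nl <- length(complex$ligand_idx)
  coords <- array(NA_real_, c(np, 3, n))
  for (f in seq_len(n)) {
    lab <- labels[f]
    if (lab == "unbound") {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # radius density ~ r^2 within the shell
      r <- (stats::runif(1, spec$shell[1]^3, spec$shell[2]^3))^(1 / 3)
      lig <- place_ligand(complex, random_rotation(), centre + r * u)
    } else {
      p <- spec$poses[[lab]]
      lig <- place_ligand(complex, p$rotation, p$com)
    }
    if (complex$jitter_sigma > 0)
      lig <- lig + matrix(stats::rnorm(3 * nl, 0, complex$jitter_sigma),
                          nl, 3)
    coords[complex$receptor_idx, , f] <- rec
    coords[complex$ligand_idx, , f] <- lig
  }
  list(trajectory = trajectory(complex$topology, coords),
       labels = labels, spec = spec)
}

#' Specify a gated two-site Langevin binding run
#'
#' Overdamped rigid-body dynamics of the ligand in a two-step binding
#' potential: a wide, weak capture funnel (`capture_depth`, `range_crs1`)
#' plus a narrow CRS1 docking well at a point flanking the arm
#' (`depth_crs1`, fixed 0.7 nm range).  When gated, the mechanism mimics
#' induced fit: once CRS1 docking is confirmed by a sustained contact
#' streak, a countdown of `gate_delay` steps runs, after which the CRS2
#' docking well (`depth_crs2`, `range_crs2`) activates, the CRS1 dock
#' releases, and the capture funnel recentres on the CRS2 site.  Until
#' that transition the extracellular loop site is inaccessible (a
#' reflecting floor above the loop ring), so a CRS1-before-CRS2 contact
#' order holds by construction and is verified by the event log.  A
#' soft-core repulsion around every receptor bead (with a hard floor at
#' 90% of its radius) and reflecting walls complete the model.
#'
#' @param depth_crs1,depth_crs2 Docking-well depths (kT, >= 0).
#' @param range_crs1 Capture-funnel range (nm); an engagement ordering
#'   ground truth requires `range_crs1 > range_crs2`.
#' @param range_crs2 CRS2 docking-well range (nm).
#' @param capture_depth Capture-funnel depth (kT).
#' @param rep_radius Soft-core repulsion radius around receptor beads (nm),
#'   acting on the ligand centre of mass.
#' @param k_rep Repulsion strength (kT).
#' @param gated Logical: CRS2 site inactive (and inaccessible) until CRS1
#'   engagement triggers the induced-fit transition.
#' @param gate_delay Induced-fit delay (steps): after CRS1 docking is
#'   confirmed (25 consecutive contact steps) the CRS2 site stays
#'   inactive for this many further steps, giving the two-step mechanism
#'   a genuine CRS1-bound dwell epoch.
#' @param D Translational diffusion coefficient (nm^2/ns).
#' @param rot_step SD of the per-step random rotation angle (rad).
#' @param dt Time step (ns, > 0).
#' @param n_steps Number of steps.
#' @param box Box lengths (nm); x and y walls at +-box/2, z walls at 0 and
#'   box.
#' @param start Initial ligand centre of mass (nm).
#' @param stride Store every `stride`-th step as a trajectory frame.
#' @param temperature Temperature (K), metadata for downstream energy units.
#' @param seed Integer seed.
#' @return An object of class `langevin_spec`.
#' @export
langevin_spec <- function(depth_crs1 = 12, range_crs1 = 3.5,
                          depth_crs2 = 14, range_crs2 = 0.8,
                          capture_depth = 5,
                          rep_radius = 0.6, k_rep = 100, gated = TRUE,
                          gate_delay = 2000L, D = 0.1, rot_step = 0.03, dt = 0.02,
                          n_steps = 30000L, box = c(12, 12, 12),
                          start = c(0.5, 0.5, 9), stride = 10L,
                          temperature = 303, seed = 1L) {
  if (dt <= 0) stop("langevin_spec: dt must be > 0")
  if (gated && range_crs1 <= range_crs2)
    stop("langevin_spec: ordering ground truth requires range_crs1 > range_crs2")
  structure(list(depth_crs1 = depth_crs1, range_crs1 = range_crs1,
                 depth_crs2 = depth_crs2, range_crs2 = range_crs2,
                 capture_depth = capture_depth,
                 rep_radius = rep_radius, k_rep = k_rep, gated = gated,
                 gate_delay = as.integer(gate_delay), D = D, rot_step = rot_step, dt = dt,
                 n_steps = as.integer(n_steps), box = box, start = start,
                 stride = as.integer(stride), temperature = temperature,
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

#' Simulate a gated two-site Langevin binding run
#'
#' Overdamped update of the ligand centre of mass,
#' `x <- x - D grad(U) dt + sqrt(2 D dt) xi` (energies in kT), with a small
#' random rigid rotation per step and reflecting walls.  The event log
#' records the first step at which any ligand-CRS1 (resp. ligand-CRS2)
#' residue pair comes within 0.5 nm; contact detection is unconditional
#' (independent of which wells are active).
#'
#' @param spec A [langevin_spec()].
#' @param complex A [toy_complex()].
#' @return List with `trajectory` (frames every `stride` steps), `events`
#'   (data frame: event, step, time, frame; `NA` if never formed) and
#'   `spec`.
#' @export
simulate_langevin <- function(spec, complex) {
  stopifnot(inherits(spec, "langevin_spec"), inherits(complex, "toy_complex"))
  set.seed(spec$seed)
  rec <- complex$ref_coords[complex$receptor_idx, , drop = FALSE]
  regions <- complex$regions
  top <- complex$topology
  i_crs1 <- region_indices(top, regions, "CRS1")
  i_crs2 <- region_indices(top, regions, "CRS2")
  crs1 <- rec[i_crs1, , drop = FALSE]
  crs2 <- rec[i_crs2, , drop = FALSE]
  c1 <- colMeans(crs1)
  # CRS1 dock: a point flanking the arm at mid-height, just outside the
  # repulsion floor, so the docked ligand keeps persistent arm contacts
  b1 <- crs1[21, ]
  u1 <- c(b1[1], b1[2], 0); u1 <- u1 / sqrt(sum(u1^2))
  dock1 <- b1 + (0.9 * spec$rep_radius + 0.05) * u1
  # CRS2 target: radially outside the loop ring and slightly below it, so
  # the docked ligand forms side contacts with CRS2 while staying out of
  # reach of the CRS1 arm (the two sites' contacts are then exclusive)
  c2 <- colMeans(crs2[1:3, , drop = FALSE]) * c(1.55, 1.55, 1) + c(0, 0, -0.4)
  lo <- c(-spec$box[1] / 2, -spec$box[2] / 2, 0.2)
  hi <- c(spec$box[1] / 2, spec$box[2] / 2, spec$box[3])
  # gated accessibility: until the induced-fit transition opens the loop
  # site, the ligand explores only the receptor apex -- a reflecting
  # floor above the loop ring makes CRS2 contact geometrically
  # impossible before CRS1 engagement (two-step ordering by construction)
  z_closed <- 3.9

  well_grad <- function(x, centre, depth, range) {
    d <- x - centre
    depth * exp(-sum(d^2) / (2 * range^2)) * d / range^2
  }
  grad_U <- function(x, crs2_on) {
    # wide capture funnel centred on the active site (it relocates with
    # the induced-fit handover); the narrow dock wells swap at the gate
    if (crs2_on) {
      g <- well_grad(x, c2, spec$capture_depth, spec$range_crs1) +
        well_grad(x, c2, spec$depth_crs2, spec$range_crs2)
    } else {
      g <- well_grad(x, c1, spec$capture_depth, spec$range_crs1) +
        well_grad(x, dock1, spec$depth_crs1, 0.7)
    }
    dv <- sweep(rec, 2, x, "-")          # bead - x
    r <- sqrt(rowSums(dv^2))
    inside <- r < spec$rep_radius & r > 1e-9
    if (any(inside)) {
      # U = k (1 - r/r0)^2 rises towards the bead, so grad U points
      # along dv = bead - x with magnitude 2k(1 - r/r0)/r0
      mag <- 2 * spec$k_rep * (1 - r[inside] / spec$rep_radius) /
        spec$rep_radius
      g <- g + colSums(dv[inside, , drop = FALSE] * (mag / r[inside]))
    }
    g
  }

  x <- spec$start
  rot <- diag(3)
  sigma <- sqrt(2 * spec$D * spec$dt)
  n_keep <- spec$n_steps %/% spec$stride
  np <- nrow(complex$ref_coords)
  coords <- array(NA_real_, c(np, 3, n_keep))
  times <- numeric(n_keep)
  first_crs1 <- NA_integer_; first_crs2 <- NA_integer_
  crs1_streak <- 0L                      # consecutive CRS1-contact steps
  locked_step <- NA_integer_             # confirmed docking at CRS1
  big_steps <- 0L
  kf <- 0L
  for (step in seq_len(spec$n_steps)) {
    crs2_on <- !spec$gated ||
      (!is.na(locked_step) && step >= locked_step + spec$gate_delay)
    lo[3] <- if (spec$gated && !crs2_on) z_closed else 0.2
    disp <- -spec$D * grad_U(x, crs2_on) * spec$dt +
      sigma * stats::rnorm(3)
    if (sqrt(sum(disp^2)) > spec$rep_radius / 2) big_steps <- big_steps + 1L
    x <- x + disp
    # reflecting walls
    for (k in 1:3) {
      if (x[k] < lo[k]) x[k] <- 2 * lo[k] - x[k]
      if (x[k] > hi[k]) x[k] <- 2 * hi[k] - x[k]
    }
    # hard floor at 90% of the repulsion radius: project the COM out of
    # any bead's core so the soft spring can stay integrator-friendly
    floor_r <- 0.9 * spec$rep_radius
    for (pass in 1:25) {
      dv <- sweep(rec, 2, x, "-")
      r <- sqrt(rowSums(dv^2))
      deep <- which(r < floor_r - 1e-12)
      if (!length(deep)) break
      w <- deep[which.min(r[deep])]
      x <- rec[w, ] + (x - rec[w, ]) * ((floor_r + 1e-9) / max(r[w], 1e-9))
    }
    ang <- stats::rnorm(1, 0, spec$rot_step)
    ax <- stats::rnorm(3)
    rot <- axis_rotation(ax, ang) %*% rot
    lig <- place_ligand(complex, rot, x)
    crs1_contact <- min(cross_distances(lig, crs1)) < 0.5
    if (crs1_contact && is.na(first_crs1)) first_crs1 <- step
    crs1_streak <- if (crs1_contact) crs1_streak + 1L else 0L
    # induced-fit countdown starts only once docking is confirmed by a
    # sustained contact streak, so the CRS1-bound dwell epoch is genuine
    if (is.na(locked_step) && crs1_streak >= 25L) locked_step <- step
    if (is.na(first_crs2) && min(cross_distances(lig, crs2)) < 0.5)
      first_crs2 <- step
    if (step %% spec$stride == 0L) {
      kf <- kf + 1L
      coords[complex$receptor_idx, , kf] <- rec
      coords[complex$ligand_idx, , kf] <- lig
      times[kf] <- step * spec$dt
    }
  }
  if (big_steps > 0.001 * spec$n_steps)
    stop("simulate_langevin: ", big_steps, " steps exceeded half the ",
         "repulsion radius; reduce dt")
  step_to_frame <- function(s) if (is.na(s)) NA_integer_ else
    as.integer(ceiling(s / spec$stride))
  events <- data.frame(
    event = c("crs1_contact", "crs2_contact"),
    step = c(first_crs1, first_crs2),
    time = c(first_crs1, first_crs2) * spec$dt,
    frame = c(step_to_frame(first_crs1), step_to_frame(first_crs2)),
    stringsAsFactors = FALSE)
  list(trajectory = trajectory(complex$topology, coords, time = times,
                               box = spec$box),
       events = events, spec = spec)
}
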