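# Pipeline wiring: a validated run configuration, shipped parameter
# profiles, and a staged runner with a provenance manifest.

#' Shipped analysis parameter profiles
#'
#' Centralises the standard parameter sets: `"cg"` (coarse-grained) uses a
#' 0.5 nm contact/bound cutoff, switching parameters r0 = 0.9 nm, n = 6,
#' m = 12, temperature 303 K and a 10% map threshold; `"aa"` (atomistic)
#' uses a 0.4 nm cutoff, 300 K and a 25% map threshold.
#'
#' @param name `"cg"` or `"aa"`.
#' @return Named list of parameters.
#' @export
analysis_profile <- function(name = c("cg", "aa")) {
  name <- match.arg(name)
  switch(name,
         cg = list(contact_cutoff = 0.5, bound_threshold = 0.5,
                   switching = switching_params(0, 0.9, 6, 12),
                   temperature = 303, map_tau = 0.10),
         aa = list(contact_cutoff = 0.4, bound_threshold = 0.5,
                   switching = switching_params(0, 0.9, 6, 12),
                   temperature = 300, map_tau = 0.25))
}

#' Convert Angstrom to nm
#'
#' Cutoffs quoted in Angstrom (5 A, 4 A) convert to the package's internal
#' nm unit.
#'
#' @param x Lengths in Angstrom.
#' @return Lengths in nm.
#' @export
angstrom_to_nm <- function(x) x / 10

#' Assemble a validated run configuration
#'
#' @param complex A [toy_complex()] (or `NULL` when `trajectory_path` is
#'   given).
#' @param profile Profile name for [analysis_profile()].
#' @param seed Master seed; stage seeds derive from it via [derive_seed()].
#' @param out_dir Output directory (created).
#' @param n_frames Frames for the simulation stages.
#' @param weights,unbound_weight Mixture weights for `simulate_mixture`.
#' @param sel_a,sel_b Region names for the CV stage (coordination and COM
#'   distance); must resolve in the complex's region set.
#' @param bins FEL bin counts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(complex = toy_complex(), profile = "cg", seed = 1L,
                       out_dir = tempfile("bindscape_run_"),
                       n_frames = 2000L, weights = c(A = 0.6, B = 0.3),
                       unbound_weight = 0.1,
                       sel_a = "RECEPTOR", sel_b = "LIGAND",
                       bins = c(60, 60)) {
  prm <- analysis_profile(profile)
  if (prm$contact_cutoff <= 0 || prm$map_tau < 0)
    stop("run_config: thresholds must be positive")
  for (s in c(sel_a, sel_b))
    if (!s %in% names(complex$regions))
      stop("run_config: unresolvable region '", s, "'")
  structure(list(complex = complex, profile = profile, params = prm,
                 seed = as.integer(seed), out_dir = out_dir,
                 n_frames = as.integer(n_frames), weights = weights,
                 unbound_weight = unbound_weight,
                 sel_a = sel_a, sel_b = sel_b, bins = bins),
            class = "run_config")
}

#' Run pipeline stages in order
#'
#' Executes the requested stages in dependency order and writes a JSON
#' manifest (parameters, seeds, outputs with MD5 hashes).  Supported
#' stages: `"simulate_mixture"` (toy trajectory + ground-truth labels),
#' `"cv"` (COM distance, coordination, minimum interchain distance),
#' `"fel"` (landscape grid + basin summary), `"contacts"`
#' (contact-frequency matrix).  Unknown stage names fail before any work;
#' re-running a config reproduces deterministic outputs bit for bit.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate_mixture", "cv", "fel",
                                    "contacts")) {
  known <- c("simulate_mixture", "cv", "fel", "contacts")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("run_pipeline: unknown stage(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "))
  stages <- known[known %in% stages]     # dependency order
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  state <- list()
  emit <- function(name) outputs <<- c(outputs, file.path(config$out_dir, name))

  for (stage in stages) {
    message("stage: ", stage)
    if (stage == "simulate_mixture") {
      poses <- default_poses(config$complex)
      spec <- mixture_spec(poses, config$weights, config$unbound_weight,
                           n_frames = config$n_frames,
                           seed = derive_seed(config$seed, 1L))
      sim <- sample_mixture(spec, config$complex)
      state$sim <- sim
      write_trajectory(sim$trajectory,
                       file.path(config$out_dir, "trajectory.xyz"),
                       "xyz_frames")
      write_table(data.frame(frame = seq_along(sim$labels),
                             label = sim$labels),
                  file.path(config$out_dir, "labels.csv"), "csv")
      jsonlite::write_json(
        list(weights = as.list(config$weights),
             unbound_weight = config$unbound_weight,
             n_frames = config$n_frames, seed = spec$seed),
        file.path(config$out_dir, "mixture_spec.json"), auto_unbox = TRUE)
      emit("trajectory.xyz"); emit("labels.csv"); emit("mixture_spec.json")
    } else if (stage == "cv") {
      traj <- pipeline_traj(config, state)
      rg <- config$complex$regions
      d <- com_distance(traj, rg, config$sel_a, config$sel_b)
      co <- coordination_number(traj, rg, config$sel_a, config$sel_b,
                                config$params$switching)
      md <- min_interchain_distance(traj, "R", "L")
      state$cv <- list(d = d, coord = co, mindist = md)
      write_table(data.frame(frame = seq_along(d), time = traj$time,
                             com_distance = as.numeric(d),
                             coordination = as.numeric(co),
                             min_distance = as.numeric(md)),
                  file.path(config$out_dir, "cv.csv"), "csv")
      emit("cv.csv")
    } else if (stage == "fel") {
      if (is.null(state$cv)) stop("run_pipeline: 'fel' requires 'cv'")
      grid <- build_fel(state$cv$d, state$cv$coord, bins = config$bins,
                        temperature = config$params$temperature)
      basins <- find_basins(grid)
      state$fel <- list(grid = grid, basins = basins)
      centers <- expand.grid(d = grid$d_centers, coord = grid$coord_centers)
      write_table(data.frame(centers,
                             count = as.numeric(grid$counts),
                             P = as.numeric(grid$P),
                             F = as.numeric(grid$F),
                             basin = as.integer(basins$labels)),
                  file.path(config$out_dir, "fel.csv"), "csv")
      jsonlite::write_json(basins$summary,
                           file.path(config$out_dir, "basins.json"),
                           dataframe = "rows", digits = NA)
      emit("fel.csv"); emit("basins.json")
    } else if (stage == "contacts") {
      traj <- pipeline_traj(config, state)
      map <- contact_frequency(traj, "R", "L",
                               cutoff = config$params$contact_cutoff)
      state$map <- map
      m <- map$mat
      dimnames(m) <- list(map$receptor_res, map$ligand_res)
      utils::write.csv(m, file.path(config$out_dir, "contact_map.csv"))
      emit("contact_map.csv")
    }
  }
  manifest <- list(
    package = "bindscape",
    version = as.character(utils::packageVersion("bindscape")),
    profile = config$profile, seed = config$seed,
    parameters = list(contact_cutoff = config$params$contact_cutoff,
                      bound_threshold = config$params$bound_threshold,
                      temperature = config$params$temperature,
                      map_tau = config$params$map_tau,
                      bins = config$bins,
                      weights = as.list(config$weights),
                      unbound_weight = config$unbound_weight),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Trajectory for analysis stages: the simulated one, or re-simulate
# deterministically if the simulate stage was not requested this run.
pipeline_traj <- function(config, state) {
  if (!is.null(state$sim)) return(state$sim$trajectory)
  poses <- default_poses(config$complex)
  spec <- mixture_spec(poses, config$weights, config$unbound_weight,
                       n_frames = config$n_frames,
                       seed = derive_seed(config$seed, 1L))
  sample_mixture(spec, config$complex)$trajectory
}
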