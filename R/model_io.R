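# Names treated as backbone particles: CG backbone beads and the protein
# main-chain atoms of atomistic models.
BACKBONE_NAMES <- c("BB", "CA", "C", "N", "O")

#' Construct a molecular topology
#'
#' A topology is the static particle table shared by every frame of a
#' trajectory: one row per particle with its residue and chain labels.
#'
#' @param particles data frame with columns `particle_id` (unique integer,
#'   >= 0), `name` (particle/atom name), `residue_index` (1-based author
#'   numbering, non-decreasing within a chain), `residue_name` (3-letter
#'   code) and `chain_id` (single character).  An `is_backbone` logical
#'   column is derived from `name` when absent.
#' @return An object of class `topology`.
#' @export
topology <- function(particles) {
  req <- c("particle_id", "name", "residue_index", "residue_name", "chain_id")
  missing_cols <- setdiff(req, names(particles))
  if (length(missing_cols))
    stop("topology: missing columns: ", paste(missing_cols, collapse = ", "))
  particles <- as.data.frame(particles, stringsAsFactors = FALSE)
  if (anyDuplicated(particles$particle_id))
    stop("topology: particle_id values must be unique")
  if (any(particles$particle_id < 0))
    stop("topology: particle_id must be >= 0")
  if (is.null(particles$is_backbone))
    particles$is_backbone <- particles$name %in% BACKBONE_NAMES
  for (ch in unique(particles$chain_id)) {
    ri <- particles$residue_index[particles$chain_id == ch]
    if (is.unsorted(ri))
      stop("topology: residue_index must be non-decreasing within chain ", ch)
  }
  structure(list(particles = particles,
                 chains = sort(unique(particles$chain_id))),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d particles, %d residues, chains {%s}\n",
              nrow(x$particles),
              nrow(unique(x$particles[, c("chain_id", "residue_index")])),
              paste(x$chains, collapse = ", ")))
  invisible(x)
}

n_particles <- function(top) nrow(top$particles)

#' Construct a trajectory
#'
#' @param top A [topology()].
#' @param coords Numeric array of dimension `n_particles x 3 x n_frames`,
#'   coordinates in nm.
#' @param time Numeric vector of frame times in ns (monotone non-decreasing);
#'   defaults to `0, 1, 2, ...`.
#' @param box Optional length-3 orthorhombic box vector in nm (`NULL` for an
#'   unbounded system; no periodic imaging is applied).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(top, coords, time = NULL, box = NULL) {
  stopifnot(inherits(top, "topology"))
  if (length(dim(coords)) == 2L) # single frame
    coords <- array(coords, dim = c(dim(coords), 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L)
    stop("trajectory: coords must be an n_particles x 3 x n_frames array")
  if (d[1] != n_particles(top))
    stop("trajectory: coordinate count (", d[1], ") != particle count (",
         n_particles(top), ")")
  if (d[3] < 1L) stop("trajectory: at least one frame required")
  if (!all(is.finite(coords))) stop("trajectory: non-finite coordinates")
  if (is.null(time)) time <- seq_len(d[3]) - 1
  if (length(time) != d[3]) stop("trajectory: time length != frame count")
  if (is.unsorted(time)) stop("trajectory: time must be non-decreasing")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0))
      stop("trajectory: box must be 3 positive lengths (nm)")
  }
  structure(list(topology = top, coords = coords, time = as.numeric(time),
                 box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  print(x$topology)
  cat(sprintf("  %d frames, t = %.4g .. %.4g ns%s\n",
              n_frames(x), x$time[1], x$time[n_frames(x)],
              if (is.null(x$box)) " (unbounded)" else
                sprintf(", box %.3g x %.3g x %.3g nm", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `n_particles x 3` matrix (nm).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

# ---------------------------------------------------------------------------
# Region sets
# ---------------------------------------------------------------------------

#' Define a named set of residue-range selections
#'
#' Regions name the functionally relevant residue stretches used throughout
#' the analyses (e.g. the receptor N-terminal recognition site CRS1,
#' extracellular loops forming CRS2, ligand subregions).  Residue indices
#' use author numbering as read from the input file; overlapping ranges are
#' unioned.
#'
#' @param defs Named list; each element a list with `chain` (single
#'   character), `ranges` (list of `c(lo, hi)` residue-index pairs) and
#'   optionally `backbone` (logical, default `FALSE`: restrict the selection
#'   to backbone particles).
#' @return An object of class `region_set`.
#' @export
region_set <- function(defs) {
  if (is.null(names(defs)) || any(names(defs) == "") ||
      anyDuplicated(names(defs)))
    stop("region_set: definitions must have unique non-empty names")
  defs <- lapply(defs, function(d) {
    if (is.null(d$chain) || is.null(d$ranges) || length(d$ranges) == 0L)
      stop("region_set: each region needs a chain and a non-empty range list")
    ranges <- lapply(d$ranges, function(r) {
      r <- as.integer(r)
      if (length(r) == 1L) r <- c(r, r)
      if (length(r) != 2L || r[2] < r[1])
        stop("region_set: ranges must be c(lo, hi) with hi >= lo")
      r
    })
    resids <- sort(unique(unlist(lapply(ranges, function(r) r[1]:r[2]))))
    list(chain = as.character(d$chain), ranges = ranges, resids = resids,
         backbone = isTRUE(d$backbone))
  })
  structure(defs, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-10s chain %s, %d residues%s\n", nm, x[[nm]]$chain,
                length(x[[nm]]$resids),
                if (x[[nm]]$backbone) " (backbone)" else ""))
  invisible(x)
}

#' Load a region set from a YAML file
#'
#' Expected layout:
#' ```yaml
#' regions:
#'   CRS1: {chain: A, ranges: [[1, 31]], backbone: true}
#' ```
#' When a topology is supplied every referenced residue is validated
#' against it.
#'
#' @param path YAML file path.
#' @param top Optional [topology()] for validation.
#' @return A [region_set()].
#' @export
load_regions <- function(path, top = NULL) {
  doc <- yaml::read_yaml(path)
  defs <- if (!is.null(doc$regions)) doc$regions else doc
  rs <- region_set(defs)
  if (!is.null(top)) validate_regions(rs, top)
  rs
}

#' Validate a region set against a topology
#'
#' @param regions A [region_set()].
#' @param top A [topology()].
#' @return Invisibly `TRUE`; errors listing offending residues otherwise.
#' @export
validate_regions <- function(regions, top) {
  for (nm in names(regions)) {
    r <- regions[[nm]]
    present <- unique(top$particles$residue_index[
      top$particles$chain_id == r$chain])
    bad <- setdiff(r$resids, present)
    if (length(bad))
      stop("region '", nm, "': residues absent from chain ", r$chain, ": ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
  }
  invisible(TRUE)
}

#' Particle indices selected by a region
#'
#' @param traj A [trajectory()] (or a [topology()]).
#' @param regions A [region_set()].
#' @param name Region name.
#' @return Integer vector of particle row indices.
#' @export
region_indices <- function(traj, regions, name) {
  top <- if (inherits(traj, "trajectory")) traj$topology else traj
  if (!name %in% names(regions))
    stop("unknown region '", name, "'")
  r <- regions[[name]]
  p <- top$particles
  idx <- which(p$chain_id == r$chain & p$residue_index %in% r$resids &
                 (!r$backbone | p$is_backbone))
  if (length(idx) == 0L)
    stop("region '", name, "' selects no particles")
  idx
}

#' All particle indices of one chain
#' @param traj A [trajectory()] or [topology()].
#' @param chain Chain identifier.
#' @param backbone_only Restrict to backbone particles.
#' @return Integer vector of particle row indices.
#' @export
chain_indices <- function(traj, chain, backbone_only = FALSE) {
  top <- if (inherits(traj, "trajectory")) traj$topology else traj
  p <- top$particles
  idx <- which(p$chain_id == chain & (!backbone_only | p$is_backbone))
  if (length(idx) == 0L) stop("chain '", chain, "' selects no particles")
  idx
}

# ---------------------------------------------------------------------------
# Trajectory readers/writers
# ---------------------------------------------------------------------------

#' Read a trajectory from disk
#'
#' Two plain-text formats are supported: multi-model PDB (frames delimited
#' by MODEL/ENDMDL; coordinates converted from Angstrom to nm) and a simple
#' per-frame XYZ format (see [write_trajectory()]).  Residue numbering is
#' taken verbatim from the file (1-based author numbering, never
#' re-indexed).
#'
#' @param path Input file.
#' @param format `"pdb_multimodel"` or `"xyz_frames"`.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "xyz_frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         pdb_multimodel = read_pdb_frames(path),
         xyz_frames = read_xyz_frames(path))
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty input: no ATOM records in ", path)
  top <- topology(data.frame(
    particle_id = seq_len(nrow(at)) - 1L,
    name = trimws(at$elety),
    residue_index = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE))
  xyz <- pdb$xyz                      # n_frames x 3N, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  np <- nrow(at)
  coords <- array(NA_real_, c(np, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  trajectory(top, coords)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: ", path)
  frames <- list(); times <- numeric(); i <- 1L; top <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n <= 0L)
      stop("parse error at line ", i, ": expected particle count, got '",
           lines[i], "'")
    tline <- lines[i + 1L]
    t <- suppressWarnings(as.numeric(sub("^t=", "", tline)))
    if (is.na(t)) stop("parse error at line ", i + 1L,
                       ": expected 't=<ns>', got '", tline, "'")
    rows <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rows), "[[:space:]]+")
    if (any(lengths(fields) != 7L))
      stop("parse error near line ", i + 2L,
           ": expected 'chain resid resname name x y z'")
    m <- do.call(rbind, fields)
    xyz <- matrix(suppressWarnings(as.numeric(m[, 5:7])), ncol = 3)
    if (any(is.na(xyz)))
      stop("parse error near line ", i + 2L, ": non-numeric coordinate")
    if (is.null(top)) {
      top <- topology(data.frame(
        particle_id = seq_len(n) - 1L,
        name = m[, 4], residue_index = as.integer(m[, 2]),
        residue_name = m[, 3], chain_id = m[, 1],
        stringsAsFactors = FALSE))
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t)
    i <- i + 2L + n
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  trajectory(top, coords, time = times)
}

#' Write a trajectory to disk
#'
#' `pdb_multimodel` writes standard fixed-width ATOM records (nm converted
#' to Angstrom, so coordinates round-trip to ~1e-4 nm).  `xyz_frames` is a
#' plain whitespace format, per frame: a line with the particle count, a
#' line `t=<ns>`, then one `chain resid resname name x y z` line per
#' particle with coordinates in nm.
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @param format `"pdb_multimodel"` or `"xyz_frames"`.
#' @return Invisibly `path`.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "xyz_frames")) {
  format <- match.arg(format)
  p <- traj$topology$particles
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb_multimodel") {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- frame_coords(traj, f) * 10  # nm -> Angstrom
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        seq_len(nrow(p)) %% 100000L,
        formatC(substr(p$name, 1, 4), width = -4),
        substr(p$residue_name, 1, 3), p$chain_id, p$residue_index,
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      writeLines(as.character(nrow(p)), con)
      writeLines(sprintf("t=%.9g", traj$time[f]), con)
      writeLines(sprintf("%s %d %s %s %.9g %.9g %.9g",
                         p$chain_id, p$residue_index, p$residue_name,
                         p$name, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular results
# ---------------------------------------------------------------------------

#' Write a homogeneous record table
#'
#' CSV keeps numeric fields at full precision (15 significant digits); JSON
#' serialises NaN as `null`.  [read_table()] restores either format, mapping
#' JSON `null` in numeric columns back to `NaN`.
#'
#' @param records Data frame.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly `path`.
#' @export
write_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "csv") {
    num <- vapply(records, is.numeric, logical(1))
    out <- records
    out[num] <- lapply(records[num], function(x)
      ifelse(is.na(x), "NaN", formatC(x, digits = 17, format = "g")))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path Input file.
#' @param format `"csv"` or `"json"`.
#' @return Data frame; JSON `null` in numeric columns becomes `NaN`.
#' @export
read_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df[] <- lapply(df, function(x) {
      if (is.numeric(x)) { x[is.na(x)] <- NaN; x } else x
    })
    df
  }
}
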