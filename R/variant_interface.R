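# Missense-variant triage against the simulation-derived interface:
# pathogenicity bins, stability-prediction harmonisation, interface
# membership, and residue contact-network centralities.

AM_TOOLS_POSITIVE <- c("foldx", "mutabind2")   # positive ddG = destabilising
AM_TOOLS_NEGATIVE <- c("dynamut2", "ddmut-ppi") # negative ddG = destabilising

#' Classify a pathogenicity score into benign/ambiguous/pathogenic
#'
#' Bins follow the standard published intervals: 0-0.33 benign,
#' 0.34-0.564 ambiguous, 0.565-1 pathogenic.  Scores are rounded to three
#' decimals first; a rounded score falling in the residual 0.331-0.339
#' gap is assigned to the class of the nearer bin edge (midpoint 0.335
#' goes to ambiguous).
#'
#' @param score Numeric scores in `[0, 1]`, vectorised.
#' @return Character vector in `{"benign", "ambiguous", "pathogenic"}`.
#' @export
classify_pathogenicity <- function(score) {
  if (any(score < 0 | score > 1)) stop("classify_pathogenicity: score outside [0, 1]")
  s <- round(score, 3)
  out <- character(length(s))
  out[s <= 0.33] <- "benign"
  out[s > 0.33 & s < 0.335] <- "benign"       # nearer to the 0.33 edge
  out[s >= 0.335 & s <= 0.564] <- "ambiguous"
  out[s >= 0.565] <- "pathogenic"
  out
}

#' Harmonise a stability prediction and classify it
#'
#' Predictors disagree on the sign convention: FoldX and MutaBind2 report
#' positive ddG for destabilising mutations, DynaMut2 and DDMut-PPI report
#' negative ddG for destabilisation.  Values are unified to the FoldX
#' convention and thresholded at +-2 kcal/mol: unified ddG > 2 is
#' destabilising, < -2 stabilising, otherwise neutral.
#'
#' @param ddg ddG values in kcal/mol (vectorised).
#' @param tool Tool name(s): `"foldx"`, `"mutabind2"`, `"dynamut2"` or
#'   `"ddmut-ppi"` (case-insensitive).
#' @return Data frame with `ddg_unified` (kcal/mol, FoldX convention) and
#'   `class` in `{"destabilizing", "stabilizing", "neutral"}`.
#' @export
classify_stability <- function(ddg, tool) {
  tool <- tolower(tool)
  if (length(tool) == 1L) tool <- rep(tool, length(ddg))
  bad <- !(tool %in% c(AM_TOOLS_POSITIVE, AM_TOOLS_NEGATIVE))
  if (any(bad))
    stop("classify_stability: unknown tool(s) ",
         paste(unique(tool[bad]), collapse = ", "),
         "; supported: ", paste(c(AM_TOOLS_POSITIVE, AM_TOOLS_NEGATIVE),
                                collapse = ", "),
         " (positive-destabilising: ", paste(AM_TOOLS_POSITIVE, collapse = ", "),
         "; negative-destabilising: ", paste(AM_TOOLS_NEGATIVE, collapse = ", "), ")")
  unified <- ifelse(tool %in% AM_TOOLS_NEGATIVE, -ddg, ddg)
  cls <- ifelse(unified > 2, "destabilizing",
                ifelse(unified < -2, "stabilizing", "neutral"))
  data.frame(ddg_unified = unified, class = cls, stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Expected CSV header: `protein,position,ref,alt,score[,tool,ddg]`.
#'
#' @param path CSV file.
#' @return Data frame of variants with validated `score` in `[0, 1]`.
#' @export
read_variants <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("protein", "position", "ref", "alt", "score")
  missing_cols <- setdiff(req, names(v))
  if (length(missing_cols))
    stop("read_variants: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(v$score < 0 | v$score > 1))
    stop("read_variants: score outside [0, 1]")
  v
}

#' Flag variants at the binding interface
#'
#' A variant is at the interface iff its residue participates in at least
#' one contact surviving [threshold_map()] at `tau`.  Residues absent from
#' the map axis are flagged `FALSE` with a warning (not an error), so
#' tables mixing proteins pass through.
#'
#' @param variants Data frame with `position` (and optionally `protein`).
#' @param map A [contact_frequency()] result.
#' @param tau Persistence threshold.
#' @param axis Which map axis the variants' protein corresponds to:
#'   `"receptor"` or `"ligand"`.
#' @return `variants` with added logical `interface` column (and
#'   `pathogenicity_class` if a `score` column is present).
#' @export
flag_interface <- function(variants, map, tau = 0.10,
                           axis = c("receptor", "ligand")) {
  axis <- match.arg(axis)
  hs <- hotspots(map, tau)
  iface_res <- if (axis == "receptor") hs$receptor$residue else
    hs$ligand$residue
  axis_res <- if (axis == "receptor") map$receptor_res else map$ligand_res
  off_axis <- !(variants$position %in% axis_res)
  if (any(off_axis))
    warning("flag_interface: ", sum(off_axis),
            " variant position(s) absent from the map axis; flagged FALSE")
  variants$interface <- variants$position %in% iface_res
  if (!is.null(variants$score))
    variants$pathogenicity_class <- classify_pathogenicity(variants$score)
  variants
}

#' Residue contact-network centralities of one structure frame
#'
#' Builds the residue contact graph of a single frame (nodes = residues;
#' an edge joins two residues iff any interparticle distance is strictly
#' below the cutoff and the residues are not sequence-adjacent — within
#' one chain, `|delta index| >= 2` — so centralities reflect tertiary
#' contacts).  Degree, betweenness and closeness follow standard
#' unweighted shortest-path definitions; betweenness and closeness are
#' normalised per connected component, and isolated residues score 0.
#'
#' @param traj A [trajectory()] (first frame used unless `frame` given).
#' @param cutoff Edge cutoff in nm (default 0.5).
#' @param frame Frame index (default 1).
#' @return Data frame with `chain`, `residue`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
residue_network <- function(traj, cutoff = 0.5, frame = 1) {
  p <- traj$topology$particles
  xyz <- frame_coords(traj, frame)
  key <- paste(p$chain_id, p$residue_index)
  res <- !duplicated(key)
  res_chain <- p$chain_id[res]
  res_idx <- p$residue_index[res]
  nres <- sum(res)
  grp <- match(key, key[res])
  # residue-residue minimum distances
  edges <- NULL
  dall <- as.matrix(stats::dist(xyz))
  for (i in seq_len(nres - 1)) {
    pi_ <- which(grp == i)
    for (j in (i + 1):nres) {
      same_chain <- res_chain[i] == res_chain[j]
      if (same_chain && abs(res_idx[i] - res_idx[j]) < 2) next
      pj <- which(grp == j)
      if (min(dall[pi_, pj]) < cutoff)
        edges <- rbind(edges, c(i, j))
    }
  }
  out <- data.frame(chain = res_chain, residue = res_idx,
                    degree = 0L, betweenness = 0, closeness = 0)
  if (is.null(edges)) {
    warning("residue_network: no contacts below cutoff; empty graph")
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nres - igraph::vcount(g)))
  out$degree <- igraph::degree(g)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2) next     # isolated: closeness/betweenness 0
    sub <- igraph::induced_subgraph(g, members)
    out$closeness[members] <- igraph::closeness(sub, normalized = TRUE)
    out$betweenness[members] <- igraph::betweenness(sub, normalized = TRUE)
  }
  out
}
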