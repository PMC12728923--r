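test_that("pathogenicity bins reproduce the published boundaries", {
  expect_equal(classify_pathogenicity(0.10), "benign")
  expect_equal(classify_pathogenicity(0.50), "ambiguous")
  expect_equal(classify_pathogenicity(0.90), "pathogenic")
  # exact boundary probes
  expect_equal(classify_pathogenicity(c(0.33, 0.34, 0.564, 0.565)),
               c("benign", "ambiguous", "ambiguous", "pathogenic"))
  # the 0.33-0.34 gap resolves to the nearer edge after 3-decimal rounding
  expect_equal(classify_pathogenicity(0.332), "benign")
  expect_equal(classify_pathogenicity(0.338), "ambiguous")
  expect_equal(classify_pathogenicity(0.5648), "pathogenic")  # rounds to 0.565
  expect_error(classify_pathogenicity(1.2), "outside")
  expect_error(classify_pathogenicity(-0.1), "outside")
})

test_that("stability classification unifies tool sign conventions", {
  expect_equal(classify_stability(2.2, "foldx")$class, "destabilizing")
  expect_equal(classify_stability(-2.5, "dynamut2")$class, "destabilizing")
  expect_equal(classify_stability(-2.5, "dynamut2")$ddg_unified, 2.5)
  expect_equal(classify_stability(1.0, "foldx")$class, "neutral")
  expect_equal(classify_stability(-3.0, "mutabind2")$class, "stabilizing")
  expect_equal(classify_stability(3.0, "ddmut-ppi")$class, "stabilizing")
  # exactly +-2 is neutral (strict thresholds)
  expect_equal(classify_stability(2.0, "foldx")$class, "neutral")
  expect_error(classify_stability(1.0, "rosetta"), "supported")
  v <- classify_stability(c(2.2, -2.5), c("foldx", "dynamut2"))
  expect_equal(v$class, c("destabilizing", "destabilizing"))
})

test_that("variant tables read, validate, and annotate", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("protein,position,ref,alt,score,tool,ddg",
               "LIG,2,F,S,0.9,foldx,2.2",
               "LIG,39,P,T,0.2,foldx,0.5",
               "REC,15,R,Q,0.7,,"), path)
  v <- read_variants(path)
  expect_equal(nrow(v), 3)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("protein,position,ref,alt,score", "X,1,A,V,1.4"), bad)
  expect_error(read_variants(bad), "score")
  writeLines(c("protein,position,alt,score", "X,1,V,0.4"), bad)
  expect_error(read_variants(bad), "missing columns")
})

test_that("interface flags follow the thresholded contact map monotonically", {
  fx <- get_mixture_fixture()
  m <- contact_frequency(fx$trajectory, "R", "L", cutoff = 0.5)
  hs <- hotspots(m, 0.10)
  iface <- hs$ligand$residue[1]
  cold <- setdiff(fx$complex$regions$LIGAND$resids, hs$ligand$residue)[1]
  variants <- data.frame(protein = "LIG", position = c(iface, cold, 999),
                         ref = "A", alt = "V", score = c(0.9, 0.2, 0.5))
  expect_warning(out <- flag_interface(variants, m, tau = 0.10,
                                       axis = "ligand"), "absent")
  expect_true(out$interface[1])
  expect_false(out$interface[2])
  expect_false(out$interface[3])
  expect_equal(out$pathogenicity_class,
               c("pathogenic", "benign", "ambiguous"))
  # raising tau never adds flagged variants
  for (tau in c(0.10, 0.25, 0.50, 0.75)) {
    flagged <- suppressWarnings(
      flag_interface(variants, m, tau, axis = "ligand")$interface)
    if (tau == 0.10) prev <- flagged
    expect_true(all(!flagged | prev))
    prev <- flagged
  }
})

test_that("residue contact network reproduces hand-computed centralities", {
  # 3 residues in a path A-B-C (sequence-adjacency exclusion forces the
  # chain split): put B on its own chain so edges A-B and B-C survive
  top <- topology(data.frame(
    particle_id = 0:2, name = "BB", residue_index = c(1L, 1L, 2L),
    residue_name = "X", chain_id = c("A", "B", "A"),
    stringsAsFactors = FALSE))
  xyz <- matrix(c(0, 0, 0, 0.4, 0, 0, 0.8, 0, 0), 3, byrow = TRUE)
  traj <- trajectory(top, array(xyz, c(3, 3, 1)))
  net <- residue_network(traj, cutoff = 0.45)
  b <- net[net$chain == "B", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$betweenness, 1)          # normalised, n = 3
  expect_equal(b$closeness, 1)
  ends <- net[net$chain == "A", ]
  expect_true(all(ends$degree == 1L))
  expect_true(all(ends$betweenness == 0))
  # fully connected triangle: everyone's betweenness is zero
  top3 <- topology(data.frame(
    particle_id = 0:2, name = "BB", residue_index = 1L,
    residue_name = "X", chain_id = c("A", "B", "C"),
    stringsAsFactors = FALSE))
  xyz2 <- matrix(c(0, 0, 0, 0.3, 0, 0, 0.15, 0.25, 0), 3, byrow = TRUE)
  net2 <- residue_network(trajectory(top3, array(xyz2, c(3, 3, 1))),
                          cutoff = 0.45)
  expect_true(all(net2$betweenness == 0))
  expect_true(all(net2$degree == 2L))
  # isolated residue scores zero degree and closeness
  xyz3 <- matrix(c(0, 0, 0, 0.4, 0, 0, 9, 9, 9), 3, byrow = TRUE)
  net3 <- residue_network(trajectory(top, array(xyz3, c(3, 3, 1))),
                          cutoff = 0.45)
  iso <- net3[net3$chain == "A" & net3$residue == 2, ]
  expect_equal(iso$degree, 0L)
  expect_equal(iso$closeness, 0)
  # contact-free frame warns, all-zero stats
  far <- matrix(c(0, 0, 0, 5, 0, 0, 9, 9, 9), 3, byrow = TRUE)
  expect_warning(net4 <- residue_network(
    trajectory(top, array(far, c(3, 3, 1))), cutoff = 0.45), "empty")
  expect_true(all(net4$degree == 0))
})

test_that("sequence-adjacent residues are excluded from the network", {
  # consecutive residues on one chain within cutoff: no edge
  top <- tiny_topology(3)
  xyz <- matrix(c(0, 0, 0, 0.3, 0, 0, 0.6, 0, 0), 3, byrow = TRUE)
  expect_warning(net <- residue_network(
    trajectory(top, array(xyz, c(3, 3, 1))), cutoff = 0.45), "empty")
  # residues 1 and 3 are non-adjacent: bring them close -> one edge
  xyz2 <- matrix(c(0, 0, 0, 5, 5, 5, 0.4, 0, 0), 3, byrow = TRUE)
  net2 <- residue_network(trajectory(top, array(xyz2, c(3, 3, 1))),
                          cutoff = 0.45)
  expect_equal(net2$degree[net2$residue %in% c(1, 3)], c(1L, 1L))
})
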