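# Bond graph construction, angle/dihedral enumeration, native geometry,
# coarse-graining and topology assembly.

test_that("bond graph of a CA chain is the chain backbone", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  st <- make_fixture("ca_helix", 10)
  g <- build_bond_graph(st, tset)
  expect_equal(nrow(g$edges), 9L)
  expect_true(all(g$provenance == "inter_residue"))
  expect_equal(g$edges[, 2] - g$edges[, 1], rep(1L, 9))
})

test_that("chains are not covalently joined unless a user bond says so", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  st <- make_fixture("two_chain", 5)
  g <- build_bond_graph(st, tset)
  expect_equal(nrow(g$edges), 8L)   # 4 + 4, no inter-chain edge
  expect_true(all(st$atoms$chain_idx[g$edges[, 1]] == st$atoms$chain_idx[g$edges[, 2]]))
  st2 <- sbm_structure(st$atoms, chain_breaks = st$chain_breaks,
                       extra_bonds = rbind(c(5L, 6L)))
  g2 <- build_bond_graph(st2, tset)
  expect_equal(nrow(g2$edges), 9L)
  expect_true("user_extra" %in% g2$provenance)
})

test_that("all-atom bond graph matches the hand-enumerated bond list", {
  tset <- parse_template_set(bundled_template("sbm_aa"))
  st <- make_tripeptide()
  g <- build_bond_graph(st, tset)
  label <- paste0(st$atoms$resseq, st$atoms$name)
  got <- sort(apply(g$edges, 1, function(e) paste(sort(label[e]), collapse = "-")))
  want <- sort(vapply(tripeptide_expected_bonds(),
                      function(b) paste(sort(b), collapse = "-"), ""))
  expect_equal(got, want)
})

test_that("missing template bond atoms are reported", {
  tset <- parse_template_set(bundled_template("sbm_aa"))
  st <- make_tripeptide()
  at <- st$atoms[st$atoms$name != "CB" | st$atoms$resseq != 1, ]
  expect_error(build_bond_graph(sbm_structure(at), tset), "CB")
})

test_that("angle/dihedral enumeration matches brute force on random graphs", {
  keyset <- function(m) sort(apply(m, 1, paste, collapse = "-"))
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    g <- random_graph(n)
    expect_equal(keyset(enumerate_angles(g)), keyset(ref_enum_angles(n, g$edges)))
    expect_equal(keyset(enumerate_dihedrals(g)), keyset(ref_enum_dihedrals(n, g$edges)))
  }
})

test_that("enumeration handles chains, stars and degenerate graphs", {
  chain3 <- structure(list(n = 3, edges = rbind(c(1L, 2L), c(2L, 3L)),
                           provenance = rep("x", 2)), class = "sbm_bondgraph")
  expect_equal(nrow(enumerate_angles(chain3)), 1L)
  expect_equal(nrow(enumerate_dihedrals(chain3)), 0L)
  single <- structure(list(n = 2, edges = rbind(c(1L, 2L)), provenance = "x"),
                      class = "sbm_bondgraph")
  expect_equal(nrow(enumerate_angles(single)), 0L)
  star <- structure(list(n = 4, edges = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                         provenance = rep("x", 3)), class = "sbm_bondgraph")
  expect_equal(nrow(enumerate_angles(star)), 3L)
  expect_equal(nrow(enumerate_dihedrals(star)), 0L)
  # unbranched chain of N atoms: N-2 angles, N-3 dihedrals
  for (N in c(5, 9)) {
    g <- structure(list(n = N, edges = cbind(1:(N - 1), 2:N),
                        provenance = rep("x", N - 1)), class = "sbm_bondgraph")
    expect_equal(nrow(enumerate_angles(g)), N - 2)
    expect_equal(nrow(enumerate_dihedrals(g)), N - 3)
  }
})

test_that("native geometry measurement follows the stated conventions", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0.38))
  expect_equal(measure_geometry(xyz, c(1, 2)), 0.38)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(measure_geometry(collinear, c(1, 2, 3)), pi)
  # cis arrangement -> 0; trans -> pi
  cis <- make_fixture("planar_four", phi = 0)
  expect_equal(measure_geometry(cis, c(1, 2, 3, 4)), 0, tolerance = 1e-12)
  trans <- make_fixture("planar_four", phi = pi)
  expect_equal(abs(measure_geometry(trans, c(1, 2, 3, 4))), pi, tolerance = 1e-12)
  # degenerate inputs are rejected
  expect_error(measure_geometry(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), 1:3),
               "degenerate")
  expect_error(measure_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), 1:4),
               "degenerate")
})

test_that("dihedral sign convention matches an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(5)
  for (rep in 1:25) {
    xyz <- matrix(stats::rnorm(12), 4, 3)
    got <- tryCatch(measure_geometry(xyz, 1:4), error = function(e) NA)
    if (is.na(got)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(xyz))) * pi / 180
    expect_equal(got, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("coarse-graining keeps the designated atom per residue", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  ci2 <- make_ci2_synthetic()
  cg <- coarse_grain(ci2, tset)
  expect_equal(nrow(cg$atoms), 64L)
  expect_true(all(cg$atoms$name == "CA"))
  cas <- ci2$atoms[ci2$atoms$name == "CA", c("x", "y", "z")]
  expect_equal(coords(cg), as.matrix(cas), ignore_attr = TRUE)
  # already coarse-grained input is the identity on positions
  cg2 <- coarse_grain(cg, tset)
  expect_equal(coords(cg2), coords(cg), ignore_attr = TRUE)
  # a residue without its designated atom is an error
  at <- ci2$atoms[-1, ]  # drop residue 1 CA
  expect_error(coarse_grain(sbm_structure(at), tset), "designated")
})

test_that("SBM_CA topology carries the template worked-example parameters", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  st <- make_fixture("ca_helix", 10)
  top <- assemble_topology(st, tset, NULL)
  expect_equal(top$bonds$k, rep(20000, 9))
  expect_equal(top$bonds$r0, rep(0.38, 9), tolerance = 1e-9)
  expect_equal(top$angles$ktheta, rep(40, 8))
  expect_equal(top$dihedrals$kd, rep(1, 7))
  expect_equal(nrow(top$contacts), 0L)   # zero contacts is a valid topology
  # native values equal measured geometry
  for (r in 1:3) {
    expect_equal(top$angles$theta0[r],
                 measure_geometry(coords(st), unlist(top$angles[r, 1:3])))
    expect_equal(top$dihedrals$phi0[r],
                 measure_geometry(coords(st), unlist(top$dihedrals[r, 1:4])))
  }
})

test_that("exclusion invariants hold on assembled topologies", {
  top <- ci2_ca_topology()
  excl_key <- paste(top$exclusions[, 1], top$exclusions[, 2])
  # every contact pair is excluded from the generic nonbonded interaction
  expect_true(all(paste(top$contacts$i, top$contacts$j) %in% excl_key))
  # every pair within exclusion_depth bonds is excluded (chain: |i-j| <= 3)
  ij <- t(utils::combn(nrow(top$atoms), 2))
  near <- ij[ij[, 2] - ij[, 1] <= top$settings$exclusion_depth, , drop = FALSE]
  expect_true(all(paste(near[, 1], near[, 2]) %in% excl_key))
  # no pair is simultaneously a contact and a bond
  expect_false(any(paste(top$contacts$i, top$contacts$j) %in%
                   paste(top$bonds$i, top$bonds$j)))
})

test_that("coarse-grain-then-assemble equals assemble-on-pre-coarse-grained", {
  tset <- parse_template_set(bundled_template("sbm_ca"))
  ci2 <- make_ci2_synthetic()
  cg <- coarse_grain(ci2, tset)
  amap <- cutoff_contact_map(ci2, 0.8, 1)
  cmap <- map_contacts_to_cg(amap, attr(cg, "residue_of_atom"), cg, 4)
  top1 <- assemble_topology(cg, tset, cmap)
  # path 2: write the CG structure out, read it back, assemble
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cg, f)
  cg2 <- read_pdb(f)
  cmap2 <- sbm_contacts(cmap$entries, level = "residue", provenance = "cutoff")
  top2 <- assemble_topology(cg2, tset, cmap2)
  expect_equal(top2$bonds, top1$bonds, tolerance = 1e-4)
  expect_equal(top2$angles, top1$angles, tolerance = 1e-3)
  expect_equal(top2$contacts$eps, top1$contacts$eps)
  expect_equal(nrow(top2$dihedrals), nrow(top1$dihedrals))
})

test_that("energy normalization rescales the contact/dihedral balance", {
  top <- ci2_ca_topology()
  out <- normalize_energies(top, ratio = 2, total = 128)
  expect_equal(sum(out$contacts$eps) / sum(out$dihedrals$kd), 2, tolerance = 1e-12)
  expect_equal(sum(out$contacts$eps) + sum(out$dihedrals$kd), 128, tolerance = 1e-12)
})
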