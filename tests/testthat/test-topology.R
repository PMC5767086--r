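test_that("alanine is a single apolar bead and asparagine a lone polar site", {
  ala <- build_peptide_topology("A", version = "2.4")
  expect_identical(n_sites(ala), 1L)
  expect_identical(ala$sites$site_type, "ap")

  asn <- build_peptide_topology("N", version = "2.4")
  expect_identical(n_sites(asn), 2L)
  expect_identical(asn$sites$site_type, c("p", "p"))
  expect_equal(asn$bonds$r0, 0.26)
})

test_that("lysine Cbeta is apolar in v1 but polar in v2.4", {
  sc1 <- sidechain_template("LYS", "1")
  sc24 <- sidechain_template("LYS", "2.4")
  expect_identical(sc1$type, c("ap", "pos"))
  expect_identical(sc24$type, c("p", "pos"))
})

test_that("version-resolved site reassignments follow the 2.4 scheme", {
  # Phe polar Cdelta; Tyr polar Cgamma+Cepsilon; Trp polar Cgamma;
  # Gln/Arg/Asp/Glu polar Cbeta; Cys apolar; Val two apolar sites
  expect_identical(sidechain_template("PHE", "2.4")$type,
                   c("ap", "ap", "p"))
  expect_identical(sidechain_template("TYR", "2.4")$type,
                   c("ap", "p", "p"))
  tw <- sidechain_template("TRP", "2.4")
  expect_identical(tw$type[tw$name == "CG"], "p")
  expect_identical(sum(tw$type == "ap"), 3L)
  expect_identical(sidechain_template("GLN", "2.4")$type[1], "p")
  expect_identical(sidechain_template("GLN", "1")$type[1], "ap")
  expect_identical(sidechain_template("CYS", "2.4")$type, "ap")
  expect_identical(sidechain_template("CYS", "1")$type, "p")
  expect_identical(sidechain_template("VAL", "2.4")$type, c("ap", "ap"))
  expect_identical(sidechain_template("VAL", "1")$type, "ap")
  expect_identical(sidechain_template("HIS", "2.4")$type, c("ap", "p", "p"))
  # Leu/Val short 1.6 A Cb-Cg bond vs 2.5 A for Met/Ile
  expect_equal(sidechain_template("LEU", "2.4")$r0[2], 0.16)
  expect_equal(sidechain_template("VAL", "2.4")$r0[2], 0.16)
  expect_equal(sidechain_template("ILE", "2.4")$r0[2], 0.25)
  expect_equal(sidechain_template("MET", "2.4")$r0[2], 0.25)
})

test_that("every sidechain has at most four sites in every version", {
  for (v in c("1", "2.3", "2.4"))
    for (res in unique(cgmemb:::.aa1to3))
      expect_lte(nrow(sidechain_template(res, v)), 4L)
})

test_that("v2.4 uses no ca sites while v1 backbones are all ca", {
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  t24 <- build_peptide_topology(seq20, version = "2.4")
  expect_false("ca" %in% t24$sites$site_type)
  expect_setequal(unique(t24$sites$site_type[t24$sites$name == "CA"]),
                  c("p", "ap"))
  ca24 <- t24$sites[t24$sites$name == "CA", ]
  expect_identical(ca24$site_type[ca24$residue_name == "ALA"], "ap")
  expect_true(all(ca24$site_type[ca24$residue_name != "ALA"] == "p"))
  t1 <- build_peptide_topology(seq20, version = "1")
  expect_identical(unique(t1$sites$site_type[t1$sites$name == "CA"]), "ca")
})

test_that("invalid sequences are rejected", {
  expect_error(build_peptide_topology(""), "non-empty")
  expect_error(build_peptide_topology("AXZ"), "unknown residue")
})

test_that("charged termini replace the terminal backbone types", {
  tp <- build_peptide_topology("GGG", termini = "charged")
  ca <- tp$sites[tp$sites$name == "CA", ]
  expect_identical(ca$site_type, c("pos", "p", "neg"))
})

test_that("helix restraints add N-2 angle and N-3 torsion terms", {
  walp <- build_peptide_topology(peptide_sequence("WALP23"))
  walp <- apply_helix_restraints(walp)
  expect_identical(nrow(walp$g96_angles), 21L)
  expect_identical(nrow(walp$torsions), 20L)
  expect_equal(unique(walp$g96_angles$theta0), 89)
  expect_equal(unique(walp$torsions$phi0), 50)
  expect_equal(unique(walp$g96_angles$k_theta), 2000)
  expect_equal(unique(walp$torsions$k_phi), 2000)
  expect_error(apply_helix_restraints(build_peptide_topology("AA")),
               "at least 3")
})

test_that("restraint energies vanish at their target geometry", {
  # triplet at exactly 89 degrees
  th <- 89 * pi / 180
  sites <- data.frame(name = "CA", site_type = "p", mass = 56,
                      residue_index = 1:3, residue_name = "GLY",
                      group = "X")
  topo <- cg_topology(sites,
                      g96_angles = data.frame(ai = 1, aj = 2, ak = 3,
                                              theta0 = 89, k_theta = 2000))
  pos <- rbind(c(0.38, 0, 0), c(0, 0, 0),
               0.38 * c(cos(th), sin(th), 0)) + 3
  ff <- make_toy_forcefield("p", kind = "flat")
  fc <- compute_forces(simulation_state(pos, box = c(6, 6, 6)), topo, ff)
  expect_lt(abs(fc$energies["g96_angle"]), 1e-10)
  expect_lt(max(abs(fc$forces)), 1e-6)

  # helix quadruplet near the 50-degree torsion target
  helix <- build_ideal_helix(4)
  sites4 <- data.frame(name = "CA", site_type = "p", mass = 56,
                       residue_index = 1:4, residue_name = "GLY",
                       group = "X")
  topo4 <- cg_topology(sites4,
                       torsions = data.frame(ai = 1, aj = 2, ak = 3, al = 4,
                                             phi0 = 50, k_phi = 2000))
  fc4 <- compute_forces(simulation_state(helix + 3, box = c(6, 6, 6)),
                        topo4, ff)
  expect_lt(fc4$energies["torsion"], 0.01)   # 0.04 deg off the target
})

test_that("tilt vector residue pairs match the published convention", {
  expect_identical(tilt_vector_residues("LS3"), c(5L, 16L))
  expect_identical(tilt_vector_residues("WALP23"), c(5L, 19L))
  expect_identical(tilt_vector_residues("L24"), c(8L, 26L))
  expect_identical(tilt_vector_residues("LA12"), c(8L, 26L))
  expect_error(tilt_vector_residues("KALP21"))
})

test_that("benchmark peptide sequences have the expected composition", {
  expect_identical(peptide_sequence("LS3"), "LSSLLSLLSSLLSLLSSLLSL")
  ws <- peptide_sequence("WALP23")
  expect_identical(nchar(ws), 23L)
  expect_identical(substr(ws, 1, 3), "GWW")
  expect_identical(nchar(peptide_sequence("L24")), 28L)
  expect_identical(nchar(peptide_sequence("LA12")), 28L)
})

test_that("atomistic mapping places sites at subgroup mass centers", {
  atoms <- data.frame(
    atom = c("CA", "CB1", "CB2"),
    residue_index = 1, residue_name = "XXX",
    x = c(0.1, 0, 0.28), y = 0.2, z = 0.3,
    mass = c(12, 12, 16))
  mapping <- list(XXX = list(
    list(name = "CA", type = "p", atoms = "CA"),
    list(name = "CB", type = "ap", atoms = c("CB1", "CB2"))))
  res <- map_structure_to_cg(atoms, mapping)
  # single-atom subgroup: exactly at the alpha carbon
  expect_equal(res$coords[1, ], c(0.1, 0.2, 0.3), ignore_attr = TRUE)
  # hand-computed mass center: (12*0 + 16*0.28) / 28 = 0.16
  expect_equal(res$coords[2, 1], 0.16)
  expect_identical(n_sites(res$topology), 2L)
})

test_that("a tryptophan mapping yields four sidechain sites", {
  ring <- data.frame(
    atom = c("CA", "CB", "CG", "CD1", "NE1", "CE2", "CZ2", "CH2"),
    residue_index = 1, residue_name = "TRP",
    x = seq(0, 0.7, by = 0.1), y = 0, z = 0,
    element = c("C", "C", "C", "C", "N", "C", "C", "C"))
  mapping <- list(TRP = list(
    list(name = "CA", type = "p", atoms = "CA"),
    list(name = "CB", type = "ap", atoms = "CB"),
    list(name = "CG", type = "p", atoms = c("CG", "CD1")),
    list(name = "CD", type = "ap", atoms = c("NE1", "CE2")),
    list(name = "CE", type = "ap", atoms = c("CZ2", "CH2"))))
  res <- map_structure_to_cg(ring, mapping)
  sc <- res$topology$sites[res$topology$sites$name != "CA", ]
  expect_identical(nrow(sc), 4L)
})

test_that("mapping rejects missing atoms and overlapping subgroups", {
  atoms <- data.frame(atom = c("CA", "CB"), residue_index = 1,
                      residue_name = "XXX", x = 0:1, y = 0, z = 0,
                      mass = 12)
  expect_error(map_structure_to_cg(
    atoms, list(XXX = list(list(name = "CA", type = "p",
                                atoms = c("CA", "CQ"))))),
    "missing atom")
  expect_error(map_structure_to_cg(
    atoms, list(XXX = list(
      list(name = "CA", type = "p", atoms = "CA"),
      list(name = "CB", type = "ap", atoms = c("CA", "CB"))))),
    "overlapping")
})

test_that("mapping is equivariant under rigid transformations", {
  set.seed(5)
  atoms <- data.frame(
    atom = c("CA", "C1", "C2"), residue_index = 1, residue_name = "XXX",
    x = rnorm(3), y = rnorm(3), z = rnorm(3), mass = c(12, 12, 16))
  mapping <- list(XXX = list(
    list(name = "CA", type = "p", atoms = "CA"),
    list(name = "CB", type = "ap", atoms = c("C1", "C2"))))
  base <- map_structure_to_cg(atoms, mapping)$coords
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(1, -2, 0.5)
  xyz <- as.matrix(atoms[c("x", "y", "z")]) %*% t(R)
  atoms2 <- atoms
  atoms2$x <- xyz[, 1] + shift[1]
  atoms2$y <- xyz[, 2] + shift[2]
  atoms2$z <- xyz[, 3] + shift[3]
  moved <- map_structure_to_cg(atoms2, mapping)$coords
  expect_equal(moved, sweep(base %*% t(R), 2, shift, "+"),
               tolerance = 1e-12)
})

test_that("the DOPC template builds with the required head-group beads", {
  topo <- build_dopc_topology()
  counts <- table(topo$sites$site_type)
  expect_identical(as.integer(counts[c("ch", "ph", "gl", "e1", "e2")]),
                   rep(1L, 5))
  # esters are mandatory for the thickness analysis
  tmpl <- dopc_template()
  expect_error(build_dopc_topology(tmpl[!tmpl$type %in% c("e1", "e2"), ]),
               "ester")
  bad <- tmpl
  bad$type[1] <- "zz"
  expect_error(build_dopc_topology(bad), "unregistered")
})

test_that("replication scales site counts and keeps terms in range", {
  one <- build_dopc_topology()
  many <- replicate_topology(one, 256)
  expect_identical(n_sites(many), 256L * n_sites(one))
  expect_identical(nrow(many$bonds), 256L * nrow(one$bonds))
  expect_lte(max(many$bonds$j), n_sites(many))
})

test_that("exclusions cover all 1-2 and 1-3 pairs", {
  topo <- build_peptide_topology("NQ")
  ex <- paste(topo$exclusions[, 1], topo$exclusions[, 2])
  for (b in seq_len(nrow(topo$bonds)))
    expect_true(paste(min(topo$bonds$i[b], topo$bonds$j[b]),
                      max(topo$bonds$i[b], topo$bonds$j[b])) %in% ex)
  # N backbone - Q sidechain CB: 1-3 through the Q backbone
  expect_true("1 4" %in% ex)
})
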