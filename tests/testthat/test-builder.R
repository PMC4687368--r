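# Backbone construction, rotamer side-chain placement, chirality, caps.

test_that("built backbones reproduce their torsion restraints", {
  spec <- peptide_spec(strrep("A", 10))
  rh <- assign_restraints(strrep("H", 10))
  bb <- build_backbone(spec, rh)
  pp <- structure_phi_psi(bb)
  expect_equal(pp$phi[-1], rep(-60, 9), tolerance = 1e-6)
  expect_equal(pp$psi[-10], rep(-40, 9), tolerance = 1e-6)
  # omega is trans throughout
  for (i in 2:10) {
    om <- measure_dihedral(pepbuildr:::atom_xyz(bb, i - 1, "CA"),
                           pepbuildr:::atom_xyz(bb, i - 1, "C"),
                           pepbuildr:::atom_xyz(bb, i, "N"),
                           pepbuildr:::atom_xyz(bb, i, "CA"))
    expect_equal(abs(om), 180, tolerance = 1e-6)
  }
})

test_that("random restraint vectors are reproduced within 1e-3 degree", {
  set.seed(7)
  spec <- peptide_spec(strrep("A", 8))
  for (rep in 1:15) {
    r <- data.frame(position = 1:8,
                    phi = runif(8, -179, 180), psi = runif(8, -179, 180))
    r$phi[1] <- NA; r$psi[8] <- NA
    bb <- build_backbone(spec, r)
    pp <- structure_phi_psi(bb)
    expect_equal(pp$phi[-1], r$phi[-1], tolerance = 1e-3 / 180)
    expect_equal(pp$psi[-8], r$psi[-8], tolerance = 1e-3 / 180)
  }
})

test_that("all-coil restraints give an extended chain", {
  spec <- peptide_spec(strrep("A", 12))
  bb <- build_backbone(spec, assign_restraints(strrep("C", 12)))
  d <- measure_distance(pepbuildr:::atom_xyz(bb, 1, "CA"),
                        pepbuildr:::atom_xyz(bb, 12, "CA"))
  expect_lt(abs(d - 3.8 * 11) / (3.8 * 11), 0.05)
})

test_that("a flipped restraint changes only dihedrals at that residue", {
  spec <- peptide_spec(strrep("A", 9))
  r1 <- assign_restraints(strrep("H", 9))
  r2 <- r1
  r2$phi[5] <- -120; r2$psi[5] <- 120
  p1 <- structure_phi_psi(build_backbone(spec, r1))
  p2 <- structure_phi_psi(build_backbone(spec, r2))
  expect_equal(p2$phi[-5], p1$phi[-5], tolerance = 1e-9)
  expect_equal(p2$psi[-5], p1$psi[-5], tolerance = 1e-9)
  expect_equal(p2$phi[5], -120, tolerance = 1e-6)
})

test_that("full builds are deterministic", {
  spec <- parse_peptide_spec("
sequence: CAKLSEC
disulfides: [[1, 7]]
residues:
  - {position: 3, chirality: D}
")
  restr <- assign_restraints("CHHHHEC")
  s1 <- build_peptide(spec, restr)
  s2 <- build_peptide(spec, restr)
  expect_identical(coords(s1), coords(s2))
})

test_that("side chains take the top rotamer of the nearest bin", {
  lib <- rotamer_library()
  spec <- peptide_spec("ALLLLLA")
  bb <- build_backbone(spec, assign_restraints("HHHHHHH"))
  s <- place_sidechains(bb, spec, lib)
  # helix bin for LEU: top rotamer chi1 from the library
  sub <- lib[lib$res == "LEU" & lib$phi == -60 & lib$psi == -40, ]
  want_chi1 <- sub$chi1[which.max(sub$prob)]
  chi1 <- measure_dihedral(pepbuildr:::atom_xyz(s, 4, "N"),
                           pepbuildr:::atom_xyz(s, 4, "CA"),
                           pepbuildr:::atom_xyz(s, 4, "CB"),
                           pepbuildr:::atom_xyz(s, 4, "CG"))
  expect_equal(chi1, want_chi1, tolerance = 1e-3 / 180)
  chi2 <- measure_dihedral(pepbuildr:::atom_xyz(s, 4, "CA"),
                           pepbuildr:::atom_xyz(s, 4, "CB"),
                           pepbuildr:::atom_xyz(s, 4, "CG"),
                           pepbuildr:::atom_xyz(s, 4, "CD1"))
  expect_equal(chi2, sub$chi2[which.max(sub$prob)],
               tolerance = 1e-3 / 180)
})

test_that("probability ties break to the lowest-index rotamer", {
  lib <- structure(data.frame(
    res = "SER", phi = c(-60, -60), psi = c(-40, -40),
    chi1 = c(100, -100), chi2 = NA, chi3 = NA, chi4 = NA,
    prob = c(0.5, 0.5)), class = c("rotamer_library", "data.frame"))
  chi <- select_rotamer(lib, "SER", -60, -40)
  expect_equal(chi[["chi1"]], 100)
})

test_that("residues without library entries fall back with a message", {
  lib <- rotamer_library()
  expect_null(select_rotamer(lib, "ALA", -60, -40))
  spec <- peptide_spec("AAAWAAA")   # TRP carries chis; drop it from the lib
  bb <- build_backbone(spec, assign_restraints("CCCCCCC"))
  expect_message(place_sidechains(bb, spec, lib[lib$res != "TRP", ]),
                 "no rotamer library entry")
})

test_that("chirality flip mirrors the side chain and flips the improper", {
  spec <- peptide_spec("AKLSEFT")
  s <- build_peptide(spec, assign_restraints("HHEHCHH"))
  imp <- function(st, i) {
    measure_dihedral(pepbuildr:::atom_xyz(st, i, "N"),
                     pepbuildr:::atom_xyz(st, i, "C"),
                     pepbuildr:::atom_xyz(st, i, "CA"),
                     pepbuildr:::atom_xyz(st, i, "CB"))
  }
  before <- imp(s, 3)
  s1 <- set_chirality(s, 3)
  after <- imp(s1, 3)
  expect_equal(after, -before, tolerance = 1e-6)
  expect_true(sign(after) != sign(before))
  # backbone untouched; bond lengths/angles preserved
  bbsel <- s$atoms$name %in% c("N", "CA", "C", "O")
  expect_equal(coords(s1)[bbsel, ], coords(s)[bbsel, ], tolerance = 1e-12)
  tpl <- lookup_template(fix_registry(), "LEU")
  for (k in seq_len(nrow(tpl$zmat))) {
    r <- tpl$zmat[k, ]
    d0 <- measure_distance(pepbuildr:::atom_xyz(s, 3, r$ref1),
                           pepbuildr:::atom_xyz(s, 3, r$atom))
    d1 <- measure_distance(pepbuildr:::atom_xyz(s1, 3, r$ref1),
                           pepbuildr:::atom_xyz(s1, 3, r$atom))
    expect_equal(d1, d0, tolerance = 1e-6)
  }
  # involution
  s2 <- set_chirality(s1, 3)
  expect_equal(coords(s2), coords(s), tolerance = 1e-6)
  # glycine refuses
  specg <- peptide_spec("AAAGAAA")
  sg <- build_peptide(specg, assign_restraints("CCCCCCC"))
  expect_error(set_chirality(sg, 4), "achiral")
})

test_that("all-D build is the mirror image of the all-L build", {
  seqs <- "AKLSEFT"
  specL <- peptide_spec(seqs)
  specD <- peptide_spec(data.frame(position = 1:7,
                                   code = strsplit(seqs, "")[[1]],
                                   chirality = "D"))
  rL <- assign_restraints("HHEHCHH")
  rD <- rL; rD$phi <- -rD$phi; rD$psi <- -rD$psi
  sL <- build_peptide(specL, rL)
  sD <- build_peptide(specD, rD)
  refl <- sL
  xyz <- coords(refl); xyz[, 1] <- -xyz[, 1]
  refl <- set_coords(refl, xyz)
  expect_lt(superpose(sD, refl, "all")$rmsd, 1e-3)
})

test_that("caps replace the zwitterionic termini with correct bookkeeping", {
  spec0 <- peptide_spec("AKLSEFA")
  s0 <- build_peptide(spec0, assign_restraints("CCCCCCC"))
  # default: zwitterionic termini
  expect_true(all(c("H1", "H2", "H3") %in%
                  s0$atoms$name[s0$atoms$resno == 1]))
  expect_true("OXT" %in% s0$atoms$name[s0$atoms$resno == 7])

  spec <- peptide_spec("AKLSEFA", n_cap = "acetyl", c_cap = "amide")
  s <- apply_caps(s0, spec)
  # acetyl: +6 atoms (CH3 with 3 H, C, O), -3 ammonium H, +1 amide H
  ace <- s$atoms[s$atoms$resno == 0, ]
  expect_setequal(ace$name, c("CH3", "HH31", "HH32", "HH33", "C", "O"))
  expect_false(any(c("H1", "H2", "H3") %in%
                   s$atoms$name[s$atoms$resno == 1]))
  expect_true("H" %in% s$atoms$name[s$atoms$resno == 1])
  expect_equal(nrow(s$atoms) - nrow(s0$atoms), 6 - 2 + 3 - 1)
  # amide cap: OXT gone, NH2 pseudo-residue appended
  expect_false("OXT" %in% s$atoms$name)
  expect_setequal(s$atoms$name[s$atoms$resno == 8], c("N", "HN1", "HN2"))
  # geometry: cap bonds at standard lengths
  expect_equal(measure_distance(pepbuildr:::atom_xyz(s, 0, "C"),
                                pepbuildr:::atom_xyz(s, 1, "N")),
               1.335, tolerance = 1e-6)
  expect_equal(measure_distance(pepbuildr:::atom_xyz(s, 7, "C"),
                                pepbuildr:::atom_xyz(s, 8, "N")),
               1.335, tolerance = 1e-6)
  # N-methylamide variant
  sm <- apply_caps(s0, peptide_spec("AKLSEFA", c_cap = "n_methylamide"))
  expect_true(all(c("N", "H", "CH3") %in%
                  sm$atoms$name[sm$atoms$resno == 8]))
  # caps on an NC-cyclic spec refuse
  expect_error(apply_caps(s0, structure(list(
    residues = spec0$residues, n_cap = "acetyl", c_cap = "none",
    nc_cyclic = TRUE, disulfide_pairs = list()),
    class = "peptide_spec")), "cyclic")
})

test_that("capped and cyclized topologies stay charge-consistent", {
  spec <- peptide_spec("AKLSEFA", n_cap = "acetyl", c_cap = "amide")
  s <- build_peptide(spec, assign_restraints("CCCCCCC"))
  topo <- build_topology(s, spec)
  expect_equal(sum(topo$params$charge), 0, tolerance = 1e-9)  # K+1, E-1
  spec0 <- peptide_spec("AKLSEFA")
  s0 <- build_peptide(spec0, assign_restraints("CCCCCCC"))
  expect_equal(sum(build_topology(s0, spec0)$params$charge), 0,
               tolerance = 1e-9)                    # zwitterion nets 0
})
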