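# Shared fixtures, built once per test run.

.fix <- new.env()

fix_registry <- function() {
  if (is.null(.fix$reg)) .fix$reg <- default_registry()
  .fix$reg
}

# 7-residue mixed-sequence coil build + topology (used by refine tests)
fix_coil7 <- function() {
  if (is.null(.fix$coil7)) {
    spec <- peptide_spec("AKLSEFA")
    s <- build_peptide(spec, assign_restraints("CCCCCCC"))
    .fix$coil7 <- list(spec = spec, structure = s,
                       topology = build_topology(s, spec))
  }
  .fix$coil7
}

# 10-residue poly-alanine helix, pre-minimized (used by MD tests)
fix_helix10_min <- function() {
  if (is.null(.fix$helix10)) {
    spec <- peptide_spec(strrep("A", 10))
    s <- build_peptide(spec, assign_restraints(strrep("H", 10)))
    topo <- build_topology(s, spec)
    mn <- minimize(s, topo, md_protocol(minimize_sd_steps = 150,
                                        minimize_cg_steps = 250))
    .fix$helix10 <- list(spec = spec, structure = mn$structure,
                         topology = topo, energy = mn$energy)
  }
  .fix$helix10
}

# tiny hand-built structure + topology for analytic energy checks
toy_structure <- function(xyz, elements = rep("C", nrow(xyz))) {
  pep_structure(data.frame(
    name = paste0("X", seq_len(nrow(xyz))), element = elements,
    resno = seq_len(nrow(xyz)), resid = "TOY",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

toy_topology <- function(nat, bonds = NULL, angles = NULL, dihedrals = NULL,
                         impropers = NULL, nb_pairs = NULL,
                         charge = rep(0, nat), rmin2 = rep(1.9, nat),
                         eps = rep(0.1, nat), mass = rep(12.011, nat),
                         cutoff = Inf, switch_width = 2) {
  empty <- list(
    bonds = data.frame(i = integer(), j = integer(), k = numeric(),
                       r0 = numeric(), patch = character()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        kth = numeric(), th0 = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), kd = numeric(), n = numeric(),
                           gamma = numeric()),
    impropers = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), kimp = numeric(),
                           phi0 = numeric()),
    nb_pairs = data.frame(i = integer(), j = integer(),
                          lj_scale = numeric(), coul_scale = numeric()))
  out <- empty
  if (!is.null(bonds)) out$bonds <- bonds
  if (!is.null(angles)) out$angles <- angles
  if (!is.null(dihedrals)) out$dihedrals <- dihedrals
  if (!is.null(impropers)) out$impropers <- impropers
  if (!is.null(nb_pairs)) out$nb_pairs <- nb_pairs
  structure(c(out, list(
    params = data.frame(charge = charge, rmin2 = rmin2, eps = eps,
                        mass = mass, hyb = rep("sp3", nat)),
    cutoff = cutoff, switch_width = switch_width,
    bonds_named = NULL, patches = list(), atom_key = NULL)),
    class = "pep_topology")
}

# brute-force rigid superposition: rotation grid + local refinement,
# independent of the Kabsch implementation
brute_force_rmsd <- function(P, Q, coarse = 20) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% rotmat(ang) - Qc)^2)))
  grid <- seq(-pi, pi, by = coarse * pi / 180)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_v) { best_v <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
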