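# Molecular-mechanics topology: bonded terms (harmonic bonds and angles,
# periodic dihedrals, harmonic impropers), per-atom charges/LJ/mass, and
# the nonbonded pair list with 1-2/1-3 exclusions and 1-4 scaling.
#
# Parameter policy: bond/angle/improper equilibria are taken from the
# as-built ideal geometry of the input structure (the templates define that
# geometry), except for covalent-patch terms (disulfide, head-to-tail
# closure), which carry explicit standard equilibria because the patched
# geometry is not closed until minimization.  Force constants are generic,
# physically plausible values.

FC <- list(k_bond = 300, k_bond_h = 340, k_bond_ss = 166,
           k_angle = 50, k_angle_h = 35,
           k_dih_sp3 = 1.4, k_dih_sp2 = 10, k_dih_ss = 3.5,
           k_improper = 15, k_improper_ca = 25)

# explicit equilibrium angles (deg) for terms spanning a patch bond
PATCH_ANGLES <- list(
  disulfide = 103.7,
  nc_peptide = c("CA C N" = 116.6, "O C N" = 123.0, "C N CA" = 121.9,
                 "C N H" = 119.0))

# special atoms the builder adds beyond the template atom lists
TERMINAL_CHARGES <- list(h3n = 1.2719 / 3, h2n = 0.5, oxt = -0.8,
                         o_shift = -0.2)

bond_row <- function(ri, ni, rj, nj, r0, patch = "") {
  data.frame(res_i = ri, name_i = ni, res_j = rj, name_j = nj,
             r0 = r0, patch = patch)
}

# assemble the named bond list for a structure from templates + backbone
assemble_bonds <- function(structure, spec, registry) {
  a <- structure$atoms
  has <- function(r, n) atom_index(structure, r, n) > 0L
  all_resnos <- sort(unique(a$resno))
  res_class <- vapply(all_resnos, function(i) {
    lookup_template(registry, a$resid[a$resno == i][1L])$class
  }, "")
  resnos <- all_resnos[res_class != "cap"]
  cap_resnos <- all_resnos[res_class == "cap"]
  n <- max(resnos)
  bonds <- list()
  add <- function(b) bonds[[length(bonds) + 1L]] <<- b
  for (i in resnos) {
    code <- a$resid[a$resno == i][1L]
    tpl <- lookup_template(registry, code)
    add(bond_row(i, "N", i, "CA", BB_GEOM$b_n_ca))
    add(bond_row(i, "CA", i, "C", BB_GEOM$b_ca_c))
    if (has(i, "O")) {
      add(bond_row(i, "C", i, "O",
                   if (has(i, "OXT")) BB_GEOM$b_c_oxt else BB_GEOM$b_c_o))
    }
    if (has(i, "OXT")) add(bond_row(i, "C", i, "OXT", BB_GEOM$b_c_oxt))
    if (has(i, "H")) add(bond_row(i, "N", i, "H", BB_GEOM$b_n_h))
    for (hn in c("H1", "H2", "H3")) {
      if (has(i, hn)) add(bond_row(i, "N", i, hn, BB_GEOM$b_n_h))
    }
    zm <- tpl$zmat
    for (k in seq_len(NROW(zm))) {
      if (startsWith(zm$ref1[k], "@")) next
      if (has(i, zm$atom[k]) && has(i, zm$ref1[k])) {
        add(bond_row(i, zm$atom[k], i, zm$ref1[k], zm$length[k]))
      }
    }
    for (k in seq_len(NROW(tpl$bonds))) {
      if (has(i, tpl$bonds$a[k]) && has(i, tpl$bonds$b[k])) {
        add(bond_row(i, tpl$bonds$a[k], i, tpl$bonds$b[k],
                     tpl$bonds$length[k]))
      }
    }
    if (i < n && has(i + 1L, "N")) {
      add(bond_row(i, "C", i + 1L, "N", BB_GEOM$b_c_n))
    }
  }
  # caps occupy pseudo-residues 0 and n+1; their z-matrices carry the bonds
  for (capres in cap_resnos) {
    code <- a$resid[a$resno == capres][1L]
    tpl <- lookup_template(registry, code)
    host <- if (capres < min(resnos)) min(resnos) else n
    for (k in seq_len(NROW(tpl$zmat))) {
      ref <- tpl$zmat$ref1[k]
      if (startsWith(ref, "@")) {
        add(bond_row(capres, tpl$zmat$atom[k], host, substring(ref, 2L),
                     tpl$zmat$length[k]))
      } else {
        add(bond_row(capres, tpl$zmat$atom[k], capres, ref,
                     tpl$zmat$length[k]))
      }
    }
  }
  do.call(rbind, bonds)
}

# per-atom parameters (charge, LJ, mass, hyb) resolved from templates
atom_params <- function(structure, registry) {
  a <- structure$atoms
  charge <- rmin2 <- eps <- mass <- numeric(nrow(a))
  hyb <- character(nrow(a))
  is_cap <- a$resid %in% c("ACE", "NH2", "NME") |
    vapply(a$resid, function(cd) {
      identical(lookup_template(registry, cd)$class, "cap")
    }, TRUE)
  last_res <- max(a$resno[!is_cap])
  has_oxt <- any(a$resno == last_res & a$name == "OXT")
  for (i in seq_len(nrow(a))) {
    tpl <- lookup_template(registry, a$resid[i])
    j <- match(a$name[i], tpl$atoms$name)
    el <- a$element[i]
    mass[i] <- ELEMENT_MASS[[el]]
    if (!is.na(j)) {
      charge[i] <- tpl$atoms$charge[j]
      rmin2[i] <- tpl$atoms$rmin2[j]
      eps[i] <- tpl$atoms$eps[j]
      hyb[i] <- tpl$atoms$hyb[j]
    } else if (a$name[i] %in% c("H1", "H2", "H3")) {
      charge[i] <- if (tpl$amide_h) TERMINAL_CHARGES$h3n else TERMINAL_CHARGES$h2n
      rmin2[i] <- 0.60; eps[i] <- 0.0157; hyb[i] <- "sp3"
    } else if (a$name[i] == "OXT") {
      charge[i] <- TERMINAL_CHARGES$oxt
      k <- match("O", tpl$atoms$name)
      rmin2[i] <- tpl$atoms$rmin2[k]; eps[i] <- tpl$atoms$eps[k]
      hyb[i] <- "sp2"
    } else {
      stop("no parameters for atom ", a$name[i], " of residue ",
           a$resno[i], " (", a$resid[i], ")")
    }
    # carboxylate oxygen shares the terminal negative charge
    if (has_oxt && a$name[i] == "O" && a$resno[i] == last_res) {
      charge[i] <- charge[i] + TERMINAL_CHARGES$o_shift
    }
  }
  # charges of template atoms absent from the structure (deleted thiol
  # hydrogens of disulfides, or all hydrogens of heavy-atom-only input)
  # are folded into their bonded parent so the net charge is conserved
  for (resno in unique(a$resno)) {
    code <- a$resid[a$resno == resno][1L]
    tpl <- lookup_template(registry, code)
    present <- a$name[a$resno == resno]
    absent <- setdiff(tpl$atoms$name, present)
    if (resno == 1L && any(a$resno == 1L & a$name %in% c("H1", "H2", "H3"))) {
      absent <- setdiff(absent, "H")   # replaced by the ammonium hydrogens
    }
    for (nm in absent) {
      parent <- if (nm == "H") "N" else if (nm == "O") "C" else {
        k <- match(nm, tpl$zmat$atom)
        if (is.na(k)) next
        tpl$zmat$ref1[k]
      }
      if (startsWith(parent, "@")) next
      pi_ <- which(a$resno == resno & a$name == parent)
      if (length(pi_)) {
        qi <- tpl$atoms$charge[match(nm, tpl$atoms$name)]
        charge[pi_[1L]] <- charge[pi_[1L]] + qi
      }
    }
  }
  # heavy-atom-only input (e.g. an external model without hydrogens) with
  # a free carboxylate also carries a free ammonium terminus: restore its
  # +1 on the terminal nitrogen so the molecule stays neutral overall
  if (!any(a$element == "H") && has_oxt) {
    first_res <- min(a$resno[!is_cap])
    ni <- which(a$resno == first_res & a$name == "N")
    if (length(ni)) charge[ni[1L]] <- charge[ni[1L]] + 1
  }
  data.frame(charge = charge, rmin2 = rmin2, eps = eps, mass = mass,
             hyb = hyb)
}

# expand named bond list to indices; derive angles/dihedrals/impropers and
# the nonbonded pair list with exclusions
derive_terms <- function(structure, bonds_named, params, cutoff,
                         one_four_lj = 0.5, one_four_coul = 1 / 1.2) {
  a <- structure$atoms
  nat <- nrow(a)
  xyz <- coords(structure)
  idx <- function(r, nm) {
    i <- which(a$resno == r & a$name == nm)
    if (!length(i)) stop("bond references missing atom ", nm, "/", r)
    i[1L]
  }
  bi <- mapply(idx, bonds_named$res_i, bonds_named$name_i)
  bj <- mapply(idx, bonds_named$res_j, bonds_named$name_j)
  el <- a$element
  kb <- ifelse(el[bi] == "H" | el[bj] == "H", FC$k_bond_h, FC$k_bond)
  kb[el[bi] == "S" & el[bj] == "S"] <- FC$k_bond_ss
  bonds <- data.frame(i = bi, j = bj, k = kb, r0 = bonds_named$r0,
                      patch = bonds_named$patch)

  nb_of <- vector("list", nat)           # neighbor lists
  for (b in seq_len(nrow(bonds))) {
    nb_of[[bonds$i[b]]] <- c(nb_of[[bonds$i[b]]], bonds$j[b])
    nb_of[[bonds$j[b]]] <- c(nb_of[[bonds$j[b]]], bonds$i[b])
  }
  patch_kind <- function(p, q) {
    hit <- which(((bonds$i == p & bonds$j == q) |
                  (bonds$i == q & bonds$j == p)) & nzchar(bonds$patch))
    if (length(hit)) bonds$patch[hit[1L]] else ""
  }

  # angles
  ang <- list()
  for (j in seq_len(nat)) {
    nbs <- unique(nb_of[[j]])
    if (length(nbs) < 2L) next
    cmb <- utils::combn(nbs, 2L)
    for (m in seq_len(ncol(cmb))) {
      i <- cmb[1L, m]; k <- cmb[2L, m]
      pk <- c(patch_kind(i, j), patch_kind(j, k))
      pk <- pk[nzchar(pk)]
      if (length(pk)) {
        kind <- pk[1L]
        if (kind == "disulfide") {
          th0 <- PATCH_ANGLES$disulfide
        } else {
          key <- paste(a$name[i], a$name[j], a$name[k])
          rkey <- paste(a$name[k], a$name[j], a$name[i])
          tab <- PATCH_ANGLES$nc_peptide
          th0 <- if (key %in% names(tab)) tab[[key]]
                 else if (rkey %in% names(tab)) tab[[rkey]] else 115
        }
      } else {
        th0 <- measure_angle(xyz[i, ], xyz[j, ], xyz[k, ])
      }
      kth <- if (el[i] == "H" || el[k] == "H") FC$k_angle_h else FC$k_angle
      ang[[length(ang) + 1L]] <- c(i, j, k, kth, th0)
    }
  }
  angles <- if (length(ang)) {
    m <- do.call(rbind, ang)
    data.frame(i = m[, 1L], j = m[, 2L], k = m[, 3L], kth = m[, 4L],
               th0 = m[, 5L])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    kth = numeric(), th0 = numeric())

  # proper dihedrals: one term set per central bond, divided across paths
  dih <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds$i[b]; k <- bonds$j[b]
    is_ <- setdiff(unique(nb_of[[j]]), k)
    ls_ <- setdiff(unique(nb_of[[k]]), j)
    if (!length(is_) || !length(ls_)) next
    paths <- expand.grid(i = is_, l = ls_)
    paths <- paths[paths$i != paths$l, , drop = FALSE]
    if (!nrow(paths)) next
    pk <- bonds$patch[b]
    if (identical(pk, "disulfide")) {
      kd <- FC$k_dih_ss; nper <- 2; gam <- 0
    } else if (identical(pk, "nc_peptide")) {
      kd <- FC$k_dih_sp2; nper <- 2; gam <- 180
    } else if (params$hyb[j] == "sp2" && params$hyb[k] == "sp2") {
      kd <- FC$k_dih_sp2; nper <- 2; gam <- 180
    } else {
      kd <- FC$k_dih_sp3; nper <- 3; gam <- 0
    }
    for (m in seq_len(nrow(paths))) {
      dih[[length(dih) + 1L]] <- c(paths$i[m], j, k, paths$l[m],
                                   kd / nrow(paths), nper, gam)
    }
  }
  dihedrals <- if (length(dih)) {
    m <- do.call(rbind, dih)
    data.frame(i = m[, 1L], j = m[, 2L], k = m[, 3L], l = m[, 4L],
               kd = m[, 5L], n = m[, 6L], gamma = m[, 7L])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), kd = numeric(), n = numeric(),
                    gamma = numeric())

  # impropers: sp2 planarity + alpha-carbon chirality
  imp <- list()
  for (c0 in seq_len(nat)) {
    nbs <- unique(nb_of[[c0]])
    if (params$hyb[c0] == "sp2" && length(nbs) == 3L) {
      i <- nbs[1L]; jj <- nbs[2L]; l <- nbs[3L]
      spans_patch <- nzchar(patch_kind(i, c0)) || nzchar(patch_kind(jj, c0)) ||
        nzchar(patch_kind(l, c0))
      phi0 <- if (spans_patch) 180 else
        measure_dihedral(xyz[i, ], xyz[jj, ], xyz[c0, ], xyz[l, ])
      imp[[length(imp) + 1L]] <- c(i, jj, c0, l, FC$k_improper, phi0)
    }
    if (a$name[c0] == "CA" && length(nbs) == 4L) {
      nN <- nbs[a$name[nbs] == "N" & a$resno[nbs] == a$resno[c0]]
      nC <- nbs[a$name[nbs] == "C" & a$resno[nbs] == a$resno[c0]]
      side <- nbs[el[nbs] != "H" & !a$name[nbs] %in% c("N", "C")]
      if (length(nN) && length(nC) && length(side)) {
        s <- side[1L]
        phi0 <- measure_dihedral(xyz[nN, ], xyz[nC, ], xyz[c0, ], xyz[s, ])
        imp[[length(imp) + 1L]] <- c(nN, nC, c0, s, FC$k_improper_ca, phi0)
      }
    }
  }
  impropers <- if (length(imp)) {
    m <- do.call(rbind, imp)
    data.frame(i = m[, 1L], j = m[, 2L], k = m[, 3L], l = m[, 4L],
               kimp = m[, 5L], phi0 = m[, 6L])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), kimp = numeric(), phi0 = numeric())

  # exclusions: 1-2, 1-3 excluded; 1-4 scaled
  excl <- matrix(FALSE, nat, nat)
  scale14 <- matrix(FALSE, nat, nat)
  for (b in seq_len(nrow(bonds))) excl[bonds$i[b], bonds$j[b]] <- TRUE
  for (m in seq_len(nrow(angles))) excl[angles$i[m], angles$k[m]] <- TRUE
  for (m in seq_len(nrow(dihedrals))) {
    i <- dihedrals$i[m]; l <- dihedrals$l[m]
    if (!excl[i, l] && !excl[l, i]) scale14[i, l] <- TRUE
  }
  excl <- excl | t(excl)
  scale14 <- (scale14 | t(scale14)) & !excl
  ut <- upper.tri(excl)
  keep <- ut & !excl
  pi_ <- row(excl)[keep]; pj_ <- col(excl)[keep]
  s14 <- scale14[keep]
  nb_pairs <- data.frame(
    i = pi_, j = pj_,
    lj_scale = ifelse(s14, one_four_lj, 1),
    coul_scale = ifelse(s14, one_four_coul, 1))

  list(bonds = bonds, angles = angles, dihedrals = dihedrals,
       impropers = impropers, nb_pairs = nb_pairs)
}

#' Build a molecular-mechanics topology for a structure
#'
#' Assembles the bond graph from the residue templates and backbone
#' connectivity of the atoms actually present (hydrogen-free structures
#' are handled by simply omitting hydrogen terms), derives angle,
#' dihedral, improper and nonbonded terms, and resolves per-atom charges,
#' Lennard-Jones parameters and masses.
#'
#' @param structure A built `pep_structure` with ideal geometry.
#' @param spec The corresponding [peptide_spec()] (used for bookkeeping;
#'   may be `NULL` for structures read from PDB).
#' @param registry Template registry.
#' @param cutoff Nonbonded cutoff in Angstrom (default 10; the legacy
#'   8 Angstrom behaviour is available by passing `cutoff = 8`).
#' @param switch_width Width (A) of the cubic switching region below the
#'   cutoff that keeps the nonbonded potential smooth.
#' @return An object of class `pep_topology`.
#' @export
build_topology <- function(structure, spec = NULL,
                           registry = default_registry(),
                           cutoff = 10, switch_width = 2) {
  stopifnot(cutoff > 0)
  params <- atom_params(structure, registry)
  bonds_named <- assemble_bonds(structure, spec, registry)
  terms <- derive_terms(structure, bonds_named, params, cutoff)
  structure(c(terms, list(
    params = params, cutoff = cutoff, switch_width = switch_width,
    bonds_named = bonds_named, patches = list(),
    atom_key = paste(structure$atoms$resno, structure$atoms$name))),
    class = "pep_topology")
}

# re-derive all terms after a patch edited structure/bond list
rederive_topology <- function(structure, topology, registry) {
  params <- atom_params(structure, registry)
  terms <- derive_terms(structure, topology$bonds_named, params,
                        topology$cutoff)
  structure(c(terms, list(
    params = params, cutoff = topology$cutoff,
    switch_width = topology$switch_width,
    bonds_named = topology$bonds_named, patches = topology$patches,
    atom_key = paste(structure$atoms$resno, structure$atoms$name))),
    class = "pep_topology")
}

#' @export
print.pep_topology <- function(x, ...) {
  cat("<pep_topology>", nrow(x$params), "atoms:",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals,", nrow(x$impropers), "impropers,",
      nrow(x$nb_pairs), "nb pairs; cutoff", x$cutoff, "A\n")
  if (length(x$patches)) {
    for (p in x$patches) cat("  patch:", p$kind, "\n")
  }
  invisible(x)
}
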