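# Covalent constraints: side-chain disulfide bridges and head-to-tail
# (N-C) peptide cyclization.  Patches edit the bond graph and delete the
# displaced atoms; the geometry is NOT closed at patch time — closure is
# delegated to minimization, which pulls the new bond to its equilibrium
# length.

DISULFIDE_LENGTH <- 2.05   # S-S equilibrium, Angstrom
NC_BOND_LENGTH <- 1.329    # peptide-bond equilibrium, Angstrom

bond_patch <- function(kind, atoms, removed_atoms, target_length) {
  structure(list(kind = kind, atoms = atoms, removed_atoms = removed_atoms,
                 target_length = target_length), class = "bond_patch")
}

remove_atoms <- function(structure, keys) {
  a <- structure$atoms
  drop <- paste(a$resno, a$name) %in% keys
  structure$atoms <- a[!drop, , drop = FALSE]
  structure$atoms$serial <- seq_len(nrow(structure$atoms))
  rownames(structure$atoms) <- NULL
  structure
}

#' Add a disulfide bridge between two cysteine-like residues
#'
#' Covalently links the SG atoms of residues `pair[1]` and `pair[2]`:
#' the thiol hydrogens (HG) are deleted from both residues, an SG-SG bond
#' with equilibrium length 2.05 Angstrom is added, and the associated
#' angle/dihedral terms (with standard X-S-S equilibria) are derived.
#' The sulfur atoms are not moved; run [minimize()] to close the bridge.
#'
#' @param structure A built `pep_structure`.
#' @param topology The matching `pep_topology`.
#' @param pair Integer pair `(i, j)` of residue positions.
#' @param registry Template registry.
#' @return A list with elements `structure` and `topology`.
#' @export
add_disulfide <- function(structure, topology, pair,
                          registry = default_registry()) {
  pair <- as.integer(pair)
  stopifnot(length(pair) == 2L, pair[1L] != pair[2L])
  for (p in pair) {
    if (!atom_index(structure, p, "SG")) {
      resid <- unique(structure$atoms$resid[structure$atoms$resno == p])
      stop("residue ", p, " (", paste(resid, collapse = "/"),
           ") has no SG atom; cannot form a disulfide")
    }
  }
  existing <- topology$bonds_named
  dup <- existing$patch == "disulfide" &
    ((existing$res_i == pair[1L] & existing$res_j == pair[2L]) |
     (existing$res_i == pair[2L] & existing$res_j == pair[1L]))
  if (any(dup)) stop("pair (", pair[1L], ",", pair[2L], ") already bonded")
  removed <- paste(pair, "HG")
  structure <- remove_atoms(structure, removed)
  topology$bonds_named <- rbind(
    topology$bonds_named[!(paste(topology$bonds_named$res_i,
                                 topology$bonds_named$name_i) %in% removed |
                           paste(topology$bonds_named$res_j,
                                 topology$bonds_named$name_j) %in% removed), ],
    bond_row(pair[1L], "SG", pair[2L], "SG", DISULFIDE_LENGTH, "disulfide"))
  topology$patches <- c(topology$patches, list(
    bond_patch("disulfide", list(c(pair[1L], "SG"), c(pair[2L], "SG")),
               removed, DISULFIDE_LENGTH)))
  topology <- rederive_topology(structure, topology, registry)
  list(structure = structure, topology = topology)
}

#' Cyclize a peptide head-to-tail
#'
#' Adds the N(1)-C(n) peptide bond (equilibrium 1.329 Angstrom): the
#' C-terminal OXT and two of the three N-terminal ammonium hydrogens are
#' deleted (the survivor becomes the amide hydrogen), an omega-style
#' torsion term at 180 degrees is placed across the new bond, and standard
#' amide angle equilibria are used for the terms spanning it.  Geometry is
#' closed by subsequent minimization.  Capped termini are an error, as is
#' cyclizing twice.
#'
#' @inheritParams add_disulfide
#' @return A list with elements `structure` and `topology`.
#' @export
cyclize_nc <- function(structure, topology, registry = default_registry()) {
  a <- structure$atoms
  if (any(a$resid %in% c("ACE", "NH2", "NME"))) {
    stop("cannot head-to-tail cyclize a capped peptide")
  }
  if (any(topology$bonds_named$patch == "nc_peptide")) {
    stop("peptide is already head-to-tail cyclic")
  }
  n <- max(a$resno)
  if (!atom_index(structure, n, "OXT")) {
    stop("C-terminus has no free carboxylate (capped or already patched)")
  }
  removed <- c(paste(n, "OXT"), paste(1L, c("H2", "H3")))
  removed <- removed[vapply(strsplit(removed, " "), function(k) {
    atom_index(structure, as.integer(k[1L]), k[2L]) > 0L
  }, TRUE)]
  structure <- remove_atoms(structure, removed)
  # surviving ammonium hydrogen becomes the amide hydrogen
  h1 <- which(structure$atoms$resno == 1L & structure$atoms$name == "H1")
  if (length(h1)) structure$atoms$name[h1] <- "H"
  bn <- topology$bonds_named
  gone <- paste(bn$res_i, bn$name_i) %in% removed |
          paste(bn$res_j, bn$name_j) %in% removed
  bn <- bn[!gone, , drop = FALSE]
  bn$name_i[bn$res_i == 1L & bn$name_i == "H1"] <- "H"
  bn$name_j[bn$res_j == 1L & bn$name_j == "H1"] <- "H"
  topology$bonds_named <- rbind(
    bn, bond_row(n, "C", 1L, "N", NC_BOND_LENGTH, "nc_peptide"))
  topology$patches <- c(topology$patches, list(
    bond_patch("nc_peptide", list(c(n, "C"), c(1L, "N")), removed,
               NC_BOND_LENGTH)))
  # C-terminal O reverts from carboxylate to carbonyl equilibrium
  co <- which(topology$bonds_named$res_i == n &
              topology$bonds_named$name_i == "C" &
              topology$bonds_named$name_j == "O" &
              topology$bonds_named$res_j == n)
  if (length(co)) topology$bonds_named$r0[co] <- BB_GEOM$b_c_o
  topology <- rederive_topology(structure, topology, registry)
  list(structure = structure, topology = topology)
}
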