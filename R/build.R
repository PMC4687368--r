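# Chain builder: internal-coordinate (NeRF) construction of the backbone
# from torsion restraints, template-driven side-chain placement with a
# backbone-dependent rotamer library, chirality flips and terminal caps.

# incremental atom accumulator keyed by "resno|name"
new_build_env <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}
add_atom <- function(env, resno, resid, name, element, xyz) {
  env$rows[[paste(resno, name, sep = "|")]] <-
    list(resno = resno, resid = resid, name = name, element = element,
         x = xyz[1L], y = xyz[2L], z = xyz[3L])
}
get_atom <- function(env, resno, name) {
  r <- env$rows[[paste(resno, name, sep = "|")]]
  if (is.null(r)) NULL else c(r$x, r$y, r$z)
}
env_to_structure <- function(env, model_id = 1L) {
  df <- do.call(rbind, lapply(env$rows, function(r) {
    data.frame(name = r$name, element = r$element, resno = r$resno,
               resid = r$resid, x = r$x, y = r$y, z = r$z)
  }))
  pep_structure(df, model_id = model_id)
}
structure_to_env <- function(structure) {
  env <- new_build_env()
  a <- structure$atoms
  for (i in seq_len(nrow(a))) {
    add_atom(env, a$resno[i], a$resid[i], a$name[i], a$element[i],
             c(a$x[i], a$y[i], a$z[i]))
  }
  env
}

# resolve a z-matrix torsion expression ("chi1+120", "-60", "psi") to degrees
resolve_torsion <- function(expr, chi = numeric(), psi = NA_real_) {
  s <- trimws(expr)
  v <- suppressWarnings(as.numeric(s))
  if (!is.na(v)) return(v)
  if (identical(s, "psi")) {
    if (is.na(psi)) stop("torsion symbol 'psi' has no value in this context")
    return(psi)
  }
  m <- regmatches(s, regexec("^(chi[0-9])([+-][0-9.]+)?$", s))[[1L]]
  if (!length(m)) stop("cannot parse torsion expression '", expr, "'")
  slot <- m[2L]
  off <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
  base <- chi[slot]
  if (is.null(base) || is.na(base)) base <- 180  # template default chi
  unname(base + off)
}

# element of a template atom by name
tpl_element <- function(tpl, name) {
  tpl$atoms$element[match(name, tpl$atoms$name)]
}

# place a set of template z-matrix records for residue `resno`.
# `refs_env` resolves atom names; "@N"/"@CA"/"@C" map to `host` positions.
place_zmat <- function(env, resno, resid, tpl, records,
                       chi = numeric(), mirror = FALSE, psi = NA_real_,
                       host_resno = resno, skip_existing = FALSE) {
  ref_xyz <- function(name) {
    if (startsWith(name, "@")) {
      return(get_atom(env, host_resno, substring(name, 2L)))
    }
    get_atom(env, resno, name)
  }
  for (i in seq_len(NROW(records))) {
    r <- records[i, ]
    if (skip_existing && !is.null(get_atom(env, resno, r$atom))) next
    a <- ref_xyz(r$ref3); b <- ref_xyz(r$ref2); c <- ref_xyz(r$ref1)
    if (is.null(a) || is.null(b) || is.null(c)) {
      stop("z-matrix reference atom missing while placing ", r$atom,
           " of residue ", resno)
    }
    tor <- resolve_torsion(r$torsion, chi = chi, psi = psi)
    if (mirror) tor <- -tor
    xyz <- place_atom(a, b, c, r$length, r$angle, tor)
    add_atom(env, resno, resid, r$atom, tpl_element(tpl, r$atom), xyz)
  }
  env
}

# amide hydrogen in the peptide plane, bisecting C(prev)-N-CA
place_amide_h <- function(env, resno, resid, prev_c_xyz) {
  n <- get_atom(env, resno, "N"); ca <- get_atom(env, resno, "CA")
  u1 <- n - prev_c_xyz; u1 <- u1 / vnorm(u1)
  u2 <- n - ca; u2 <- u2 / vnorm(u2)
  h <- n + BB_GEOM$b_n_h * (u1 + u2) / vnorm(u1 + u2)
  add_atom(env, resno, resid, "H", "H", h)
}

# protonated N-terminus: 3 hydrogens (2 for ring nitrogens)
place_nterm_h <- function(env, resno, resid, tpl, mirror = FALSE) {
  a <- get_atom(env, resno, "C"); b <- get_atom(env, resno, "CA")
  c <- get_atom(env, resno, "N")
  tors <- if (tpl$amide_h) c(60, 180, -60) else c(60, 180)
  if (mirror) tors <- -tors
  for (k in seq_along(tors)) {
    xyz <- place_atom(a, b, c, BB_GEOM$b_n_h, 109.5, tors[k])
    add_atom(env, resno, resid, paste0("H", k), "H", xyz)
  }
}

#' Build the peptide backbone from torsion restraints
#'
#' Extends the chain atom by atom with [place_atom()] using standard
#' backbone bond lengths and angles, applying the restraint (phi, psi) at
#' every residue and a trans peptide bond (omega = 180) throughout.  The
#' output contains N, CA, C, O for every residue plus amide hydrogens,
#' alpha hydrogens and zwitterionic terminal atoms (N-terminal H1..H3,
#' C-terminal OXT); caps are applied afterwards by [apply_caps()].  The
#' measured phi/psi of the built chain equal the restraints to well below
#' 1e-3 degrees.  Steric clashes are not an error at this stage; they are
#' resolved downstream by minimization.
#'
#' @param spec A [peptide_spec()].
#' @param restraints A `torsion_restraints` object from
#'   [assign_restraints()] (or any data.frame with columns phi/psi).
#' @param registry Template registry.
#' @return A `pep_structure`.
#' @export
build_backbone <- function(spec, restraints, registry = default_registry()) {
  r <- spec$residues
  n <- nrow(r)
  stopifnot(NROW(restraints) == n)
  phi <- restraints$phi
  psi <- restraints$psi
  tpls <- lapply(r$code, function(cd) lookup_template(registry, cd))
  env <- new_build_env()

  # seed frame for residue 1
  N <- c(0, 0, 0)
  CA <- c(BB_GEOM$b_n_ca, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, BB_GEOM$b_ca_c, BB_GEOM$a_n_ca_c, 0)
  add_atom(env, 1L, tpls[[1L]]$code, "N", "N", N)
  add_atom(env, 1L, tpls[[1L]]$code, "CA", "C", CA)
  add_atom(env, 1L, tpls[[1L]]$code, "C", "C", C)
  for (i in seq_len(n - 1L)) {
    Np <- place_atom(get_atom(env, i, "N"), get_atom(env, i, "CA"),
                     get_atom(env, i, "C"),
                     BB_GEOM$b_c_n, BB_GEOM$a_ca_c_n, psi[i])
    CAp <- place_atom(get_atom(env, i, "CA"), get_atom(env, i, "C"), Np,
                      BB_GEOM$b_n_ca, BB_GEOM$a_c_n_ca, BB_GEOM$omega)
    Cp <- place_atom(get_atom(env, i, "C"), Np, CAp,
                     BB_GEOM$b_ca_c, BB_GEOM$a_n_ca_c, phi[i + 1L])
    resid <- tpls[[i + 1L]]$code
    add_atom(env, i + 1L, resid, "N", "N", Np)
    add_atom(env, i + 1L, resid, "CA", "C", CAp)
    add_atom(env, i + 1L, resid, "C", "C", Cp)
  }

  # decorations: carbonyl O, amide H, alpha hydrogens, terminal atoms
  for (i in seq_len(n)) {
    tpl <- tpls[[i]]
    resid <- tpl$code
    mirror <- identical(r$chirality[i], "D")
    Ni <- get_atom(env, i, "N"); CAi <- get_atom(env, i, "CA")
    Ci <- get_atom(env, i, "C")
    psi_eff <- if (is.na(psi[i])) 180 else psi[i]
    if (i < n) {
      O <- place_atom(Ni, CAi, Ci, BB_GEOM$b_c_o, BB_GEOM$a_ca_c_o,
                      psi_eff + 180)
      add_atom(env, i, resid, "O", "O", O)
    } else {
      O <- place_atom(Ni, CAi, Ci, BB_GEOM$b_c_oxt, BB_GEOM$a_ca_c_oxt,
                      psi_eff + 180)
      OXT <- place_atom(Ni, CAi, Ci, BB_GEOM$b_c_oxt, BB_GEOM$a_ca_c_oxt,
                        psi_eff)
      add_atom(env, i, resid, "O", "O", O)
      add_atom(env, i, resid, "OXT", "O", OXT)
    }
    if (i == 1L) {
      place_nterm_h(env, i, resid, tpl, mirror = mirror)
    } else if (tpl$amide_h) {
      place_amide_h(env, i, resid, get_atom(env, i - 1L, "C"))
    }
    # alpha hydrogens come from the template z-matrix (absent for e.g. Aib)
    zm <- tpl$zmat
    if (!is.null(zm)) {
      ha <- zm[grepl("^HA", zm$atom), , drop = FALSE]
      if (nrow(ha)) {
        place_zmat(env, i, resid, tpl, ha, mirror = mirror)
      }
    }
  }
  env_to_structure(env)
}

#' Load the bundled backbone-dependent rotamer library
#'
#' A coarse plain-text table of preferred side-chain chi angles per
#' residue type and backbone (phi, psi) bin, with probabilities.  Lookup
#' is nearest-bin; ties in probability break to the lowest row index.
#' The bundled values are coarse, plausible preferences (gauche-/trans/
#' gauche+ chi1 with bin-dependent weights), not a copy of any published
#' library, and can be replaced by the user.
#'
#' @param path Optional alternative table (columns
#'   `res, phi, psi, chi1..chi4, prob`).
#' @return A `rotamer_library` data.frame.
#' @export
rotamer_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rotamers.tsv", package = "pepbuildr")
  }
  structure(utils::read.delim(path, stringsAsFactors = FALSE),
            class = c("rotamer_library", "data.frame"))
}

# angular distance between (phi,psi) pairs, degrees
bin_distance <- function(phi, psi, bin_phi, bin_psi) {
  dphi <- abs(wrap_angle(phi - bin_phi))
  dpsi <- abs(wrap_angle(psi - bin_psi))
  sqrt(dphi^2 + dpsi^2)
}

#' Select a rotamer for one residue
#'
#' @param lib A [rotamer_library()].
#' @param code Template code (e.g. "LEU").
#' @param phi,psi Backbone torsions in degrees (NA allowed at chain ends;
#'   the available angle decides the bin).
#' @return Named chi vector (chi1..chi4, NA for unused slots), or `NULL`
#'   when the residue has no library entry.
#' @export
select_rotamer <- function(lib, code, phi, psi) {
  sub <- lib[lib$res == code, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  phi <- if (is.na(phi)) 180 else phi
  psi <- if (is.na(psi)) 180 else psi
  d <- bin_distance(phi, psi, sub$phi, sub$psi)
  sub <- sub[d == min(d), , drop = FALSE]
  best <- which(sub$prob == max(sub$prob))[1L]   # lowest-index tie-break
  chi <- as.numeric(sub[best, c("chi1", "chi2", "chi3", "chi4")])
  names(chi) <- paste0("chi", 1:4)
  chi
}

#' Place side chains from the rotamer library
#'
#' Builds every remaining template atom (side chains) onto a backbone,
#' taking chi torsions from the highest-probability rotamer of the nearest
#' backbone (phi, psi) bin.  Residues without a library entry (alanine,
#' glycine, or unparameterized codes) fall back to template default chi
#' values (a message is emitted for codes with chi slots but no entry).
#' D-residues are built mirrored.
#'
#' @param backbone A `pep_structure` from [build_backbone()].
#' @param spec The [peptide_spec()].
#' @param lib A [rotamer_library()].
#' @param registry Template registry.
#' @return The completed `pep_structure`.
#' @export
place_sidechains <- function(backbone, spec, lib = rotamer_library(),
                             registry = default_registry()) {
  env <- structure_to_env(backbone)
  bb <- structure_phi_psi(backbone)
  r <- spec$residues
  for (i in seq_len(nrow(r))) {
    tpl <- lookup_template(registry, r$code[i])
    zm <- tpl$zmat
    if (is.null(zm)) next
    mirror <- identical(r$chirality[i], "D")
    chi <- numeric()
    if (length(tpl$chis)) {
      # the library describes L-residues: D-residues are looked up at the
      # mirrored backbone angles and built with negated chi
      phi_i <- if (mirror) -bb$phi[i] else bb$phi[i]
      psi_i <- if (mirror) -bb$psi[i] else bb$psi[i]
      chi <- select_rotamer(lib, tpl$code, phi_i, psi_i)
      if (is.null(chi)) {
        message("residue ", i, " (", tpl$code,
                "): no rotamer library entry; using template default chi")
        chi <- numeric()
      }
    }
    place_zmat(env, i, tpl$code, tpl, zm, chi = chi, mirror = mirror,
               skip_existing = TRUE)
  }
  env_to_structure(env)
}

#' Invert the chirality of one residue in place
#'
#' Rebuilds the residue's alpha hydrogen and side chain mirrored through
#' the local N-CA-C plane: every template internal-coordinate record is
#' re-placed with its measured bond length and angle and the sign of its
#' measured torsion flipped.  Backbone atoms (N, CA, C, O, amide H) are
#' untouched, bond lengths and angles are preserved to floating-point
#' accuracy, and applying the operation twice restores the original
#' coordinates.  Glycine (or any achiral template) is an error.
#'
#' @param structure A built `pep_structure`.
#' @param position 1-based residue position.
#' @param registry Template registry.
#' @return The updated structure.
#' @export
set_chirality <- function(structure, position, registry = default_registry()) {
  resid <- unique(structure$atoms$resid[structure$atoms$resno == position])
  if (!length(resid)) stop("no residue at position ", position)
  tpl <- lookup_template(registry, resid[1L])
  if (!tpl$chiral) {
    stop("residue ", position, " (", tpl$code,
         ") is achiral; cannot flip chirality")
  }
  env <- structure_to_env(structure)
  zm <- tpl$zmat
  # measure every internal coordinate from the ORIGINAL geometry first,
  # then rebuild in z-matrix order with torsion signs flipped
  meas <- vector("list", NROW(zm))
  for (i in seq_len(NROW(zm))) {
    r <- zm[i, ]
    d <- get_atom(env, position, r$atom)
    if (is.null(d)) next   # atom not built (e.g. backbone-only structure)
    a <- get_atom(env, position, r$ref3)
    b <- get_atom(env, position, r$ref2)
    c <- get_atom(env, position, r$ref1)
    meas[[i]] <- c(measure_distance(c, d), measure_angle(b, c, d),
                   measure_dihedral(a, b, c, d))
  }
  for (i in seq_len(NROW(zm))) {
    if (is.null(meas[[i]])) next
    r <- zm[i, ]
    a <- get_atom(env, position, r$ref3)
    b <- get_atom(env, position, r$ref2)
    c <- get_atom(env, position, r$ref1)
    xyz <- place_atom(a, b, c, meas[[i]][1L], meas[[i]][2L], -meas[[i]][3L])
    add_atom(env, position, tpl$code, r$atom, tpl_element(tpl, r$atom), xyz)
  }
  # N-terminal hydrogens are part of the local stereocentre environment
  if (position == min(structure$atoms$resno[structure$atoms$resno >= 1L])) {
    a <- get_atom(env, position, "C"); b <- get_atom(env, position, "CA")
    c <- get_atom(env, position, "N")
    for (hn in c("H1", "H2", "H3")) {
      d <- get_atom(env, position, hn)
      if (is.null(d)) next
      xyz <- place_atom(a, b, c, measure_distance(c, d),
                        measure_angle(b, c, d),
                        -measure_dihedral(a, b, c, d))
      add_atom(env, position, tpl$code, hn, "H", xyz)
    }
  }
  out <- env_to_structure(env, model_id = structure$model_id)
  # keep original atom order
  ord <- match(paste(structure$atoms$resno, structure$atoms$name),
               paste(out$atoms$resno, out$atoms$name))
  out$atoms <- out$atoms[ord, ]
  out$atoms$serial <- seq_len(nrow(out$atoms))
  rownames(out$atoms) <- NULL
  out
}

#' Apply terminal caps to a built structure
#'
#' Replaces the zwitterionic termini by the caps named in the spec:
#' acetyl (CH3-CO-) at the N-terminus removes the terminal ammonium
#' hydrogens and restores a standard amide nitrogen; amide (-CO-NH2) or
#' N-methylamide (-CO-NH-CH3) at the C-terminus removes OXT and converts
#' the carboxylate to a standard carbonyl.  Cap atoms are stored as
#' pseudo-residues at positions 0 (ACE) and n+1 (NH2/NME).  Capping a
#' head-to-tail cyclic peptide is an error.
#'
#' @param structure A built `pep_structure` (zwitterionic termini).
#' @param spec The [peptide_spec()].
#' @param registry Template registry.
#' @return The capped structure.
#' @export
apply_caps <- function(structure, spec, registry = default_registry()) {
  if (spec$nc_cyclic && (spec$n_cap != "none" || spec$c_cap != "none")) {
    stop("cannot cap a head-to-tail cyclic peptide")
  }
  env <- structure_to_env(structure)
  n <- max(structure$atoms$resno)
  if (spec$n_cap == "acetyl") {
    cap <- lookup_template(registry, "ACE")
    for (hn in c("H1", "H2", "H3")) {
      env$rows[[paste(1L, hn, sep = "|")]] <- NULL
    }
    place_zmat(env, 0L, "ACE", cap, cap$zmat, host_resno = 1L)
    # restore the amide hydrogen on residue 1 (absent for proline-like N)
    tpl1 <- lookup_template(registry, spec$residues$code[1L])
    if (tpl1$amide_h) {
      place_amide_h(env, 1L, tpl1$code, get_atom(env, 0L, "C"))
    }
  }
  if (spec$c_cap != "none") {
    code <- if (spec$c_cap == "amide") "NH2" else "NME"
    cap <- lookup_template(registry, code)
    # carboxylate -> carbonyl: drop OXT, re-place O at amide geometry
    Ni <- get_atom(env, n, "N"); CAi <- get_atom(env, n, "CA")
    Ci <- get_atom(env, n, "C"); Oi <- get_atom(env, n, "O")
    psi_o <- measure_dihedral(Ni, CAi, Ci, Oi)
    env$rows[[paste(n, "OXT", sep = "|")]] <- NULL
    resid_n <- unique(structure$atoms$resid[structure$atoms$resno == n])[1L]
    add_atom(env, n, resid_n, "O", "O",
             place_atom(Ni, CAi, Ci, BB_GEOM$b_c_o, BB_GEOM$a_ca_c_o, psi_o))
    place_zmat(env, n + 1L, code, cap, cap$zmat, host_resno = n,
               psi = psi_o - 180)
  }
  env_to_structure(env, model_id = structure$model_id)
}

#' Build a complete peptide model
#'
#' Convenience pipeline: [build_backbone()], [place_sidechains()] and
#' [apply_caps()] in order.  D-residues are built mirrored directly.
#'
#' @inheritParams build_backbone
#' @param lib Rotamer library.
#' @return A `pep_structure` ready for topology construction.
#' @export
build_peptide <- function(spec, restraints, registry = default_registry(),
                          lib = rotamer_library()) {
  s <- build_backbone(spec, restraints, registry)
  s <- place_sidechains(s, spec, lib, registry)
  apply_caps(s, spec, registry)
}
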