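# Atom-level structure container.  A `pep_structure` is a data.frame of
# atoms (serial, name, element, resno, resid, x, y, z) wrapped with a
# model id; a `pep_ensemble` is a list of such models sharing an atom set.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resid`, `x`, `y`, `z` (serial is derived).
#' @param model_id Integer model identifier.
#' @return An object of class `pep_structure`.
#' @export
pep_structure <- function(atoms, model_id = 1L) {
  need <- c("name", "element", "resno", "resid", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  key <- paste(atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, atom name): ", key[duplicated(key)][1L])
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  structure(list(atoms = atoms[, c("serial", need)], model_id = model_id),
            class = "pep_structure")
}

#' @export
print.pep_structure <- function(x, ...) {
  cat("<pep_structure>", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues (model", x$model_id, ")\n")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure A `pep_structure`.
#' @return n x 3 numeric matrix (Angstrom), rows in atom order.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#'
#' @param structure A `pep_structure`.
#' @param xyz n x 3 matrix matching the atom order.
#' @return The updated structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3L)
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

# index of atom (resno, name); 0 when absent
atom_index <- function(structure, resno, name) {
  i <- which(structure$atoms$resno == resno & structure$atoms$name == name)
  if (length(i)) i[1L] else 0L
}

#' Coordinates of one named atom
#'
#' @param structure A `pep_structure`.
#' @param resno Residue position.
#' @param name Atom name (e.g. `"CA"`, `"SG"`).
#' @return Numeric length-3 coordinates (Angstrom); missing atoms error.
#' @export
atom_xyz <- function(structure, resno, name) {
  i <- atom_index(structure, resno, name)
  if (!i) stop("atom ", name, " of residue ", resno, " not found")
  as.numeric(structure$atoms[i, c("x", "y", "z")])
}

#' Measure a backbone or named dihedral in a structure
#'
#' `structure_phi_psi` returns the measured backbone (phi, psi) per
#' residue (NA at the chain ends).
#'
#' @param structure A `pep_structure`.
#' @return data.frame with columns `position, phi, psi` in degrees.
#' @export
structure_phi_psi <- function(structure) {
  resnos <- sort(unique(structure$atoms$resno[structure$atoms$resno >= 1L]))
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- resnos[k]
    if (atom_index(structure, i - 1L, "C") &&
        all(c(atom_index(structure, i, "N"), atom_index(structure, i, "CA"),
              atom_index(structure, i, "C")) > 0L)) {
      phi[k] <- measure_dihedral(atom_xyz(structure, i - 1L, "C"),
                                 atom_xyz(structure, i, "N"),
                                 atom_xyz(structure, i, "CA"),
                                 atom_xyz(structure, i, "C"))
    }
    if (atom_index(structure, i + 1L, "N")) {
      psi[k] <- measure_dihedral(atom_xyz(structure, i, "N"),
                                 atom_xyz(structure, i, "CA"),
                                 atom_xyz(structure, i, "C"),
                                 atom_xyz(structure, i + 1L, "N"))
    }
  }
  data.frame(position = resnos, phi = phi, psi = psi)
}

#' Build an ensemble from structures
#'
#' All models must share an identical (residue, atom-name) set.
#'
#' @param models List of `pep_structure` objects.
#' @param representative_model Optional model id declared as the best
#'   representative (as an NMR header would).
#' @return An object of class `pep_ensemble`.
#' @export
pep_ensemble <- function(models, representative_model = NULL) {
  stopifnot(length(models) >= 1L)
  key <- function(s) paste(s$atoms$resno, s$atoms$name)
  k1 <- key(models[[1L]])
  for (m in models[-1L]) {
    if (!identical(key(m), k1)) stop("models do not share an atom set")
  }
  for (i in seq_along(models)) models[[i]]$model_id <- i
  structure(list(models = models,
                 representative_model = representative_model),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  cat("<pep_ensemble>", length(x$models), "models,",
      nrow(x$models[[1L]]$atoms), "atoms each")
  if (!is.null(x$representative_model)) {
    cat(", representative model", x$representative_model)
  }
  cat("\n")
  invisible(x)
}

#' @export
length.pep_ensemble <- function(x) length(x$models)
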