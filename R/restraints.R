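# Secondary-structure and beta-turn annotations -> per-residue backbone
# torsion restraints; DSSP 8-state to 3-state reduction.

#' Reduce a DSSP 8-state string to 3 states
#'
#' Character-wise map over the DSSP alphabet \{T,S,G,H,I,B,E,-\}:
#' G and H become helix (H), B and E become strand (E), everything else
#' (T, S, I, -) becomes coil (C).
#'
#' @param states8 Character scalar over the DSSP alphabet (may be empty).
#' @return A 3-state string over \{H,E,C\} of the same length.
#' @export
reduce_dssp <- function(states8) {
  stopifnot(is.character(states8), length(states8) == 1L)
  chars <- strsplit(states8, "")[[1L]]
  map <- c(G = "H", H = "H", B = "E", E = "E",
           T = "C", S = "C", I = "C", "-" = "C")
  out <- map[chars]
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    stop("unknown DSSP state '", chars[i], "' at position ", i)
  }
  paste(out, collapse = "")
}

#' Regular secondary-structure content
#'
#' Fraction of residues in regular secondary structure (helix + strand),
#' used as the >= 60 % dataset gate for simulation subsets.
#'
#' @param states3 3-state string over \{H,E,C\}.
#' @return Fraction in \[0, 1\].
#' @export
ss_content <- function(states3) {
  chars <- strsplit(states3, "")[[1L]]
  if (!length(chars)) stop("empty secondary-structure string")
  if (!all(chars %in% c("H", "E", "C"))) {
    stop("secondary-structure alphabet must be {H, E, C}")
  }
  mean(chars %in% c("H", "E"))
}

#' Parse the 8-state string out of a DSSP output file
#'
#' Reads the per-residue summary section of a classic DSSP file (the block
#' following the `#  RESIDUE AA` header) and returns the 8-state string,
#' with blank structure columns reported as `'-'`.  Bare state strings are
#' returned unchanged, so both forms can be fed to [reduce_dssp()].
#'
#' @param input Path to a DSSP file, or a bare 8-state string.
#' @return Character scalar over the DSSP alphabet.
#' @export
read_dssp_states <- function(input) {
  if (!file.exists(input)) return(input)
  lines <- readLines(input, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) {
    # not a DSSP file: treat single line content as a bare state string
    txt <- trimws(paste(lines, collapse = ""))
    return(txt)
  }
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  # chain breaks are marked by '!' in the AA column (14); skip them
  aa <- substr(body, 14L, 14L)
  body <- body[aa != "!"]
  ss <- substr(body, 17L, 17L)
  ss[ss == " "] <- "-"
  paste(ss, collapse = "")
}

#' Bundled beta-turn type table
#'
#' Canonical (phi, psi) angles at turn positions i+1 and i+2 for the
#' classic turn types (I, I', II, II', IV, VIII), shipped as a plain-text
#' table (`extdata/turn_types.tsv`) that users may replace.
#'
#' @param path Optional path to an alternative table with columns
#'   `type, phi1, psi1, phi2, psi2`.
#' @return A data.frame of turn types.
#' @export
turn_type_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "turn_types.tsv", package = "pepbuildr")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# "I'" and "Ip" both normalize to the table key "Ip"
normalize_turn_type <- function(type) {
  t <- gsub("'", "p", type)
  paste0(toupper(gsub("p", "", t)), if (grepl("p", t)) "p" else "")
}

#' Assign backbone torsion restraints
#'
#' Converts a 3-state secondary-structure string plus optional beta-turn
#' annotations into per-residue (phi, psi) targets: helix residues get
#' (-60, -40), strand residues (-120, 120) and coil residues (180, 180),
#' the extended conformation.  For each annotated turn starting at residue
#' i, positions i+1 and i+2 receive that turn type's canonical angles from
#' the bundled table, overriding the secondary-structure assignment;
#' overlapping turns are resolved last-annotation-wins.  The first
#' residue's phi and the last residue's psi are undefined (NA).
#'
#' @param states3 3-state string over \{H,E,C\}.
#' @param turns Optional data.frame with columns `start` (1-based position
#'   i of the turn's first residue) and `type` (turn type code, e.g. "I",
#'   "II'", "VIII"), or `NULL`.
#' @param turn_table Turn-angle table (see [turn_type_table()]).
#' @return A `torsion_restraints` data.frame with columns
#'   `position, phi, psi` (degrees in (-180, 180], NA where undefined).
#' @export
assign_restraints <- function(states3, turns = NULL,
                              turn_table = turn_type_table()) {
  chars <- strsplit(states3, "")[[1L]]
  n <- length(chars)
  if (!all(chars %in% c("H", "E", "C"))) {
    stop("secondary-structure alphabet must be {H, E, C}")
  }
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    tor <- SS_TORSIONS[[chars[i]]]
    phi[i] <- tor[["phi"]]
    psi[i] <- tor[["psi"]]
  }
  if (!is.null(turns) && NROW(turns)) {
    for (k in seq_len(NROW(turns))) {
      i <- as.integer(turns$start[k])
      type <- normalize_turn_type(turns$type[k])
      if (i < 1L || i + 3L > n) {
        stop("turn at position ", i, " extends beyond the ", n,
             "-residue peptide")
      }
      row <- turn_table[turn_table$type == type, , drop = FALSE]
      if (!nrow(row)) stop("unknown turn type '", turns$type[k], "'")
      phi[i + 1L] <- row$phi1; psi[i + 1L] <- row$psi1
      phi[i + 2L] <- row$phi2; psi[i + 2L] <- row$psi2
    }
  }
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  phi[1L] <- NA_real_
  psi[n] <- NA_real_
  structure(data.frame(position = seq_len(n), phi = phi, psi = psi),
            class = c("torsion_restraints", "data.frame"))
}
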