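# Multi-model PDB reading and writing.  Implemented in-package because the
# evaluation stack needs MODEL/ENDMDL ensembles, the representative-model
# REMARK, SSBOND and closure CONECT records to round-trip together.

format_atom_name <- function(name, element) {
  # PDB columns 13-16: element-aligned
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 1L && nchar(name) <= 3L) {
    return(sprintf("%-4s", paste0(" ", name)))
  }
  sprintf("%-4s", name)
}

atom_record <- function(serial, name, resid, resno, x, y, z, element) {
  sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, format_atom_name(name, element),
          substr(resid, 1L, 3L), resno, x, y, z, 1, 0, element)
}

#' Write structures to PDB text
#'
#' Writes a `pep_structure` or multi-model `pep_ensemble` as standard PDB:
#' MODEL/ENDMDL blocks, fixed-width ATOM records (3-decimal coordinates),
#' TER, SSBOND records for `ssbond` pairs, a CONECT record for a
#' head-to-tail closure bond, and the representative-model declaration as
#' a REMARK 210 line when present.
#'
#' @param x A `pep_structure` or `pep_ensemble`.
#' @param path Optional output file.
#' @param ssbond Optional list of residue-position pairs with SG-SG bonds.
#' @param nc_conect Optional integer pair (n, 1) marking the closure bond
#'   C(n)-N(1); emitted as a CONECT record.
#' @return The PDB text as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
write_pdb <- function(x, path = NULL, ssbond = NULL, nc_conect = NULL) {
  if (inherits(x, "pep_structure")) {
    x <- structure(list(models = list(x), representative_model = NULL),
                   class = "pep_ensemble")
  }
  stopifnot(inherits(x, "pep_ensemble"))
  lines <- character()
  if (!is.null(x$representative_model)) {
    lines <- c(lines, sprintf(
      "REMARK 210 BEST REPRESENTATIVE CONFORMER IN THIS ENSEMBLE : %d",
      as.integer(x$representative_model)))
  }
  for (p in ssbond) {
    lines <- c(lines, sprintf(
      "SSBOND   1 CYS A %4d    CYS A %4d", p[1L], p[2L]))
  }
  multi <- length(x$models) > 1L
  conect <- character()
  for (m in seq_along(x$models)) {
    s <- x$models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    a <- s$atoms
    recs <- vapply(seq_len(nrow(a)), function(i) {
      atom_record(a$serial[i], a$name[i], a$resid[i], a$resno[i],
                  a$x[i], a$y[i], a$z[i], a$element[i])
    }, "")
    lines <- c(lines, recs, "TER")
    if (m == 1L && !is.null(nc_conect)) {
      ic <- atom_index(s, nc_conect[1L], "C")
      in_ <- atom_index(s, nc_conect[2L], "N")
      if (ic && in_) {
        conect <- sprintf("CONECT%5d%5d", a$serial[ic], a$serial[in_])
      }
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, conect, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Parses ATOM/HETATM records (fixed-width), MODEL/ENDMDL blocks and the
#' REMARK 210 representative-model declaration.  Malformed fixed-width
#' records are reported with their line number.
#'
#' @param input Path to a PDB file, or PDB text as a character vector.
#' @return A `pep_ensemble` (of one model for single-model files).
#' @export
read_pdb <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (length(input) == 1L) {
    strsplit(input, "\n")[[1L]]
  } else {
    input
  }
  rep_model <- NULL
  rm_hit <- grep("REMARK 210.*REPRESENTATIVE CONFORMER", lines, value = TRUE)
  if (length(rm_hit)) {
    v <- suppressWarnings(as.integer(sub(".*:\\s*", "", rm_hit[1L])))
    if (!is.na(v)) rep_model <- v
  }
  models <- list()
  cur <- list()
  flush_model <- function() {
    if (length(cur)) {
      df <- do.call(rbind, cur)
      models[[length(models) + 1L]] <<- pep_structure(
        df, model_id = length(models) + 1L)
    }
    cur <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1L, 6L)
    if (tag %in% c("ATOM  ", "HETATM")) {
      x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
      y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
      z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
      resno <- suppressWarnings(as.integer(substr(line, 23L, 26L)))
      if (anyNA(c(x, y, z)) || is.na(resno)) {
        stop("malformed ATOM record at line ", ln)
      }
      name <- trimws(substr(line, 13L, 16L))
      el <- trimws(substr(line, 77L, 78L))
      if (!nzchar(el)) el <- substr(gsub("^[0-9]*", "", name), 1L, 1L)
      cur[[length(cur) + 1L]] <- data.frame(
        name = name, element = el, resno = resno,
        resid = trimws(substr(line, 18L, 21L)), x = x, y = y, z = z)
    } else if (tag == "ENDMDL") {
      flush_model()
    }
  }
  flush_model()
  if (!length(models)) stop("no ATOM records found")
  structure(list(models = models, representative_model = rep_model),
            class = "pep_ensemble")
}
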