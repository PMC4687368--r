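# Domain model for a modifiable peptide: an ordered list of residue
# specifications (code + chirality) plus terminal caps, head-to-tail
# cyclization and disulfide directives.

#' Construct a peptide specification
#'
#' @param residues A data.frame with columns `position`, `code`,
#'   `chirality` ("L"/"D") — or a plain sequence string of one-letter
#'   codes, in which case all residues are natural L.
#' @param n_cap `"none"` or `"acetyl"`.
#' @param c_cap `"none"`, `"amide"` or `"n_methylamide"`.
#' @param nc_cyclic Head-to-tail cyclization flag; excludes caps.
#' @param disulfide_pairs List of integer pairs `(i, j)` of positions
#'   forming disulfide bridges (residues must carry a thiol SG atom).
#' @param registry Template registry used for validation.
#' @param length_bounds Allowed length range; the default 7–25 is a service
#'   policy (short bioactive peptides), overridable for other uses.
#' @return An object of class `peptide_spec`.
#' @export
peptide_spec <- function(residues,
                         n_cap = "none",
                         c_cap = "none",
                         nc_cyclic = FALSE,
                         disulfide_pairs = list(),
                         registry = default_registry(),
                         length_bounds = LENGTH_BOUNDS) {
  if (is.character(residues) && length(residues) == 1L) {
    codes <- strsplit(residues, "")[[1L]]
    residues <- data.frame(position = seq_along(codes), code = codes,
                           chirality = "L")
  }
  stopifnot(is.data.frame(residues),
            all(c("position", "code", "chirality") %in% names(residues)))
  residues <- residues[order(residues$position), , drop = FALSE]
  rownames(residues) <- NULL
  spec <- structure(list(
    residues = residues,
    n_cap = match.arg(n_cap, c("none", "acetyl")),
    c_cap = match.arg(c_cap, c("none", "amide", "n_methylamide")),
    nc_cyclic = isTRUE(nc_cyclic),
    disulfide_pairs = disulfide_pairs
  ), class = "peptide_spec")
  validate_peptide_spec(spec, registry = registry,
                        length_bounds = length_bounds)
}

#' Validate a peptide specification
#'
#' Enforces the spec invariants: positions are 1..n, every code resolves to
#' exactly one registered template, chirality D is rejected on achiral
#' residues (glycine, Aib), the length is within bounds, head-to-tail
#' cyclization excludes terminal caps, and each disulfide pair references
#' two distinct thiol-bearing residues with no position reused.
#'
#' @param spec A `peptide_spec`.
#' @inheritParams peptide_spec
#' @return The validated spec, invisibly usable.
#' @export
validate_peptide_spec <- function(spec, registry = default_registry(),
                                  length_bounds = LENGTH_BOUNDS) {
  r <- spec$residues
  n <- nrow(r)
  if (!identical(as.integer(r$position), seq_len(n))) {
    stop("residue positions must be exactly 1..", n)
  }
  if (n < length_bounds[["min"]] || n > length_bounds[["max"]]) {
    stop("peptide length ", n, " outside allowed bounds [",
         length_bounds[["min"]], ", ", length_bounds[["max"]], "]")
  }
  bad <- character()
  for (i in seq_len(n)) {
    tpl <- tryCatch(lookup_template(registry, r$code[i]), error = function(e) NULL)
    if (is.null(tpl)) {
      bad <- c(bad, sprintf("position %d: unknown residue code '%s'",
                            i, r$code[i]))
      next
    }
    if (identical(tpl$class, "cap")) {
      bad <- c(bad, sprintf("position %d: '%s' is a cap, not a residue",
                            i, r$code[i]))
    }
    if (identical(r$chirality[i], "D") && !tpl$chiral) {
      bad <- c(bad, sprintf("position %d: residue '%s' is achiral and cannot be D",
                            i, r$code[i]))
    }
    if (!r$chirality[i] %in% c("L", "D")) {
      bad <- c(bad, sprintf("position %d: chirality must be L or D", i))
    }
  }
  if (length(bad)) stop(paste(bad, collapse = "\n"))
  if (spec$nc_cyclic && (spec$n_cap != "none" || spec$c_cap != "none")) {
    stop("head-to-tail cyclization excludes terminal caps")
  }
  used <- integer()
  for (p in spec$disulfide_pairs) {
    p <- as.integer(p)
    if (length(p) != 2L || p[1L] == p[2L] || any(p < 1L | p > n)) {
      stop("malformed disulfide pair: (", paste(p, collapse = ","), ")")
    }
    for (i in p) {
      tpl <- lookup_template(registry, r$code[i])
      if (!"SG" %in% tpl$atoms$name) {
        stop("disulfide pair references residue ", i, " ('", r$code[i],
             "'), which has no thiol SG atom")
      }
    }
    if (any(p %in% used)) {
      stop("position ", intersect(p, used)[1L], " appears in two disulfide pairs")
    }
    used <- c(used, p)
  }
  spec
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("<peptide_spec> length", nrow(x$residues), "\n")
  cat(" sequence:", mask_nonnatural(x), "\n")
  mods <- x$residues[x$residues$chirality == "D" | nchar(x$residues$code) > 1L, ]
  if (nrow(mods)) {
    cat(" modified:", paste(sprintf("%d:%s(%s)", mods$position, mods$code,
                                    mods$chirality), collapse = " "), "\n")
  }
  if (x$n_cap != "none") cat(" n_cap:", x$n_cap, "\n")
  if (x$c_cap != "none") cat(" c_cap:", x$c_cap, "\n")
  if (x$nc_cyclic) cat(" head-to-tail cyclic\n")
  for (p in x$disulfide_pairs) cat(" disulfide:", p[1L], "-", p[2L], "\n")
  invisible(x)
}

#' Parse a peptide specification from a structured config
#'
#' The config is YAML with a `sequence` string (one-letter codes) plus
#' optional modification directives:
#' \preformatted{
#' sequence: ACDKGCKLLAG
#' n_cap: acetyl            # none | acetyl
#' c_cap: amide             # none | amide | n_methylamide
#' nc_cyclic: false
#' disulfides: [[2, 6]]
#' residues:                # per-position overrides
#'   - {position: 4, code: ORN}       # replace by template code
#'   - {position: 7, chirality: D}    # stereo flip
#' }
#'
#' @param config_text YAML text, or the path to a YAML file.
#' @inheritParams peptide_spec
#' @return A validated [peptide_spec()].
#' @export
parse_peptide_spec <- function(config_text, registry = default_registry(),
                               length_bounds = LENGTH_BOUNDS) {
  cfg <- if (length(config_text) == 1L && file.exists(config_text) &&
             !grepl("\n", config_text)) {
    yaml::read_yaml(config_text)
  } else {
    yaml::yaml.load(paste(config_text, collapse = "\n"))
  }
  if (is.null(cfg$sequence)) stop("config must name a 'sequence'")
  codes <- strsplit(toupper(gsub("[[:space:]]", "", cfg$sequence)), "")[[1L]]
  residues <- data.frame(position = seq_along(codes), code = codes,
                         chirality = "L")
  for (ov in cfg$residues) {
    p <- as.integer(ov$position)
    if (is.na(p) || p < 1L || p > nrow(residues)) {
      stop("residue directive references position ", ov$position,
           " of a ", nrow(residues), "-residue peptide")
    }
    if (!is.null(ov$code)) residues$code[p] <- ov$code
    if (!is.null(ov$chirality)) residues$chirality[p] <- toupper(ov$chirality)
  }
  pairs <- lapply(cfg$disulfides, as.integer)
  peptide_spec(residues,
               n_cap = cfg$n_cap %||% "none",
               c_cap = cfg$c_cap %||% "none",
               nc_cyclic = isTRUE(cfg$nc_cyclic),
               disulfide_pairs = pairs,
               registry = registry,
               length_bounds = length_bounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a peptide specification back to YAML
#'
#' The output round-trips through [parse_peptide_spec()] to an identical
#' spec.
#'
#' @param spec A `peptide_spec`.
#' @param path Optional file to write; otherwise the YAML text is returned.
#' @return YAML text (invisibly if written to `path`).
#' @export
write_peptide_spec <- function(spec, path = NULL) {
  r <- spec$residues
  base <- vapply(r$code, function(code) {
    if (nchar(code) == 1L) code else "?"
  }, "")
  # non-natural positions are emitted as overrides on a placeholder letter;
  # use the template parent letter so the sequence remains parseable
  seq_letters <- base
  overrides <- list()
  for (i in seq_len(nrow(r))) {
    if (nchar(r$code[i]) > 1L) {
      seq_letters[i] <- "A"   # placeholder, replaced by the override
      overrides[[length(overrides) + 1L]] <-
        list(position = i, code = r$code[i])
    }
    if (identical(r$chirality[i], "D")) {
      overrides[[length(overrides) + 1L]] <-
        list(position = i, chirality = "D")
    }
  }
  cfg <- list(sequence = paste(seq_letters, collapse = ""))
  if (spec$n_cap != "none") cfg$n_cap <- spec$n_cap
  if (spec$c_cap != "none") cfg$c_cap <- spec$c_cap
  if (spec$nc_cyclic) cfg$nc_cyclic <- TRUE
  if (length(spec$disulfide_pairs)) {
    cfg$disulfides <- lapply(spec$disulfide_pairs, as.integer)
  }
  if (length(overrides)) cfg$residues <- overrides
  txt <- yaml::as.yaml(cfg)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Mask non-natural residues in a sequence
#'
#' Produces the one-character-per-residue string handed to external
#' secondary-structure and turn predictors: non-natural residues become
#' `'X'`, while natural residues, D-residues and PTM-carrying natural
#' residues keep their parent one-letter code.  Masking is idempotent
#' (`'X'` is itself reported as `'X'`).
#'
#' @param spec A `peptide_spec`.
#' @param registry Template registry.
#' @return A character scalar, one character per residue.
#' @export
mask_nonnatural <- function(spec, registry = default_registry()) {
  chars <- vapply(spec$residues$code, function(code) {
    if (identical(code, "X")) return("X")   # already masked: idempotent
    tpl <- lookup_template(registry, code)
    switch(tpl$class,
           natural = tpl$letter,
           ptm = tpl$letter,       # parent one-letter code
           nonnatural = "X",
           stop("cannot mask residue of class '", tpl$class, "'"))
  }, "")
  paste(chars, collapse = "")
}

#' Read a plain peptide sequence from FASTA
#'
#' Thin wrapper over `seqinr::read.fasta` returning the first sequence as
#' an upper-case string.
#'
#' @param path FASTA file path.
#' @return Character scalar sequence.
#' @export
read_fasta_sequence <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (!length(seqs)) stop("no sequences in ", path)
  toupper(as.character(seqs[[1L]]))
}
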