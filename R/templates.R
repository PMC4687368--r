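# Residue template registry.  A template carries everything the builder and
# the force-field need for one residue type: atoms with partial charges and
# Lennard-Jones parameters, internal-coordinate (z-matrix) records for every
# atom beyond the backbone N/CA/C frame, ring-closure bonds and side-chain
# torsion (chi) definitions.  Templates are plain-text files so users can
# add entries for further non-natural or post-translationally modified
# residues without touching the package.

#' Parse a residue template file
#'
#' Reads one plain-text template.  The format is line-oriented,
#' whitespace-separated, with `#` comments:
#' \preformatted{
#' code ALA
#' class natural          # natural | nonnatural | ptm | cap
#' letter A               # one-letter parent code ('X'/'-' where none)
#' formal_charge 0
#' chiral yes
#' amide_h yes
#' atom <name> <element> <charge e> <LJ rmin/2 A> <LJ eps kcal/mol> <hyb>
#' zmat <atom> <bond ref> <angle ref> <torsion ref> <length> <angle> <torsion>
#' bond <a> <b> <length>  # ring-closure bonds not implied by the z-matrix
#' chi  chi1 N CA CB CG
#' }
#' The `torsion` field of a `zmat` record is a number in degrees, a chi slot
#' expression (`chi1`, `chi2+120`, ...) filled from the rotamer library, or
#' `psi` (used by C-terminal caps, resolved from the host backbone).  Cap
#' templates reference host backbone atoms as `@N`, `@CA`, `@C`.
#'
#' @param path Path to a `.tpl` file.
#' @return An object of class `residue_template`.
#' @export
read_template <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  toks <- strsplit(raw, "[[:space:]]+")
  fields <- list()
  atoms <- list(); zmat <- list(); bonds <- list(); chis <- list()
  for (tk in toks) {
    key <- tk[1L]
    if (key == "atom") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = tk[2L], element = tk[3L], charge = as.numeric(tk[4L]),
        rmin2 = as.numeric(tk[5L]), eps = as.numeric(tk[6L]), hyb = tk[7L])
    } else if (key == "zmat") {
      zmat[[length(zmat) + 1L]] <- data.frame(
        atom = tk[2L], ref1 = tk[3L], ref2 = tk[4L], ref3 = tk[5L],
        length = as.numeric(tk[6L]), angle = as.numeric(tk[7L]),
        torsion = tk[8L])
    } else if (key == "bond") {
      bonds[[length(bonds) + 1L]] <- data.frame(
        a = tk[2L], b = tk[3L], length = as.numeric(tk[4L]))
    } else if (key == "chi") {
      chis[[tk[2L]]] <- tk[3:6]
    } else {
      fields[[key]] <- paste(tk[-1L], collapse = " ")
    }
  }
  tpl <- structure(list(
    code = fields$code,
    class = fields$class,
    letter = fields$letter,
    fullname = fields$fullname,
    formal_charge = as.numeric(fields$formal_charge),
    chiral = identical(fields$chiral, "yes"),
    amide_h = identical(fields$amide_h, "yes"),
    atoms = if (length(atoms)) do.call(rbind, atoms) else NULL,
    zmat = if (length(zmat)) do.call(rbind, zmat) else NULL,
    bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
    chis = chis,
    provenance = basename(path)
  ), class = "residue_template")
  validate_template(tpl)
  tpl
}

#' Validate a residue template
#'
#' Checks the template invariants: every atom outside the backbone frame
#' (N/CA/C) has a z-matrix record whose references are known atoms, chi
#' definitions name existing atoms, and the net partial charge equals the
#' declared formal charge to within 1e-6.
#'
#' @param tpl A `residue_template`.
#' @return The template, invisibly; errors describe the defect.
#' @export
validate_template <- function(tpl) {
  if (is.null(tpl$code) || !nzchar(tpl$code)) stop("template missing code")
  if (is.null(tpl$atoms)) stop("template '", tpl$code, "' has no atoms")
  nm <- tpl$atoms$name
  if (anyDuplicated(nm)) stop("template '", tpl$code, "': duplicate atom names")
  frame <- if (identical(tpl$class, "cap")) character() else c("N", "CA", "C")
  # backbone O and amide H are placed by the builder, not the z-matrix
  builder_managed <- if (identical(tpl$class, "cap")) character() else c("O", "H")
  need <- setdiff(nm, c(frame, builder_managed))
  zatoms <- tpl$zmat$atom
  missing <- setdiff(need, zatoms)
  if (length(missing)) {
    stop("template '", tpl$code, "': atoms without internal-coordinate ",
         "records: ", paste(missing, collapse = ", "))
  }
  host_refs <- c("@N", "@CA", "@C")
  for (i in seq_len(NROW(tpl$zmat))) {
    refs <- unlist(tpl$zmat[i, c("ref1", "ref2", "ref3")])
    bad <- setdiff(refs, c(nm, frame, host_refs))
    if (length(bad)) {
      stop("template '", tpl$code, "': z-matrix record for ",
           tpl$zmat$atom[i], " references unknown atom(s): ",
           paste(bad, collapse = ", "))
    }
  }
  for (cn in names(tpl$chis)) {
    bad <- setdiff(tpl$chis[[cn]], nm)
    if (length(bad)) {
      stop("template '", tpl$code, "': chi definition ", cn,
           " names unknown atom(s): ", paste(bad, collapse = ", "))
    }
  }
  dq <- abs(sum(tpl$atoms$charge) - tpl$formal_charge)
  if (dq > 1e-6) {
    stop("template '", tpl$code, "': net charge deviates from formal ",
         "charge by ", format(dq))
  }
  invisible(tpl)
}

#' @export
print.residue_template <- function(x, ...) {
  cat("<residue_template>", x$code, sprintf("(%s, %s)", x$class, x$fullname),
      "\n  atoms:", nrow(x$atoms), " zmat:", NROW(x$zmat),
      " chis:", length(x$chis), "\n")
  invisible(x)
}

#' Create a template registry
#'
#' A registry maps residue codes to [residue_template][read_template()]
#' objects.  `default_registry()` loads the library bundled with the
#' package: the 20 natural residues, fixture templates for an ornithine-like
#' and Aib-like non-natural residue, phosphoserine-like and
#' hydroxyproline-like PTM residues, and the acetyl/amide/N-methylamide
#' terminal caps.  Bundled non-natural parameter values are physically
#' plausible placeholders, not copies of any published force-field library.
#'
#' @param dir Directory of `.tpl` files (default: the bundled library).
#' @return An object of class `template_registry`.
#' @export
template_registry <- function(dir = NULL) {
  reg <- structure(list(templates = list()), class = "template_registry")
  if (!is.null(dir)) {
    for (f in sort(list.files(dir, pattern = "\\.tpl$", full.names = TRUE))) {
      reg <- register_template(reg, read_template(f))
    }
  }
  reg
}

#' @rdname template_registry
#' @export
default_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- template_registry(system.file("extdata", "templates",
                                              package = "pepbuildr"))
    }
    cache
  }
})

#' Register a residue template
#'
#' @param registry A `template_registry`.
#' @param template A validated `residue_template`.
#' @param override Allow replacing an existing code (default `FALSE`).
#' @return The updated registry.
#' @export
register_template <- function(registry, template, override = FALSE) {
  stopifnot(inherits(registry, "template_registry"),
            inherits(template, "residue_template"))
  validate_template(template)
  if (!override && template$code %in% names(registry$templates)) {
    stop("template code '", template$code,
         "' already registered (use override = TRUE to replace)")
  }
  registry$templates[[template$code]] <- template
  registry
}

#' Look up a template by code
#'
#' One-letter codes resolve through the natural-residue table; multi-letter
#' codes must match a registered template exactly.
#'
#' @param registry A `template_registry`.
#' @param code Residue code (one-letter or template code).
#' @return A `residue_template`; unknown codes raise an error.
#' @export
lookup_template <- function(registry, code) {
  if (nchar(code) == 1L) {
    hit <- Filter(function(t) identical(t$letter, code) &&
                    identical(t$class, "natural"), registry$templates)
    if (length(hit) == 1L) return(hit[[1L]])
    stop("no natural residue template for one-letter code '", code, "'")
  }
  tpl <- registry$templates[[code]]
  if (is.null(tpl)) stop("unknown residue template code '", code, "'")
  tpl
}

#' @export
print.template_registry <- function(x, ...) {
  cls <- vapply(x$templates, function(t) t$class, "")
  cat("<template_registry>", length(x$templates), "templates (",
      sum(cls == "natural"), "natural,", sum(cls == "nonnatural"),
      "non-natural,", sum(cls == "ptm"), "PTM,", sum(cls == "cap"),
      "caps )\n")
  invisible(x)
}

#' @export
length.template_registry <- function(x) length(x$templates)
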