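# Deterministic fixture generators: ideal-geometry peptides built through
# the restraints + builder modules, and synthetic NMR-like ensembles with
# seeded Gaussian coordinate noise.  These exercise every stage offline;
# the Gaussian ensemble model is a statistical stand-in, not a physical
# NMR model.

#' Fixture generator configuration
#'
#' @param seed Integer seed; fixed seed implies bit-identical outputs.
#' @param length Number of residues.
#' @param noise_sd Per-coordinate Gaussian noise s.d. (Angstrom, >= 0).
#' @param n_models Number of ensemble models.
#' @param ss_pattern Secondary-structure string (recycled single letter
#'   allowed, e.g. "H"); defaults to all-coil.
#' @param sequence One-letter sequence; defaults to poly-alanine.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, length = 12L, noise_sd = 0.2,
                           n_models = 10L, ss_pattern = "C",
                           sequence = NULL) {
  stopifnot(noise_sd >= 0)
  if (is.null(sequence)) sequence <- strrep("A", length)
  if (nchar(ss_pattern) == 1L) ss_pattern <- strrep(ss_pattern, length)
  stopifnot(nchar(sequence) == length, nchar(ss_pattern) == length)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 noise_sd = noise_sd, n_models = as.integer(n_models),
                 ss_pattern = ss_pattern, sequence = sequence),
            class = "fixture_config")
}

#' Build an ideal-geometry peptide fixture
#'
#' Assigns torsion restraints from `ss_pattern` and builds the full-atom
#' model through the standard pipeline; serves as ground truth for
#' torsion-fidelity and evaluation tests.
#'
#' @param config A [fixture_config()].
#' @param registry Template registry.
#' @return A `pep_structure`.
#' @export
make_ideal_peptide <- function(config = fixture_config(),
                               registry = default_registry()) {
  spec <- peptide_spec(config$sequence, registry = registry)
  restr <- assign_restraints(config$ss_pattern)
  build_peptide(spec, restr, registry = registry)
}

#' Perturb a structure into a synthetic NMR-like ensemble
#'
#' Creates `n_models` copies of `base` with i.i.d. Gaussian noise of s.d.
#' `noise_sd` on every coordinate (so the expected CA RMSF about the mean
#' is ~ sqrt(3) * noise_sd for many models).  `displace` pushes chosen
#' residues by an extra offset whose sign alternates across models, so a
#' displaced residue's CA RMSF is approximately the displacement
#' magnitude — used to engineer non-core residues for rigid-core tests.
#'
#' @param base A `pep_structure`.
#' @param config A [fixture_config()] (`seed`, `noise_sd`, `n_models`).
#' @param displace Optional named list: residue position -> displacement
#'   magnitude (Angstrom), applied along x.
#' @return A `pep_ensemble`.
#' @export
make_noisy_ensemble <- function(base, config = fixture_config(),
                                displace = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  xyz <- coords(base)
  models <- lapply(seq_len(config$n_models), function(m) {
    noisy <- xyz + matrix(stats::rnorm(length(xyz), sd = config$noise_sd),
                          nrow(xyz), 3L)
    if (!is.null(displace)) {
      sgn <- if (m %% 2L == 1L) 1 else -1
      for (resno in names(displace)) {
        rows <- base$atoms$resno == as.integer(resno)
        noisy[rows, 1L] <- noisy[rows, 1L] + sgn * displace[[resno]]
      }
    }
    set_coords(base, noisy)
  })
  pep_ensemble(models)
}
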