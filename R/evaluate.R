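# Evaluation stack: hydrogen stripping, NMR reference-model selection,
# Kabsch least-squares superposition, RMSD / CA-RMSD / B-RMSD, per-residue
# CA RMS-fluctuation rigid core, and the dataset filters.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Remove hydrogen atoms from a structure
#'
#' Drops all H (and D) atoms, preserving heavy-atom order.  Evaluation
#' metrics are computed on hydrogen-free structures, matching the usual
#' practice of removing hydrogens from both experimental and predicted
#' models before RMSD computation.  Idempotent.
#'
#' @param structure A `pep_structure`.
#' @return The hydrogen-free structure.
#' @export
strip_hydrogens <- function(structure) {
  keep <- !structure$atoms$element %in% c("H", "D")
  structure$atoms <- structure$atoms[keep, , drop = FALSE]
  structure$atoms$serial <- seq_len(nrow(structure$atoms))
  rownames(structure$atoms) <- NULL
  structure
}

#' Select the reference model of an experimental ensemble
#'
#' NMR entries may declare a best-representative conformer; that model is
#' used as the reference.  Without a declaration, the first model is
#' used.
#'
#' @param ensemble A `pep_ensemble`.
#' @return A `pep_structure`.
#' @export
select_reference <- function(ensemble) {
  stopifnot(inherits(ensemble, "pep_ensemble"))
  if (!length(ensemble$models)) stop("empty ensemble")
  m <- ensemble$representative_model
  if (!is.null(m)) {
    if (m < 1L || m > length(ensemble$models)) {
      stop("declared representative model ", m, " not present")
    }
    return(ensemble$models[[m]])
  }
  ensemble$models[[1L]]
}

# matched coordinate pair for a selection; errors list missing atoms
matched_coords <- function(mobile, reference, selection) {
  sel_filter <- function(a) {
    switch(selection,
           all = rep(TRUE, nrow(a)),
           ca = a$name == "CA",
           backbone = a$name %in% BACKBONE_ATOMS,
           stop("unknown selection '", selection, "'"))
  }
  am <- mobile$atoms[sel_filter(mobile$atoms), , drop = FALSE]
  ar <- reference$atoms[sel_filter(reference$atoms), , drop = FALSE]
  km <- paste(am$resno, am$name)
  kr <- paste(ar$resno, ar$name)
  miss_m <- setdiff(kr, km)
  miss_r <- setdiff(km, kr)
  if (length(miss_m) || length(miss_r)) {
    stop("atom selections do not correspond 1:1; missing from mobile: [",
         paste(miss_m, collapse = ", "), "]; missing from reference: [",
         paste(miss_r, collapse = ", "), "]")
  }
  ar <- ar[match(km, kr), , drop = FALSE]
  list(mobile = as.matrix(am[, c("x", "y", "z")]),
       reference = as.matrix(ar[, c("x", "y", "z")]))
}

# Kabsch: rotation R (for right-multiplication, P %*% R) minimizing
# |P R - Q| over proper rotations
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Computes the least-squares optimal rotation + translation of `mobile`
#' onto `reference` over the chosen atom selection (`"all"`, `"ca"`, or
#' `"backbone"` = N, CA, C, O), and the RMSD over that selection after
#' the transform.  Atoms correspond by (residue position, atom name);
#' mismatches are an error listing the missing atoms.
#'
#' @param mobile,reference `pep_structure` objects of the same sequence.
#' @param selection `"all"`, `"ca"` or `"backbone"`.
#' @return A `superposition_result`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom), `atom_selection`, and
#'   `transformed` (the mobile structure after the transform).
#' @export
superpose <- function(mobile, reference,
                      selection = c("all", "ca", "backbone")) {
  selection <- match.arg(selection)
  mc <- matched_coords(mobile, reference, selection)
  P <- mc$mobile; Q <- mc$reference
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  R <- kabsch_rotation(Pc, Qc)
  Pr <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  full <- sweep(coords(mobile), 2L, cp)
  moved <- sweep(full %*% R, 2L, cq, "+")
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd, atom_selection = selection,
                 transformed = set_coords(mobile, moved)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> %s-atom RMSD %.4f A\n",
              x$atom_selection, x$rmsd))
  invisible(x)
}

#' Rigid core of a multi-model ensemble
#'
#' Superposes every model onto model 1 over all CA atoms, computes each
#' residue's CA root-mean-square fluctuation about its mean position, and
#' returns the residues fluctuating less than `threshold` (default 1.5
#' Angstrom) — the rigid-core region used for ensemble-level comparison
#' of flexible NMR structures.
#'
#' @param ensemble A `pep_ensemble` with at least 2 models carrying CA
#'   atoms.
#' @param threshold RMSF inclusion threshold in Angstrom.
#' @param iterate_mean Refine the superposition reference by iterating
#'   on the ensemble mean CA coordinates (off by default: single pass
#'   onto model 1).
#' @return A `rigid_core`: `residues` (positions in the core), `rmsf`
#'   (named per-residue fluctuation), `threshold`.
#' @export
rigid_core <- function(ensemble, threshold = 1.5, iterate_mean = FALSE) {
  stopifnot(inherits(ensemble, "pep_ensemble"))
  if (length(ensemble$models) < 2L) {
    stop("rigid core needs an ensemble of at least 2 models")
  }
  ref <- ensemble$models[[1L]]
  if (!any(ref$atoms$name == "CA")) stop("models carry no CA atoms")
  get_ca <- function(s) {
    a <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    list(resno = a$resno, xyz = as.matrix(a[, c("x", "y", "z")]))
  }
  aligned <- lapply(ensemble$models, function(m) {
    sup <- superpose(m, ref, selection = "ca")
    get_ca(sup$transformed)
  })
  if (iterate_mean) {
    for (pass in 1:3) {
      mean_xyz <- Reduce(`+`, lapply(aligned, `[[`, "xyz")) / length(aligned)
      mean_ref <- ref
      ca_idx <- which(mean_ref$atoms$name == "CA")
      mean_ref$atoms <- mean_ref$atoms[ca_idx, , drop = FALSE]
      mean_ref$atoms[, c("x", "y", "z")] <- mean_xyz
      mean_ref$atoms$serial <- seq_len(nrow(mean_ref$atoms))
      aligned <- lapply(ensemble$models, function(m) {
        sup <- superpose(m, mean_ref, selection = "ca")
        get_ca(sup$transformed)
      })
    }
  }
  resno <- aligned[[1L]]$resno
  stack <- simplify2array(lapply(aligned, `[[`, "xyz"))  # res x 3 x model
  mean_xyz <- apply(stack, c(1L, 2L), mean)
  dev2 <- apply(stack, 3L, function(m) rowSums((m - mean_xyz)^2))
  rmsf <- sqrt(rowMeans(dev2))
  names(rmsf) <- resno
  structure(list(residues = resno[rmsf < threshold], rmsf = rmsf,
                 threshold = threshold), class = "rigid_core")
}

#' @export
print.rigid_core <- function(x, ...) {
  cat("<rigid_core>", length(x$residues), "of", length(x$rmsf),
      "residues below", x$threshold, "A CA RMSF\n")
  invisible(x)
}

#' Dataset filters for benchmark record sets
#'
#' Keeps records with sequence length in `[min_len, max_len]`, no
#' disulfide bridge, and the first occurrence of each sequence
#' (duplicates removed).
#'
#' @param records data.frame with columns `id`, `sequence`, `length`,
#'   `has_disulfide`.
#' @param min_len,max_len Inclusive length bounds (defaults 7 and 25).
#' @return The surviving subset of `records`.
#' @export
filter_dataset <- function(records, min_len = 7L, max_len = 25L) {
  stopifnot(all(c("id", "sequence", "length", "has_disulfide") %in%
                names(records)))
  keep <- records$length >= min_len & records$length <= max_len &
    !records$has_disulfide & !duplicated(records$sequence)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structure-vs-reference evaluation report
#'
#' Superposes a predicted structure onto the reference model of an
#' experimental ensemble (honouring the representative-model rule) and
#' reports RMSD (all heavy atoms), CA-RMSD and B-RMSD, plus the same
#' metrics restricted to the ensemble rigid core when the ensemble has
#' multiple models.  Hydrogens are stripped from both sides first.
#'
#' @param predicted A `pep_structure`.
#' @param reference_ensemble A `pep_ensemble` (or single-model structure).
#' @param core_threshold Rigid-core CA RMSF threshold (Angstrom).
#' @return A one-row data.frame of metrics.
#' @export
evaluate_structures <- function(predicted, reference_ensemble,
                                core_threshold = 1.5) {
  if (inherits(reference_ensemble, "pep_structure")) {
    reference_ensemble <- pep_ensemble(list(reference_ensemble))
  }
  stripped <- pep_ensemble(lapply(reference_ensemble$models,
                                  strip_hydrogens),
                           reference_ensemble$representative_model)
  ref <- select_reference(stripped)
  pred <- strip_hydrogens(predicted)
  # caps and chain termini may differ between prediction and experiment;
  # compare over the residues present in both
  common <- intersect(unique(pred$atoms$resno), unique(ref$atoms$resno))
  restrict <- function(s, keys) {
    s$atoms <- s$atoms[paste(s$atoms$resno, s$atoms$name) %in% keys, ,
                       drop = FALSE]
    s$atoms$serial <- seq_len(nrow(s$atoms))
    s
  }
  kp <- paste(pred$atoms$resno, pred$atoms$name)
  kr <- paste(ref$atoms$resno, ref$atoms$name)
  keys <- intersect(kp, kr)
  pred <- restrict(pred, keys)
  ref <- restrict(ref, keys)
  out <- data.frame(
    n_res = length(common),
    rmsd = superpose(pred, ref, "all")$rmsd,
    ca_rmsd = superpose(pred, ref, "ca")$rmsd,
    b_rmsd = superpose(pred, ref, "backbone")$rmsd,
    reference_model = if (!is.null(stripped$representative_model)) {
      stripped$representative_model
    } else 1L)
  if (length(stripped$models) > 1L) {
    core <- rigid_core(stripped, threshold = core_threshold)
    if (length(core$residues) >= 3L) {
      core_keys <- keys[as.integer(sub(" .*", "", keys)) %in% core$residues]
      pc <- restrict(pred, core_keys)
      rc <- restrict(ref, core_keys)
      out$core_n_res <- length(core$residues)
      out$core_ca_rmsd <- superpose(pc, rc, "ca")$rmsd
      out$core_b_rmsd <- superpose(pc, rc, "backbone")$rmsd
    }
  }
  out
}
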