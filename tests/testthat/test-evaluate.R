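# Superposition, RMSD metrics, rigid core and dataset filters.

test_that("superposition recovers identity and rigid motions exactly", {
  fx <- fix_coil7()
  s <- fx$structure
  sup <- superpose(s, s, "ca")
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- set_coords(s, sweep(coords(s) %*% R, 2, c(5, -1, 2), "+"))
  expect_lt(superpose(moved, s, "all")$rmsd, 1e-9)
})

test_that("the 2-point toy superposes to RMSD 0.5", {
  mk <- function(xyz) pep_structure(data.frame(
    name = "CA", element = "C", resno = seq_len(nrow(xyz)), resid = "GLY",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  A <- mk(rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  B <- mk(rbind(c(0, 1, 0), c(0, -1, 0)))
  expect_equal(superpose(A, B, "ca")$rmsd, 0.5, tolerance = 1e-9)
  expect_equal(brute_force_rmsd(coords(A), coords(B)), 0.5,
               tolerance = 1e-6)
})

test_that("Kabsch RMSD equals the rotation-grid brute-force optimum", {
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(3:5, 1)
    P <- matrix(rnorm(3 * n, sd = 2), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 2), n, 3)
    mk <- function(xyz) pep_structure(data.frame(
      name = "CA", element = "C", resno = seq_len(nrow(xyz)),
      resid = "GLY", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
    kab <- superpose(mk(P), mk(Q), "ca")$rmsd
    bf <- brute_force_rmsd(P, Q)
    expect_lt(abs(kab - bf), 1e-3)
    expect_lte(kab, bf + 1e-9)   # Kabsch is the optimum
  }
})

test_that("RMSD is symmetric and never above the unsuperposed value", {
  set.seed(43)
  fx <- fix_coil7()
  s <- fx$structure
  for (rep in 1:10) {
    pert <- set_coords(s, coords(s) +
                       matrix(rnorm(3 * nrow(s$atoms), sd = runif(1, 0.1, 2)),
                              ncol = 3))
    ab <- superpose(s, pert, "all")$rmsd
    ba <- superpose(pert, s, "all")$rmsd
    expect_lt(abs(ab - ba), 1e-9)
    raw <- sqrt(mean(rowSums((coords(s) - coords(pert))^2)))
    expect_lte(ab, raw + 1e-12)
  }
})

test_that("selection mismatches are reported with the missing atoms", {
  fx <- fix_coil7()
  s <- fx$structure
  s2 <- s
  s2$atoms <- s2$atoms[!(s2$atoms$resno == 3 & s2$atoms$name == "CA"), ]
  expect_error(superpose(s2, s, "ca"), "3 CA")
})

test_that("hydrogen stripping removes exactly the hydrogens", {
  spec <- peptide_spec("AAAAAAA")
  s <- build_peptide(spec, assign_restraints("CCCCCCC"))
  # alanine has 10 atoms incl. 5 H (backbone H, HA, 3x HB)
  sh <- strip_hydrogens(s)
  expect_equal(sum(sh$atoms$element == "H"), 0L)
  heavy <- s$atoms$name[s$atoms$element != "H"]
  expect_identical(sh$atoms$name, heavy)       # order preserved
  expect_identical(strip_hydrogens(sh), sh)    # idempotent
  # per-residue heavy counts: N, CA, C, O, CB (+OXT at the C-terminus)
  expect_equal(nrow(sh$atoms), 7 * 5 + 1)
})

test_that("reference-model selection honours the declaration", {
  fx <- fix_coil7()
  models <- lapply(1:5, function(i) {
    set_coords(fx$structure, coords(fx$structure) + i)
  })
  ens <- pep_ensemble(models, representative_model = 4L)
  expect_equal(select_reference(ens)$model_id, 4L)
  ens$representative_model <- NULL
  expect_equal(select_reference(ens)$model_id, 1L)
  one <- pep_ensemble(models[1])
  expect_equal(select_reference(one)$model_id, 1L)
  expect_error(select_reference(pep_ensemble(models, 9L)), "not present")
})

test_that("rigid core finds engineered flexibility", {
  cfg <- fixture_config(seed = 3, length = 15, noise_sd = 0.1,
                        n_models = 10, ss_pattern = "H",
                        sequence = strrep("A", 15))
  base <- make_ideal_peptide(cfg)
  # identical models: full core with zero RMSF
  ens0 <- pep_ensemble(lapply(1:4, function(i) base))
  rc0 <- rigid_core(ens0)
  expect_equal(rc0$residues, 1:15)
  expect_true(all(rc0$rmsf < 1e-12))
  # displaced residue excluded at the 1.5 A threshold
  ens <- make_noisy_ensemble(base, cfg, displace = list("8" = 3))
  rc <- rigid_core(ens)
  expect_false(8 %in% rc$residues)
  expect_true(all(setdiff(1:15, 8) %in% rc$residues))
  expect_gt(rc$rmsf[["8"]], 1.5)
  # threshold 0 empties the core of any noisy ensemble
  expect_length(rigid_core(ens, threshold = 0)$residues, 0L)
  # monotone in threshold
  cores <- lapply(c(0.2, 0.5, 1.5, 4), function(th) {
    rigid_core(ens, threshold = th)$residues
  })
  for (k in 2:4) expect_true(all(cores[[k - 1]] %in% cores[[k]]))
  expect_error(rigid_core(pep_ensemble(list(base))), "at least 2")
})

test_that("dataset filters drop lengths, duplicates and disulfides", {
  rec <- data.frame(
    id = paste0("p", 1:7),
    sequence = c("AAAAAA", "AAAAAAA", strrep("A", 25), strrep("A", 26),
                 "CKLSAQC", "AAAAAAA", "WKLSAQW"),
    length = c(6, 7, 25, 26, 7, 7, 7),
    has_disulfide = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filter_dataset(rec)
  # 6 and 26 fail the length gate, p5 carries a disulfide, p6 duplicates p2
  expect_setequal(out$id, c("p2", "p3", "p7"))
  # first occurrence of a duplicate survives
  expect_true("p2" %in% out$id && !"p6" %in% out$id)
})

test_that("evaluation reports all three metrics plus the core variants", {
  cfg <- fixture_config(seed = 6, length = 10, noise_sd = 0.15,
                        n_models = 8, ss_pattern = "H",
                        sequence = strrep("A", 10))
  base <- make_ideal_peptide(cfg)
  ens <- make_noisy_ensemble(base, cfg)
  rep <- evaluate_structures(base, ens)
  expect_true(all(c("rmsd", "ca_rmsd", "b_rmsd", "core_ca_rmsd") %in%
                  names(rep)))
  expect_true(all(rep[, c("rmsd", "ca_rmsd", "b_rmsd")] >= 0))
  # prediction vs itself: all metrics zero
  self <- evaluate_structures(base, pep_ensemble(list(base)))
  expect_lt(max(self$rmsd, self$ca_rmsd, self$b_rmsd), 1e-9)
})

test_that("superposition RMSD agrees with the bio3d reference", {
  requireNamespace("bio3d", quietly = TRUE)
  set.seed(47)
  fx <- fix_coil7()
  s <- fx$structure
  pert <- set_coords(s, coords(s) +
                     matrix(rnorm(3 * nrow(s$atoms), sd = 0.8), ncol = 3))
  ours <- superpose(pert, s, "all")$rmsd
  ref <- bio3d::rmsd(as.vector(t(coords(s))),
                     as.vector(t(coords(pert))), fit = TRUE)
  expect_lt(abs(ours - ref), 6e-4)   # bio3d reports 3 decimals
})
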