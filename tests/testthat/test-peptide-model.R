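# Peptide specification, residue templates and the masking rule.

test_that("bundled registry carries naturals, fixtures and caps", {
  reg <- fix_registry()
  cls <- vapply(reg$templates, function(t) t$class, "")
  expect_equal(sum(cls == "natural"), 20L)
  expect_true(all(c("ORN", "AIB", "SEP", "HYP", "ACE", "NH2", "NME") %in%
                  names(reg$templates)))
  # lookups are total over one-letter codes
  for (letter in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    expect_s3_class(lookup_template(reg, letter), "residue_template")
  }
  expect_error(lookup_template(reg, "ZZZ"), "unknown")
})

test_that("template registration round-trips and guards duplicates", {
  reg <- template_registry()
  orn <- read_template(system.file("extdata", "templates", "ORN.tpl",
                                   package = "pepbuildr"))
  reg <- register_template(reg, orn)
  expect_identical(lookup_template(reg, "ORN"), orn)
  expect_error(register_template(reg, orn), "already registered")
  expect_silent(reg <- register_template(reg, orn, override = TRUE))
  # a template with a missing internal-coordinate record fails validation
  broken <- orn
  broken$zmat <- broken$zmat[broken$zmat$atom != "CG", ]
  expect_error(register_template(reg, broken, override = TRUE),
               "internal-coordinate")
  # net charge must equal the declared formal charge
  off <- orn
  off$atoms$charge[1] <- off$atoms$charge[1] + 0.01
  expect_error(validate_template(off), "net charge")
})

test_that("every bundled template's charges sum to its formal charge", {
  for (tpl in fix_registry()$templates) {
    expect_lt(abs(sum(tpl$atoms$charge) - tpl$formal_charge), 1e-6)
  }
})

test_that("peptide specs validate lengths, codes, chirality and pairs", {
  # identity case: 7 natural residues, no modifications
  spec <- peptide_spec("ACDKLMN")
  expect_equal(nrow(spec$residues), 7L)
  expect_true(all(spec$residues$chirality == "L"))
  expect_equal(spec$n_cap, "none")
  # default service bounds 7..25
  expect_error(peptide_spec("ACDKLM"), "outside allowed bounds")
  expect_error(peptide_spec(strrep("A", 26)), "outside allowed bounds")
  # the bound is a policy: overridable
  expect_silent(peptide_spec("ACD", length_bounds = c(min = 2, max = 30)))
  # glycine cannot be D
  rg <- data.frame(position = 1:7, code = strsplit("AGAAAAA", "")[[1]],
                   chirality = c("L", "D", rep("L", 5)))
  expect_error(peptide_spec(rg), "achiral")
  # disulfides must hit thiol-bearing residues, no reuse
  expect_silent(peptide_spec("ACAAAAACA",
                             disulfide_pairs = list(c(2, 8))))
  expect_error(peptide_spec("ASAAAAACA",
                            disulfide_pairs = list(c(2, 8))),
               "no thiol")
  expect_error(peptide_spec("CCAAAAACC",
                            disulfide_pairs = list(c(1, 8), c(1, 9))),
               "two disulfide pairs")
  # caps and head-to-tail cyclization are exclusive
  expect_error(peptide_spec("ACDKLMN", n_cap = "acetyl", nc_cyclic = TRUE),
               "exclud")
})

test_that("config parsing applies directives and reports bad positions", {
  spec <- parse_peptide_spec("
sequence: ACDKGCKLA
disulfides: [[2, 6]]
residues:
  - {position: 4, code: ORN}
  - {position: 7, chirality: D}
")
  expect_equal(spec$residues$code[4], "ORN")
  expect_equal(spec$residues$chirality[7], "D")
  expect_equal(spec$disulfide_pairs, list(c(2L, 6L)))
  expect_error(parse_peptide_spec("
sequence: ACDKGCKLA
residues:
  - {position: 99, code: ORN}
"), "position 99")
  expect_error(parse_peptide_spec("
sequence: ACDKZCKLA
"), "unknown residue code")
})

test_that("spec serialization round-trips to an identical spec", {
  specs <- list(
    peptide_spec("ACDKGCKLA"),
    parse_peptide_spec("
sequence: CCAKGAKLC
n_cap: acetyl
c_cap: n_methylamide
disulfides: [[1, 9]]
residues:
  - {position: 4, code: SEP}
  - {position: 6, chirality: D}
"),
    peptide_spec("AKLAAKA", nc_cyclic = TRUE))
  for (spec in specs) {
    back <- parse_peptide_spec(write_peptide_spec(spec))
    expect_equal(back, spec)
  }
})

test_that("masking hides non-natural codes only", {
  reg <- fix_registry()
  mk <- function(codes, chir = rep("L", length(codes))) {
    structure(list(residues = data.frame(
      position = seq_along(codes), code = codes, chirality = chir)),
      class = "peptide_spec")
  }
  # non-natural residue -> X
  expect_equal(mask_nonnatural(mk(c("A", "ORN", "K"))), "AXK")
  expect_equal(mask_nonnatural(mk(c("A", "AIB", "K"))), "AXK")
  # all-natural sequence unchanged
  expect_equal(mask_nonnatural(peptide_spec("ACDKLMN")), "ACDKLMN")
  # D-residues keep the parent letter (not X)
  expect_equal(mask_nonnatural(mk(c("A", "A", "A"), c("L", "L", "D"))),
               "AAA")
  # PTM residues keep the parent letter
  expect_equal(mask_nonnatural(mk(c("A", "SEP", "K"))), "ASK")
  expect_equal(mask_nonnatural(mk(c("A", "HYP", "K"))), "APK")
  # idempotent and length-preserving
  spec <- mk(c("A", "ORN", "K", "SEP", "G", "X", "W"))
  m1 <- mask_nonnatural(spec)
  expect_equal(nchar(m1), 7L)
  spec2 <- mk(strsplit(m1, "")[[1]])
  expect_equal(mask_nonnatural(spec2), m1)
})

test_that("every bundled residue template builds to finite coordinates", {
  reg <- fix_registry()
  codes <- names(Filter(function(t) t$class != "cap", reg$templates))
  restr <- assign_restraints("CCCCCCC")
  for (code in codes) {
    r <- data.frame(position = 1:7,
                    code = c("A", "A", "A", code, "A", "A", "A"),
                    chirality = "L")
    spec <- peptide_spec(r)
    s <- build_peptide(spec, restr)
    expect_true(all(is.finite(coords(s))), label = code)
    # bonded atoms at sane separations
    topo <- build_topology(s, spec)
    xyz <- coords(s)
    d <- sqrt(rowSums((xyz[topo$bonds$i, , drop = FALSE] -
                       xyz[topo$bonds$j, , drop = FALSE])^2))
    expect_true(all(d > 0.7 & d < 2.5), label = code)
  }
})

test_that("FASTA sequences read back as plain strings", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">pep1", "ACDKLMNPQ"), f)
  expect_equal(read_fasta_sequence(f), "ACDKLMNPQ")
})
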