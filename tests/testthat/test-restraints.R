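# DSSP reduction, secondary-structure content and restraint assignment.

test_that("DSSP 8-state reduction follows the helix/strand/coil map", {
  expect_equal(reduce_dssp("GHIE-TSB"), "HHCECCCE")
  expect_equal(reduce_dssp(""), "")
  expect_equal(reduce_dssp("HHHH"), "HHHH")   # fixed point
  expect_error(reduce_dssp("GHZ"), "position 3")
})

test_that("reduction is total and surjective over the DSSP alphabet", {
  alphabet <- c("T", "S", "G", "H", "I", "B", "E", "-")
  images <- vapply(alphabet, reduce_dssp, "")
  expect_setequal(unique(images), c("H", "E", "C"))
  # random strings: length preserved, content monotone in {G,H,B,E} count
  set.seed(21)
  prev_content <- -1
  for (k in 0:8) {
    chars <- c(sample(c("T", "S", "I", "-"), 8 - k, replace = TRUE),
               sample(c("G", "H", "B", "E"), k, replace = TRUE))
    s8 <- paste(sample(chars), collapse = "")
    s3 <- reduce_dssp(s8)
    expect_equal(nchar(s3), 8L)
    content <- ss_content(s3)
    expect_gt(content, prev_content)
    prev_content <- content
  }
})

test_that("regular-structure content implements the 60% gate", {
  expect_equal(ss_content("HHHHECCCCC"), 0.5)
  expect_equal(ss_content("HHHHHHHHHH"), 1.0)
  expect_equal(ss_content("HHHHHHECCC"), 0.7)
  expect_true(ss_content("HHHHHHECCC") >= 0.60)
  expect_false(ss_content("HHHHECCCCC") >= 0.60)
  expect_error(ss_content(""), "empty")
  expect_error(ss_content("HXE"), "alphabet")
})

test_that("DSSP files and bare strings both yield state strings", {
  f <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >  S+", "    2    2 A C  G  3  S+",
    "    3    3 A D     X  -", "    4    4 A K  E  <  S-"), f)
  # column 17 carries the summary state; blank means '-'
  expect_equal(read_dssp_states(f), "HG-E")
  expect_equal(read_dssp_states("GHTSE"), "GHTSE")
  expect_equal(reduce_dssp(read_dssp_states(f)), "HHCE")
})

test_that("restraints encode the canonical state torsions", {
  n <- 8
  rh <- assign_restraints(strrep("H", n))
  expect_true(all(rh$phi[-1] == -60))
  expect_true(all(rh$psi[-n] == -40))
  re <- assign_restraints(strrep("E", n))
  expect_true(all(re$phi[-1] == -120))
  expect_true(all(re$psi[-n] == 120))
  rc <- assign_restraints(strrep("C", n))
  expect_true(all(rc$phi[-1] == 180))   # extended conformation
  expect_true(all(rc$psi[-n] == 180))
  # chain-end angles are undefined
  for (r in list(rh, re, rc)) {
    expect_true(is.na(r$phi[1]) && is.na(r$psi[n]))
    ok <- stats::na.omit(c(r$phi, r$psi))
    expect_true(all(ok > -180 & ok <= 180))
    expect_equal(nrow(r), n)
  }
})

test_that("turn annotations override positions i+1 and i+2 only", {
  tab <- turn_type_table()
  expect_setequal(tab$type, c("I", "Ip", "II", "IIp", "IV", "VIII"))
  base <- assign_restraints("CCCCCCCC")
  turned <- assign_restraints("CCCCCCCC",
                              turns = data.frame(start = 3, type = "II"))
  row <- tab[tab$type == "II", ]
  expect_equal(turned$phi[4], row$phi1)
  expect_equal(turned$psi[4], row$psi1)
  expect_equal(turned$phi[5], row$phi2)
  expect_equal(turned$psi[5], row$psi2)
  untouched <- setdiff(seq_len(8), c(4, 5))
  expect_equal(turned$phi[untouched], base$phi[untouched])
  expect_equal(turned$psi[untouched], base$psi[untouched])
  # primed type spelling accepted
  t2 <- assign_restraints("CCCCCCCC",
                          turns = data.frame(start = 3, type = "I'"))
  expect_equal(t2$phi[4], tab[tab$type == "Ip", "phi1"])
  # overlapping turns: last annotation wins
  t3 <- assign_restraints("CCCCCCCC",
                          turns = data.frame(start = c(2, 3),
                                             type = c("I", "II")))
  expect_equal(t3$phi[4], tab[tab$type == "II", "phi1"])
  expect_equal(t3$phi[3], tab[tab$type == "I", "phi1"])
  expect_error(assign_restraints("CCCC",
                                 turns = data.frame(start = 2, type = "I")),
               "beyond")
  expect_error(assign_restraints("CCCCCCCC",
                                 turns = data.frame(start = 2,
                                                    type = "XIV")),
               "unknown turn type")
})

test_that("turn overrides are local for random annotations", {
  set.seed(33)
  tab <- turn_type_table()
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    ss <- paste(sample(c("H", "E", "C"), n, replace = TRUE),
                collapse = "")
    i <- sample(seq_len(n - 3), 1)
    type <- sample(tab$type, 1)
    base <- assign_restraints(ss)
    turned <- assign_restraints(ss, turns = data.frame(start = i,
                                                       type = type))
    changed <- which(!(turned$phi == base$phi |
                       (is.na(turned$phi) & is.na(base$phi))) |
                     !(turned$psi == base$psi |
                       (is.na(turned$psi) & is.na(base$psi))))
    expect_true(all(changed %in% c(i + 1, i + 2)))
    ok <- stats::na.omit(c(turned$phi, turned$psi))
    expect_true(all(ok > -180 & ok <= 180))
  }
})
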