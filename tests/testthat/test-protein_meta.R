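test_that("molar mass is the sum of residue masses plus one water", {
  expect_equal(protein_info("GG")$M_r, 2 * 57.0519 + 18.0153,
               tolerance = 1e-10)
  expect_equal(protein_info("GG")$M_r, 132.12, tolerance = 1e-2)
  p <- protein_info("gagv", name = "lower")
  expect_equal(p$sequence, "GAGV")  # uppercased
  expect_equal(p$a, 4L)
  m <- residue_masses()
  expect_equal(p$M_r, sum(m[c("G", "A", "G", "V")]) + 18.0153)
})

test_that("degenerate and malformed sequences are rejected with position", {
  expect_error(protein_info(""), "empty")
  expect_error(protein_info("GAXG"), "position 3")
  expect_error(protein_info("GAZG"), "'Z'")
})

test_that("the bundled alpha-synuclein fixture has 140 residues and the
           expected molar mass", {
  p <- asyn_wt()
  expect_equal(p$a, 140L)
  expect_equal(p$M_r, 14460.16, tolerance = 1e-5)
  # independent oracle: per-character sum over the raw fixture file
  lines <- readLines(system.file("extdata", "alpha_synuclein_wt.fasta",
                                 package = "hydromelt"))
  seq <- paste(lines[-1], collapse = "")
  chars <- strsplit(seq, "")[[1]]
  expect_equal(p$M_r, sum(residue_masses()[chars]) + 18.0153)
})

test_that("point mutations shift the mass by exactly the residue difference", {
  wt <- asyn_wt()
  m <- residue_masses()
  a30p <- apply_mutation(wt, "A30P")
  expect_equal(a30p$a, 140L)
  expect_equal(a30p$M_r - wt$M_r, m[["P"]] - m[["A"]])
  expect_equal(a30p$M_r - wt$M_r, 26.04, tolerance = 1e-2)
  expect_equal(substr(a30p$sequence, 30, 30), "P")
  e46k <- apply_mutation(wt, "E46K")
  expect_equal(e46k$M_r - wt$M_r, m[["K"]] - m[["E"]])
  expect_equal(e46k$M_r - wt$M_r, -0.94, tolerance = 1e-2)
  # mass consistency over arbitrary codes
  for (code in c("M1W", "K6R", "A140G")) {
    mut <- apply_mutation(wt, code)
    ref <- substr(code, 1, 1)
    new <- substr(code, nchar(code), nchar(code))
    expect_equal(mut$M_r - wt$M_r, m[[new]] - m[[ref]])
  }
})

test_that("mutation codes are validated against the sequence", {
  wt <- asyn_wt()
  expect_error(apply_mutation(wt, "A46K"), "code says A, sequence has E")
  expect_error(apply_mutation(wt, "A999P"), "out of range")
  expect_error(apply_mutation(wt, "30P"), "look like")
  expect_error(apply_mutation(wt, "A30X"), "not a canonical")
})

test_that("FASTA write/read round-trips the sequence byte-for-byte", {
  p <- protein_info("MDVFMKGLSKAKEGVVAAAEKTKQGVAEAA", name = "toy fragment")
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p, tmp)
  q <- read_fasta(tmp)
  expect_identical(q$sequence, p$sequence)
  expect_equal(q$M_r, p$M_r)
  # record selection by id in a multi-record file
  writeLines(c(">first", "GG", ">second protein", "GAG"), tmp)
  expect_equal(read_fasta(tmp)$a, 2L)
  expect_equal(read_fasta(tmp, id = "second")$a, 3L)
})
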