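test_that("model designation labels parse and round-trip", {
  d <- parse_model_designation("AF-1")
  expect_equal(d$source, "alphafold")
  expect_equal(d$mode, "none")
  expect_equal(d$number, 1L)

  d <- parse_model_designation("CP-H18")
  expect_equal(d$source, "cluspro")
  expect_equal(d$mode, "hydrophobic")
  expect_equal(d$number, 18L)

  d <- parse_model_designation("CP-12")
  expect_equal(d$mode, "balanced")

  labels <- c(paste0("AF-", 1:5), paste0("CP-", c(1, 12, 30)),
              paste0("CP-H", c(1, 14, 18, 30)))
  for (lab in labels) {
    expect_identical(format_model_designation(parse_model_designation(lab)),
                     lab)
  }
  expect_error(parse_model_designation("XQ-3"), "unknown")
  expect_error(parse_model_designation("AF-0"))
})

test_that("protomer construction enforces its invariants", {
  expect_error(new_protomer("A", fx_rec$atoms[0, ], fx_rec$tm), "no atoms")
  bad_tm <- data.frame(index = 1, start = 900, end = 920)
  expect_error(new_protomer("A", fx_rec$atoms, bad_tm),
               "outside the residue numbering")
  rev_tm <- data.frame(index = 1, start = 20, end = 10)
  expect_error(new_protomer("A", fx_rec$atoms, rev_tm), "start > end")
  expect_equal(n_tm(fx_rec), 7L)
  expect_equal(n_tm(fx_iso2), 2L)
  # sequence uses helix marker residues, one letter per residue
  expect_equal(nchar(fx_rec$sequence), length(unique(fx_rec$atoms$resseq)))
})

protomer_xyz_test <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])

test_that("complex PDB I/O round-trips coordinates and annotations", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(fx_dimer45, path)
  back <- read_complex_pdb(path)

  expect_equal(back$subject$chain_id, fx_dimer45$subject$chain_id)
  expect_equal(back$partner$chain_id, fx_dimer45$partner$chain_id)
  # coordinates at PDB field precision
  expect_lt(max(abs(protomer_xyz_test(back$subject) -
                    protomer_xyz_test(fx_dimer45$subject))), 1e-3)
  expect_lt(max(abs(protomer_xyz_test(back$partner) -
                    protomer_xyz_test(fx_dimer45$partner))), 1e-3)
  # sidecar metadata survives
  expect_equal(back$subject$tm, fx_dimer45$subject$tm)
  expect_equal(back$designation$label, "AF-3")
  expect_equal(back$complex_name, "REC-REC")
})

test_that("reading reports missing chains and bad TM ranges", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(fx_dimer45, path)
  expect_error(
    read_complex_pdb(path,
                     chain_roles = c(A = "subject", Z = "partner"),
                     tm_annotations = list(A = fx_rec$tm, Z = fx_rec$tm)),
    "chain Z absent")
  bad <- list(A = data.frame(index = 1, start = 900, end = 920),
              B = fx_rec$tm)
  expect_error(
    read_complex_pdb(path, chain_roles = c(A = "subject", B = "partner"),
                     tm_annotations = bad),
    "outside the residue numbering")
})

test_that("pairwise identity follows the global-alignment definition", {
  s <- "MDYQVSSPIYDINYYTSEPC"
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  # symmetric and case-invariant
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYIAKQRNISFVKSHFSRQLEERLGLIEVA"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_equal(pairwise_identity(tolower(a), b), pairwise_identity(a, b))
  expect_error(pairwise_identity("AC*G", "ACDG"), "non-amino-acid")
  expect_error(pairwise_identity("", "ACDG"))
})
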