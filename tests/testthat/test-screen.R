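test_that("most-stable selection keeps comparly stable distinct interfaces", {
  # two close models with distinct helix sets are both kept
  df <- data.frame(bfe_mean = c(-70.52, -69.82),
                   interface = c("TM4, TM5", "TM1, TM2, TM3 (E)"))
  expect_equal(select_most_stable(df), c(1L, 2L))

  # a dominant best model retires the rest
  df <- data.frame(bfe_mean = c(-160, -80, -75),
                   interface = c("TM6, TM7", "TM1, TM2", "TM4, TM5"))
  expect_equal(select_most_stable(df), 1L)

  # same helix set within the window: only the lower kept
  df <- data.frame(bfe_mean = c(-100, -99.5),
                   interface = c("TM4, TM5", "TM5, TM4"))
  expect_equal(select_most_stable(df), 1L)

  # never more than three
  df <- data.frame(bfe_mean = c(-100, -99, -98, -97),
                   interface = c("TM1", "TM2", "TM3", "TM4"))
  expect_length(select_most_stable(df), 3)

  # invariant to input order
  df <- data.frame(bfe_mean = c(-69.82, -70.52),
                   interface = c("TM1, TM2, TM3 (E)", "TM4, TM5"))
  expect_equal(select_most_stable(df), c(1L, 2L))
  expect_error(select_most_stable(df[0, ]), "no models")
})

test_that("selection also works from structures with binding energies", {
  m1 <- fx_dimer45; m1$bfe <- new_binding_energy(-80, 0.2)
  m2 <- fx_dimer12; m2$bfe <- new_binding_energy(-78, 0.3)
  m3 <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5),
                    axis_separation = 10.8, partner_twist_deg = 5), "CP-3")
  m3$bfe <- new_binding_energy(-79, 0.2)  # same face as m1: dropped
  expect_equal(select_most_stable(list(m1, m3, m2)), c(1L, 3L))
})

test_that("the end-to-end screen triages fixtures deterministically", {
  dir <- withr::local_tempdir()
  cfg <- generate_fixtures(dir, seed = 7)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  rep1 <- run_screen(cfg, out_dir = out1)

  expect_equal(nrow(rep1$report), 7)       # one row per input model
  expect_length(rep1$errors, 0)
  # decoys are non-compliant and never selected
  expect_false(any(rep1$report$selected[!rep1$report$compliant]))
  expect_false(rep1$report$compliant[rep1$report$group == "REC1-REC1" &
                                     rep1$report$label == "CP-4"])
  # at least one selected model per group with a compliant model
  for (g in unique(rep1$report$group)) {
    rows <- rep1$report[rep1$report$group == g, ]
    if (any(rows$compliant)) expect_true(any(rows$selected))
  }
  expect_true(all(rep1$verdicts$blocks))

  # rerun: byte-identical reports
  run_screen(cfg, out_dir = out2)
  expect_identical(readLines(file.path(out1, "screen_report.tsv")),
                   readLines(file.path(out2, "screen_report.tsv")))
  expect_identical(readLines(file.path(out1, "screen_report.json")),
                   readLines(file.path(out2, "screen_report.json")))

  # config file round-trip drives the same screen
  cfg2 <- read_screen_config(file.path(dir, "screen_config.json"))
  rep3 <- run_screen(cfg2)
  expect_equal(rep1$report, rep3$report, tolerance = 1e-12)
})

test_that("a broken group is reported and the others continue", {
  dir <- withr::local_tempdir()
  cfg <- generate_fixtures(dir, seed = 3)
  cfg$groups[[1]]$models$path[2] <- file.path(dir, "missing.pdb")
  rep <- run_screen(cfg)
  expect_named(rep$errors, "REC1-REC1")
  expect_true(all(rep$report$group == "REC1-Iso_2TM"))
})
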