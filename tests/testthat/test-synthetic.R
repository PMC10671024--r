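test_that("ideal bundles have the specified architecture", {
  expect_equal(nrow(fx_rec$tm), 7)
  expect_equal(n_tm(fx_iso2), 2)
  # consecutive C-alpha rise along the helix axis
  tm1 <- fx_rec$tm[1, ]
  ca <- gpcrdimer:::protomer_ca(fx_rec, tm1$start:tm1$end)
  expect_equal(unname(abs(diff(ca$xyz[, 3]))),
               rep(1.5, nrow(ca$xyz) - 1), tolerance = 1e-9)
  # determinism: same spec, same seed -> bit-identical structures
  b1 <- build_ideal_bundle(bundle_spec(5, jitter_sd = 0.2, seed = 9))
  b2 <- build_ideal_bundle(bundle_spec(5, jitter_sd = 0.2, seed = 9))
  expect_identical(b1, b2)
  b3 <- build_ideal_bundle(bundle_spec(5, jitter_sd = 0.2, seed = 10))
  expect_false(identical(b1, b3))
  expect_error(bundle_spec(8), "n_tm")
  expect_error(bundle_spec(1), "n_tm")
})

test_that("generated bundles round-trip through PDB I/O", {
  cm <- place_dimer(fx_rec, fx_iso2, dimer_pose_spec(c(6, 7), c(1, 2)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(cm, path)
  back <- read_complex_pdb(path)
  expect_lt(max(abs(gpcrdimer:::protomer_xyz(back$partner) -
                    gpcrdimer:::protomer_xyz(cm$partner))), 1e-3)
  expect_equal(n_tm(back$partner), 2)
})

test_that("designed poses carry their interface; separations behave", {
  ifc <- interface_residues(fx_dimer45)
  expect_gt(length(ifc$subject), 0)
  far <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5),
                                                     axis_separation = 40))
  expect_length(interface_residues(far)$subject, 0)
  expect_error(place_dimer(fx_rec, fx_rec,
                           dimer_pose_spec(c(4, 5), axis_separation = 2)),
               "interpenetrate")
  expect_error(place_dimer(fx_rec, fx_iso2,
                           dimer_pose_spec(c(4, 5), c(6, 7))),
               "not present")
})

test_that("each decoy mode violates exactly its targeted rule", {
  modes <- c(flip = "rule_orientation", offset = "rule_layers",
             asymmetric = "rule_symmetry")
  for (m in names(modes)) {
    rep <- topology_filter(make_decoy(fx_dimer45, m))
    expect_false(rep$compliant, info = m)
    for (rule in c("rule_orientation", "rule_layers", "rule_symmetry")) {
      if (rule == modes[[m]]) expect_false(rep[[rule]]$pass, info = m)
      else expect_true(rep[[rule]]$pass, info = paste(m, rule))
    }
  }
  # a 10 degree tilt is within the 30 degree orientation tolerance
  expect_true(topology_filter(make_decoy(fx_dimer45, "tilt", 10))$compliant)
  expect_false(topology_filter(make_decoy(fx_dimer45, "tilt", 40))$compliant)
  expect_error(make_decoy(fx_dimer45, "melt"))
})

test_that("synthetic energy tables are seeded and mass-conserving", {
  et1 <- synth_energy_table(fx_dimer45, -100, seed = 7)
  et2 <- synth_energy_table(fx_dimer45, -100, seed = 7)
  expect_identical(et1, et2)
  et3 <- synth_energy_table(fx_dimer45, -100, seed = 8)
  expect_false(identical(et1, et3))

  noise_sd <- 0.1
  expect_lt(abs(sum(et1$contribution) - (-100)),
            3 * noise_sd * sqrt(nrow(et1)))

  # significant residues recover the designed interface
  ifc <- interface_residues(fx_dimer45)
  et <- synth_energy_table(fx_dimer45, -100, noise_sd = 0.05, seed = 7)
  sig <- significant_residues(et, -1)
  hit_s <- intersect(sig$resseq[sig$chain == "A"], ifc$subject)
  hit_p <- intersect(sig$resseq[sig$chain == "B"], ifc$partner)
  recovery <- (length(hit_s) + length(hit_p)) /
    (length(ifc$subject) + length(ifc$partner))
  expect_gte(recovery, 0.9)

  far <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5),
                                                     axis_separation = 40))
  expect_error(synth_energy_table(far, -100), "empty interface")
  expect_error(synth_energy_table(fx_dimer45, 50), "negative")
})
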