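test_that("membrane frame of an ideal upright bundle is the z axis", {
  f <- fit_membrane_frame(fx_rec)
  expect_lt(acos(min(1, abs(f$normal[3]))), 1e-6)  # angular deviation
  expect_gt(f$normal[3], 0)                        # extracellular = +z
  expect_lt(abs(f$midplane_point[3]), 1e-6)
  expect_lt(f$fit_residual, 1e-6)
  single <- fx_iso2
  single$tm <- single$tm[1, , drop = FALSE]
  expect_error(fit_membrane_frame(single), "cannot infer membrane")
})

vnorm_test <- function(v) sqrt(sum(v^2))

test_that("frame fitting is equivariant under rigid transforms", {
  set.seed(11)
  f0 <- fit_membrane_frame(fx_rec)
  for (i in 1:5) {
    rot <- random_rotation()
    tr <- stats::rnorm(3, sd = 20)
    f1 <- fit_membrane_frame(apply_transform(fx_rec, rot, tr))
    expect_lt(vnorm_test(f1$normal - as.numeric(rot %*% f0$normal)), 1e-6)
    expect_lt(vnorm_test(f1$midplane_point -
                         (as.numeric(rot %*% f0$midplane_point) + tr)), 1e-6)
  }
})

test_that("frame normal agrees with an SVD plane fit on jittered bundles", {
  # jittered bundle with helices no longer perfectly parallel; the
  # membrane plane oracle is a total-least-squares fit through the
  # per-helix C-alpha midpoints
  b <- build_ideal_bundle(bundle_spec(7, jitter_sd = 0.3, seed = 5))
  f <- fit_membrane_frame(b)
  mids <- t(vapply(seq_len(nrow(b$tm)), function(i) {
    ca <- gpcrdimer:::protomer_ca(b, b$tm$start[i]:b$tm$end[i])
    colMeans(ca$xyz)
  }, numeric(3)))
  n_svd <- svd_plane_normal(mids)
  ang <- acos(min(1, abs(sum(f$normal * n_svd))))
  expect_lt(ang * 180 / pi, 2)
})

test_that("orientation and layer checks behave as specified", {
  f <- fit_membrane_frame(fx_rec)
  r <- orientation_consistent(f, f)
  expect_true(r$pass); expect_equal(r$angle, 0)

  fdown <- f; fdown$normal <- -f$normal
  r <- orientation_consistent(f, fdown)
  expect_false(r$pass); expect_equal(r$angle, 180)

  # constructed 20 degree tilt passes a 30 degree tolerance
  f20 <- fit_membrane_frame(apply_transform(fx_rec,
           gpcrdimer:::rotation_about(c(1, 0, 0), 20), c(0, 0, 0)))
  r <- orientation_consistent(f, f20, 30)
  expect_true(r$pass)
  expect_equal(r$angle, 20, tolerance = 1e-4)

  expect_true(layers_consistent(f, f)$pass)
  f15 <- fit_membrane_frame(apply_transform(fx_rec, diag(3), c(0, 0, 15)))
  r <- layers_consistent(f, f15, 8)
  expect_false(r$pass); expect_equal(r$offset, 15, tolerance = 1e-6)
  f5 <- fit_membrane_frame(apply_transform(fx_rec, diag(3), c(0, 0, 5)))
  expect_true(layers_consistent(f, f5, 8)$pass)
})

test_that("topology filter passes designed poses and flags decoys by rule", {
  rep0 <- topology_filter(fx_dimer45)
  expect_true(rep0$compliant)
  expect_true(rep0$rule_orientation$pass)
  expect_true(rep0$rule_layers$pass)
  expect_true(rep0$rule_symmetry$pass)
  expect_equal(rep0$rule_symmetry$subject_helices, c(4, 5))

  flip <- topology_filter(make_decoy(fx_dimer45, "flip"))
  expect_false(flip$compliant)
  expect_false(flip$rule_orientation$pass)
  expect_true(flip$rule_layers$pass)

  off <- topology_filter(make_decoy(fx_dimer45, "offset"))
  expect_false(off$compliant)
  expect_true(off$rule_orientation$pass)
  expect_false(off$rule_layers$pass)

  asym <- topology_filter(make_decoy(fx_dimer45, "asymmetric"))
  expect_false(asym$compliant)
  expect_true(asym$rule_orientation$pass)
  expect_true(asym$rule_layers$pass)
  expect_false(asym$rule_symmetry$pass)

  tilt <- topology_filter(make_decoy(fx_dimer45, "tilt", magnitude = 10))
  expect_true(tilt$compliant)

  # heterodimer: symmetry rule not applicable
  het <- place_dimer(fx_rec, fx_iso2, dimer_pose_spec(c(4, 5), c(1, 2)))
  rep_het <- topology_filter(het)
  expect_true(is.na(rep_het$rule_symmetry$pass))
  expect_true(rep_het$compliant)
})

test_that("in-plane rotation plus translation keeps poses compliant", {
  set.seed(21)
  for (pair in fx_adjacent_pairs[c(1, 3, 5)]) {
    cm <- place_dimer(fx_rec, fx_rec,
                      dimer_pose_spec(pair, pair,
                                      axis_separation = runif(1, 10, 12)))
    moved <- apply_transform(cm,
      gpcrdimer:::rotation_about(c(0, 0, 1), runif(1, 0, 360)),
      c(runif(2, -30, 30), 0))
    expect_true(topology_filter(moved)$compliant)
  }
})
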