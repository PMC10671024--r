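test_that("interface residues follow the heavy-atom cutoff definition", {
  far <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5),
                                                     axis_separation = 40))
  ifc <- interface_residues(far)
  expect_length(ifc$subject, 0)
  expect_length(ifc$partner, 0)

  ifc5 <- interface_residues(fx_dimer45, 5)
  expect_gt(length(ifc5$subject), 0)
  # designed facing helices: residues confined to TM4/TM5 (loops carry
  # no atoms in the generator), verified by brute-force scan
  hx <- gpcrdimer:::tm_index_of(fx_dimer45$subject, ifc5$subject)
  expect_true(all(hx %in% c(4, 5)))
  oracle <- brute_force_interface(fx_dimer45, 5)
  expect_identical(ifc5$subject, oracle$subject)
  expect_identical(ifc5$partner, oracle$partner)

  # monotone in the cutoff
  ifc6 <- interface_residues(fx_dimer45, 6)
  expect_true(all(ifc5$subject %in% ifc6$subject))
  expect_true(all(ifc5$partner %in% ifc6$partner))
  expect_error(interface_residues(fx_dimer45, 0), "cutoff")
})

test_that("interface detection is symmetric under role swap", {
  swapped <- new_complex_model(fx_dimer45$partner, fx_dimer45$subject)
  a <- interface_residues(fx_dimer45)
  b <- interface_residues(swapped)
  expect_identical(a$subject, b$partner)
  expect_identical(a$partner, b$subject)
})

test_that("significant residues use a strict threshold", {
  et <- data.frame(chain = "A", resseq = 1:4,
                   contribution = c(-1.5, -0.5, -1.0, -1.0000001))
  sig <- significant_residues(et, -1)
  expect_setequal(sig$resseq, c(1L, 4L))
  # nested for decreasing thresholds
  s_lo <- significant_residues(et, -1.2)$resseq
  s_hi <- significant_residues(et, -0.4)$resseq
  expect_true(all(s_lo %in% s_hi))
})

far_empty <- function() {
  place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5), axis_separation = 40))
}

test_that("helix ranking orders by contribution with index tie-break", {
  # energy-weighted ranking: TM7 sum -30 > TM6 sum -5
  cm <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(6, 7)))
  ifc <- interface_residues(cm)
  tm <- fx_rec$tm
  pick <- function(h) {
    r <- intersect(tm$start[tm$index == h]:tm$end[tm$index == h],
                   ifc$subject)
    r[1]
  }
  et <- data.frame(chain = "A",
                   resseq = c(pick(6), pick(7)),
                   contribution = c(-5, -30))
  rk <- helix_contributions(cm, ifc, et)
  expect_equal(rk$helix[1], 7)
  expect_equal(rk$helix[2], 6)

  # equal scores fall back to ascending helix index
  et_tie <- data.frame(chain = "A",
                       resseq = c(pick(6), pick(7)),
                       contribution = c(-10, -10))
  # zero out all other interface residues' implicit contributions by
  # restricting the interface to the two scored residues
  rk_tie <- helix_contributions(cm, list(subject = c(pick(6), pick(7)),
                                         partner = integer()), et_tie)
  expect_equal(rk_tie$helix, c(6, 7))

  # ranking is invariant under uniform scaling of the energies
  et2 <- et; et2$contribution <- et2$contribution * 7.3
  expect_equal(helix_contributions(cm, ifc, et2)$helix,
               helix_contributions(cm, ifc, et)$helix)

  # contact-count fallback puts the designed facing helices on top
  rk_cnt <- helix_contributions(fx_dimer45)
  expect_setequal(rk_cnt$helix[1:2], c(4, 5))
  expect_equal(nrow(helix_contributions(far_empty())), 0)
})

test_that("E/M/I qualifiers follow the helix-thirds rule", {
  frame <- fit_membrane_frame(fx_rec)
  tm1 <- fx_rec$tm[fx_rec$tm$index == 1, ]
  res <- tm1$start:tm1$end           # helix 1 runs top (EC) to bottom
  # all interface residues in the extracellular third
  expect_equal(segment_qualifier(fx_rec, 1, res[1:5], frame), "E")
  # all in the intracellular third
  expect_equal(segment_qualifier(fx_rec, 1, res[22:26], frame), "I")
  # 2 of 3 in the intracellular third passes the 0.6 default
  expect_equal(segment_qualifier(fx_rec, 1, c(res[2], res[25], res[26]),
                                 frame), "I")
  # spread evenly: no third dominates
  expect_equal(segment_qualifier(fx_rec, 1, res[c(2, 13, 25)], frame),
               "none")
})

test_that("interface strings format and parse in the table dialect", {
  rk <- data.frame(helix = c(2, 1, 3, 4),
                   qualifier = c("none", "none", "E", "I"))
  expect_equal(format_interface_string(rk), "TM2, TM1, TM3 (E), TM4 (I)")
  expect_equal(format_interface_string(data.frame(helix = c(4, 5),
                                                  qualifier = "none")),
               "TM4, TM5")
  expect_equal(format_interface_string(data.frame(helix = integer(),
                                                  qualifier = character())),
               "")
  p <- parse_interface_string("TM2, TM1, TM3 (E), TM4(I)")  # tight spacing
  expect_equal(p$helix, c(2, 1, 3, 4))
  expect_equal(p$qualifier, c("none", "none", "E", "I"))
  expect_error(parse_interface_string("TM2, helixX"), "cannot parse")
})

test_that("interface profile combines ranking, qualifiers and string", {
  prof <- interface_profile(fx_dimer45)
  expect_s3_class(prof, "interface_profile")
  expect_setequal(prof$ranking$helix[1:2], c(4, 5))
  expect_match(prof$interface_string, "^TM[45], TM[45]$")
  roundtrip <- parse_interface_string(prof$interface_string)
  expect_equal(roundtrip$helix, prof$ranking$helix)
})
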