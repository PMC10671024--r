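# Shared synthetic fixtures (built once per test run).

fx_rec <- build_ideal_bundle(bundle_spec(7), "A", "subject")
fx_rec2 <- build_ideal_bundle(bundle_spec(7, markers = c("ASP", "GLU",
  "LYS", "ARG", "HIS", "SER", "THR")), "B", "partner")
fx_iso2 <- build_ideal_bundle(bundle_spec(2, markers = c("ALA", "GLY")),
                              "B", "isoform")

fx_dimer45 <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(4, 5)),
                          "AF-3", "REC-REC")
fx_dimer12 <- place_dimer(fx_rec, fx_rec, dimer_pose_spec(c(1, 2)),
                          "CP-12", "REC-REC")

## adjacent facing-helix pairs available on a 7-helix circle
fx_adjacent_pairs <- lapply(1:6, function(k) c(k, k + 1L))
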