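test_that("hydropathy profile matches direct arithmetic", {
  expect_equal(unique(hydropathy_profile(strrep("I", 25), 19)$hydropathy), 4.5)
  expect_equal(unique(hydropathy_profile(strrep("R", 25), 19)$hydropathy), -4.5)
  # alternating I/R, window 3: interior mean of (4.5, -4.5, 4.5) = 1.5
  alt <- paste(rep(c("I", "R"), 10), collapse = "")
  prof <- hydropathy_profile(alt, 3)
  # window centred on an R flanked by two I: mean(4.5, -4.5, 4.5) = 1.5
  expect_equal(prof$hydropathy[2], 1.5)
  expect_equal(prof$hydropathy[3], -1.5)
  expect_error(hydropathy_profile("MKVLH", 4), "odd")
  expect_error(hydropathy_profile("MKV", 19), "window exceeds")
})

test_that("TM segment prediction finds planted hydrophobic stretches", {
  # six planted 21-residue poly-LIV stretches separated by charged loops
  tm <- function() paste(withr::with_seed(1, sample(c("L", "I", "V"), 21,
                                                    TRUE)), collapse = "")
  loop <- strrep("DKER", 3)
  seq <- paste0(loop, paste(rep(c(tm(), loop), 6), collapse = ""))
  starts_truth <- nchar(loop) + (0:5) * (21 + nchar(loop)) + 1
  prof <- hydropathy_profile(seq, 11)
  seg <- predict_tm_segments(prof, threshold = 1.6, min_len = 9)
  expect_equal(nrow(seg), 6)
  for (k in 1:6) {
    expect_gte(seg$start[k], starts_truth[k] - 3)
    expect_lte(seg$end[k], starts_truth[k] + 20 + 3)
  }

  none <- predict_tm_segments(hydropathy_profile(strrep("R", 60), 11))
  expect_equal(nrow(none), 0)

  short <- paste0(strrep("R", 30), strrep("I", 10), strrep("R", 30))
  seg2 <- predict_tm_segments(hydropathy_profile(short, 5), min_len = 15)
  expect_equal(nrow(seg2), 0)
})

test_that("template self-mapping is exact for every subfamily", {
  t <- aqp_templates()
  self <- tibble::tibble(id = t$subfamily, sequence = t$sequence,
                         subfamily = t$subfamily)
  prof <- profile_motifs(self)
  expect_equal(prof$npa1, rep("NPA", 5))
  expect_equal(prof$npa2, rep("NPA", 5))
  expect_true(all(prof$npa1_canonical & prof$npa2_canonical))
  for (i in seq_len(nrow(t))) {
    res <- t$sites[[i]]
    s <- t$sequence[i]
    expect_equal(prof$H2[i], substr(s, res[["H2"]], res[["H2"]]))
    expect_equal(prof$LE2[i], substr(s, res[["LE2"]], res[["LE2"]]))
  }
  # canonical PIP ar/R tetrad
  pip <- prof[prof$query_id == "PIP", ]
  expect_equal(unname(unlist(pip[, c("H2", "H5", "LE1", "LE2")])),
               c("F", "H", "T", "R"))
})

test_that("a proline-to-leucine NPA2 mutant is reported non-canonical", {
  sp <- sim_proteins(c(PIP = 3), divergence_pct = 10, seed = 7,
                     perturb_npa2 = c(PIP = "NLA"))
  prof <- profile_motifs(sp$proteins)
  expect_equal(prof$npa2, rep("NLA", 3))
  expect_false(any(prof$npa2_canonical))
  expect_true(all(prof$npa1_canonical))
})

test_that("planted ar/R tetrads and NPA boxes survive 20% background divergence", {
  sp <- sim_proteins(c(PIP = 10, TIP = 10, NIP = 10, SIP = 10, XIP = 10),
                     divergence_pct = 20, seed = 13)
  prof <- profile_motifs(sp$proteins)
  truth <- sp$truth
  expect_equal(prof$npa1, truth$npa1)
  expect_equal(prof$npa2, truth$npa2)
  expect_equal(prof$H2, truth$H2)
  expect_equal(prof$H5, truth$H5)
  expect_equal(prof$LE1, truth$LE1)
  expect_equal(prof$LE2, truth$LE2)
})

test_that("template selection by best score works without a subfamily hint", {
  sp <- sim_proteins(c(NIP = 4), divergence_pct = 15, seed = 3)
  prof <- map_positions(dplyr::select(sp$proteins, -subfamily))
  expect_equal(prof$subfamily, rep("NIP", 4))
})

test_that("ar/R group rules reproduce the nine-group table", {
  expect_equal(assign_arR_group("F", "H", "T", "R"), "PIP")
  expect_equal(assign_arR_group("V", "H", "T", "R"), "PIP")
  expect_equal(assign_arR_group("H", "I", "A", "V"), "TIP-I")
  expect_equal(assign_arR_group("H", "I", "G", "R"), "TIP-IIa")
  expect_equal(assign_arR_group("H", "I", "A", "R"), "TIP-IIb")
  expect_equal(assign_arR_group("N", "V", "A", "V", "TIP"), "TIP-III")
  expect_equal(assign_arR_group("W", "V", "A", "R"), "NIP-I")
  expect_equal(assign_arR_group("G", "S", "G", "R", "NIP"), "NIP-I")
  expect_equal(assign_arR_group("A", "I", "G", "R", "NIP"), "NIP-II")
  expect_equal(assign_arR_group("T", "I", "A", "R"), "NIP-II")
  expect_equal(assign_arR_group("A", "N", "V", "H"), "SIP-I")
  expect_equal(assign_arR_group("S", "H", "G", "A"), "SIP-II")
  expect_equal(assign_arR_group("I", "T", "V", "R"), "XIP")
})

test_that("group assignment is total and degrades gracefully", {
  # any random tetrad yields exactly one label
  tets <- withr::with_seed(5, replicate(50, sample(LETTERS[1:20], 4), simplify = FALSE))
  for (tt in tets) {
    g <- assign_arR_group(tt[1], tt[2], tt[3], tt[4])
    expect_length(g, 1)
    expect_type(g, "character")
  }
  # fewer than three resolved positions -> unclassified
  expect_equal(assign_arR_group("F", "-", "-", "-"), "unclassified")
  expect_equal(assign_arR_group("-", "-", "T", "R"), "unclassified")
  # three resolved positions still classify (wildcard on the missing one)
  expect_equal(assign_arR_group("F", "H", "-", "R"), "PIP")
})

test_that("NPA regex fallback finds boxes without a template", {
  hits <- scan_npa("AAANPAKKKNPVGGG")
  expect_equal(hits$position, c(4, 10))
  expect_equal(hits$canonical, c(TRUE, FALSE))
})
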