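test_that("the sensor panel reproduces the printed position/force map", {
  panel <- build_sensor_panel()
  df <- as.data.frame(panel)
  expect_length(panel, 8L)
  expect_identical(df$mean_rupture_force, c(12, 16, 23, 33, 43, 50, 54, 56))
  expect_identical(df$biotin_position, c(1L, 2L, 4L, 7L, 11L, 15L, 18L, 21L))
  # bijection and spot checks of the map
  expect_equal(tgt_sensor(11)$mean_rupture_force, 43)
  expect_equal(tgt_sensor(21)$mean_rupture_force, 56)
  expect_false(anyDuplicated(df$mean_rupture_force) > 0)
  # modes carry the printed FWHMs
  expect_true(all(df$fwhm[df$rupture_mode == "unzipping"] == 5))
  expect_true(all(df$fwhm[df$rupture_mode == "shearing"] == 15))
  expect_identical(df$rupture_mode[1:2], c("unzipping", "unzipping"))

  with_nc <- build_sensor_panel(include_control = TRUE)
  expect_length(with_nc, 9L)
  expect_equal(sum(!as.data.frame(with_nc)$np_conjugated), 1L)
  nc <- with_nc[[9L]]
  expect_equal(nc$mean_rupture_force, 56)
  expect_equal(nc$ligand_strand$modification, "none")
})

test_that("the two printed strands anneal into a fully complementary 21-bp duplex", {
  rep <- check_duplex(TGT_LIGAND_STRAND, TGT_ANCHOR_STRAND)
  expect_true(rep$is_fully_complementary)
  expect_equal(rep$duplex_length, 21L)
  expect_length(rep$mismatch_positions, 0L)

  # independent oracle for the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(TGT_ANCHOR_STRAND)))
  expect_identical(rc, TGT_LIGAND_STRAND)

  # a (non-palindromic) strand against itself does not anneal
  expect_false(check_duplex(TGT_LIGAND_STRAND,
                            TGT_LIGAND_STRAND)$is_fully_complementary)
})

test_that("single substitutions are located exactly (brute-force oracle)", {
  lig <- strsplit(TGT_LIGAND_STRAND, "")[[1]]
  rc_anchor <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(TGT_ANCHOR_STRAND))), "")[[1]]
  for (pos in c(1L, 5L, 11L, 21L)) {
    mut <- lig
    mut[pos] <- setdiff(c("A", "C", "G", "T"), lig[pos])[1L]
    rep <- check_duplex(paste(mut, collapse = ""), TGT_ANCHOR_STRAND)
    # oracle: direct position-wise comparison
    expect_identical(rep$mismatch_positions, which(mut != rc_anchor))
    expect_length(rep$mismatch_positions, 1L)
    expect_equal(rep$mismatch_positions, pos)
    expect_false(rep$is_fully_complementary)
  }
})

test_that("check_duplex is symmetric and validates its alphabet", {
  a <- "ACGTACGTAC"
  b <- "GTACGTACGT"
  r_ab <- check_duplex(a, b)
  r_ba <- check_duplex(b, a)
  expect_equal(r_ab$is_fully_complementary, r_ba$is_fully_complementary)
  expect_equal(r_ab$duplex_length, r_ba$duplex_length)
  # mismatch positions mirror across the duplex
  expect_setequal(r_ab$mismatch_positions,
                  r_ab$duplex_length + 1L - r_ba$mismatch_positions)
  expect_error(check_duplex("ACGN", "ACGT"), "invalid sequence")
  expect_error(strand_sequence(""), "non-empty")
  expect_error(strand_sequence("ACGT", "biotin", 5), "biotin_position")
})

test_that("sampled rupture-force distributions recover the printed FWHMs", {
  s12 <- tgt_sensor(1)   # 12 pN, unzipping, FWHM 5
  s56 <- tgt_sensor(21)  # 56 pN, shearing, FWHM 15
  expect_identical(sample_rupture_forces(s12, 0), numeric(0))
  expect_error(sample_rupture_forces(s12, -1), "non-negative")

  f12 <- sample_rupture_forces(s12, 1e5, seed = 42)
  f56 <- sample_rupture_forces(s56, 1e5, seed = 42)
  expect_equal(estimate_fwhm(f12), 5, tolerance = 0.2 / 5)
  expect_equal(estimate_fwhm(f56), 15, tolerance = 0.5 / 15)

  # Monte-Carlo mean within 3 standard errors of the nominal force
  se <- sd(f56) / sqrt(length(f56))
  expect_lt(abs(mean(f56) - 56), 3 * se)

  # reproducibility and truncation
  expect_identical(f12, sample_rupture_forces(s12, 1e5, seed = 42))
  expect_true(all(f12 > 0))
})

test_that("survival probability matches the sampled distribution", {
  s <- tgt_sensor(4)  # 23 pN shearing
  expect_error(survival_probability(s, -1), "non-negative")
  expect_equal(survival_probability(s, 0), 1, tolerance = 1e-6)
  expect_equal(survival_probability(s, s$mean_rupture_force), 0.5,
               tolerance = 1e-3)

  # Monte-Carlo oracle at several forces
  n <- 2e4
  draws <- sample_rupture_forces(s, n, seed = 7)
  for (f in c(10, 23, 30, 45)) {
    emp <- mean(draws > f)
    expect_lt(abs(survival_probability(s, f) - emp), 3 / sqrt(n))
  }

  # monotone non-increasing in applied force ...
  grid <- seq(0, 80, by = 0.5)
  sp <- survival_probability(s, grid)
  expect_true(all(diff(sp) <= 1e-12))
  expect_true(all(sp >= 0 & sp <= 1))
  # ... and non-decreasing in sensor mean force at fixed applied force
  panel <- build_sensor_panel()
  shear <- panel[3:8]  # same FWHM, increasing mean
  at30 <- vapply(shear, survival_probability, 1, applied_force = 30)
  expect_true(all(diff(at30) >= 0))
})

test_that("panel JSON and FASTA round-trips preserve the sensors", {
  panel <- build_sensor_panel(include_control = TRUE)
  json <- tempfile(fileext = ".json")
  export_panel_json(panel, json)
  back <- import_panel_json(json)
  expect_equal(as.data.frame(back), as.data.frame(panel))

  fa <- tempfile(fileext = ".fasta")
  export_panel_fasta(panel, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, 18L)
  expect_true(all(as.character(seqs) %in%
                    c(TGT_LIGAND_STRAND, TGT_ANCHOR_STRAND)))
  unlink(c(json, fa))
})
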