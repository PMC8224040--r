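test_that("reading frame is inferred by minimising in-frame stops", {
  set.seed(211)
  cds <- rand_cds(40)
  rows <- setNames(rep(cds, 6), paste0("s", 1:6))
  loc <- locus_alignment("L1", rows)
  fr <- infer_reading_frame(loc)
  expect_identical(fr$frame, 0L)
  expect_identical(fr$stop_counts[1], 0L)

  # the same rows prefixed by one base shift the frame to 1
  rows1 <- setNames(paste0("G", rows), names(rows))
  loc1 <- locus_alignment("L1b", rows1)
  fr1 <- infer_reading_frame(loc1)
  expect_identical(fr1$frame, 1L)
  # stop totals agree with a brute-force counter in all three frames
  for (f in 0:2)
    expect_identical(fr1$stop_counts[f + 1],
                     brute_stop_counts(rows1, f, 1L, nchar(rows1[[1]])))

  # random non-coding rows are unresolvable
  rows_rand <- setNames(vapply(1:5, function(i) rand_dna(300), character(1)),
                        paste0("s", 1:5))
  fr2 <- infer_reading_frame(locus_alignment("L2", rows_rand))
  expect_true(fr2$unresolvable)
  expect_true(is.na(fr2$frame))
})

test_that("planted flank demarcations are recovered exactly", {
  for (seed in 301:310) {
    sim <- simulate_locus_with_flanks(plant_stop_left = TRUE,
                                      plant_stop_right = TRUE,
                                      plant_gap_left = (seed %% 2 == 0),
                                      plant_gap_right = (seed %% 3 == 0),
                                      seed = seed)
    fr <- infer_reading_frame(sim$locus)
    expect_identical(fr$frame, 0L)
    b <- detect_flanks(sim$locus, fr$frame)
    expect_identical(b$probe_start, sim$truth$probe_start)
    expect_identical(b$probe_end, sim$truth$probe_end)
  }
  # no planted features -> empty flanks
  clean <- simulate_locus_with_flanks(plant_stop_left = FALSE,
                                      plant_stop_right = FALSE, seed = 311)
  b <- detect_flanks(clean$locus, 0L)
  expect_identical(b$probe_start, 1L)
  expect_identical(b$probe_end, clean$locus$width)
})

test_that("splitting is codon-aligned and reconstructs the source columns", {
  sim <- simulate_locus_with_flanks(seed = 313)
  fr <- infer_reading_frame(sim$locus)
  b <- detect_flanks(sim$locus, fr$frame)
  sp <- split_locus(sim$locus, fr$frame, b)
  expect_identical(nchar(sp$probe[[1]]) %% 3L, 0L)
  expect_identical((sp$probe_span[1] - 1L - sp$frame) %% 3L, 0L)
  expect_identical(unname(paste0(sp$left_flank, sp$probe, sp$right_flank)),
                   unname(sim$locus$rows))

  # frame 2: two leading bases go to the left flank
  rows2 <- setNames(paste0("GG", rep(rand_cds(30), 4)), paste0("s", 1:4))
  loc2 <- locus_alignment("L2", rows2)
  fr2 <- infer_reading_frame(loc2)
  expect_identical(fr2$frame, 2L)
  sp2 <- split_locus(loc2, fr2$frame, detect_flanks(loc2, fr2$frame))
  expect_identical(nchar(sp2$left_flank[[1]]), 2L)
})

test_that("frameshift masking follows gaps to compensation or region end", {
  codons <- strsplit(rand_cds(10), "(?<=.{3})", perl = TRUE)[[1]]
  clean <- paste0(codons, collapse = "")
  inframe <- clean; substr(inframe, 13, 15) <- "---"
  shift1 <- clean; substr(shift1, 10, 10) <- "-"
  comp <- clean; substr(comp, 10, 10) <- "-"; substr(comp, 20, 21) <- "--"
  probe <- c(a = clean, b = inframe, c = shift1, d = comp)
  sp <- mask_frameshifts(mk_split(probe))
  expect_identical(sp$probe[["a"]], clean)
  expect_identical(sp$probe[["b"]], inframe)          # 3-nt gap untouched
  expect_identical(sp$probe[["c"]],
                   paste0(substr(clean, 1, 9), strrep("N", 21)))
  expect_identical(sp$probe[["d"]],
                   paste0(substr(clean, 1, 9), strrep("N", 12),
                          substr(clean, 22, 30)))
  # the unmasked tail of the compensated row still translates to the
  # original amino acids
  tail_aa <- anchorkit:::translate_nt(substr(sp$probe[["d"]], 22, 30))
  expect_identical(tail_aa, anchorkit:::translate_nt(substr(clean, 22, 30)))
  # dimensions unchanged, non-N count non-increasing
  expect_identical(nchar(sp$probe), nchar(probe))
})

test_that("short rows are dropped at the 9-base boundary", {
  base <- "ATGAAATGG"
  probe <- c(a = base, b = base, c = base,
             d = paste0("N", substr(base, 2, 9)),          # 8 unambiguous
             e = base)                                      # 9 unambiguous
  sp <- drop_short_and_outliers(mk_split(probe), qc_params())
  expect_identical(sp$report$taxon, "d")
  expect_identical(sp$report$reason, "short")
  expect_true("e" %in% sp$split$taxa)
})

test_that("contaminant rows are removed by consensus disagreement", {
  sim <- simulate_locus_with_flanks(plant_stop_left = FALSE,
                                    plant_stop_right = FALSE, seed = 317)
  loc <- sim$locus
  set.seed(318)
  rows <- loc$rows
  rows[["s03"]] <- rand_cds(nchar(rows[[1]]) %/% 3L)   # unrelated coding row
  loc2 <- locus_alignment(loc$locus_id, rows, core = loc$core)
  res <- qc_locus(loc2)
  expect_true("s03" %in% res$report$taxon[res$report$reason == "outlier"])
  expect_false("s03" %in% res$split$taxa)
})

test_that("post-QC probe rows translate without stops and QC is idempotent", {
  for (seed in 331:335) {
    sim <- simulate_locus_with_flanks(plant_stop_left = TRUE,
                                      plant_stop_right = TRUE,
                                      plant_frameshift = TRUE, seed = seed)
    res <- qc_locus(sim$locus)
    expect_false(is.null(res$split))
    aa <- vapply(res$split$probe, anchorkit:::translate_nt, character(1))
    expect_false(any(grepl("*", aa, fixed = TRUE)))
    # masked frameshift row matches the generator's truth
    tr <- sim$truth
    if (tr$frameshift_row %in% res$split$taxa) {
      masked <- res$split$masks[[tr$frameshift_row]]
      expect_identical(masked[1, 1] + res$split$probe_span[1] - 1L,
                       tr$frameshift_col)
      expect_identical(masked[1, 2], nchar(res$split$probe[[1]]))
    }
    # running QC again on the reassembled locus changes nothing
    res2 <- qc_locus(unsplit_locus(res$split))
    expect_identical(res2$split$probe, res$split$probe)
    expect_identical(res2$split$left_flank, res$split$left_flank)
    expect_identical(res2$split$right_flank, res$split$right_flank)
    expect_identical(nrow(res2$report), 0L)
  }
})
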