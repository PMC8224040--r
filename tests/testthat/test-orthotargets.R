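test_that("codon threading reproduces Tranalign semantics", {
  expect_identical(thread_nucleotides("M-K", "ATGAAA"), "ATG---AAA")
  expect_identical(thread_nucleotides("MK", "ATGAAA"), "ATGAAA")
  # terminal stop codons are stripped before threading
  expect_identical(thread_nucleotides("MK", "ATGAAATAA"), "ATGAAA")
  expect_error(thread_nucleotides("M-K", "ATGAAAAAA"), "length mismatch")
  expect_error(thread_nucleotides("MK", "ATGGGG"), "translation mismatch.*residue 2")
  # an internal stop is a translation mismatch at that residue
  expect_error(thread_nucleotides("MKK", "ATGTAAAAA"), "residue 2")
})

test_that("threading round-trip recovers the CDS", {
  set.seed(401)
  for (rep in 1:20) {
    cds <- rand_cds(sample(10:40, 1))
    aa <- strsplit(anchorkit:::translate_nt(cds), "")[[1]]
    n_gaps <- sample(0:10, 1)
    gapped <- character(0)
    for (a in aa) gapped <- c(gapped, rep("-", sample(0:2, 1)), a)
    aa_row <- paste0(c(gapped, rep("-", n_gaps %% 3)), collapse = "")
    threaded <- thread_nucleotides(aa_row, cds)
    expect_identical(nchar(threaded), 3L * nchar(aa_row))
    expect_identical(gsub("-", "", threaded), cds)
  }
})

test_that("window conservation scores match direct computation", {
  # perfectly conserved alignment scores 1 everywhere
  rows <- setNames(rep(rand_cds(40), 8), paste0("t", 1:8))
  og <- orthogroup_alignment("og1", vapply(rows, anchorkit:::translate_nt,
                                           character(1)), rows)
  sc <- score_conservation(og, design_params())
  expect_true(all(sc$score == 1))
  expect_true(all(sc$eligible))

  # 4/8 vs 4/8 split gives modal frequency 0.5 in every column
  p10 <- design_params(window_len_aa = 10L)
  nt <- c(rep(paste0(rep("GCT", 10), collapse = ""), 4),
          rep(paste0(rep("GGT", 10), collapse = ""), 4))
  names(nt) <- paste0("t", 1:8)
  og2 <- orthogroup_alignment("og2", vapply(nt, anchorkit:::translate_nt,
                                            character(1)), nt)
  sc2 <- score_conservation(og2, p10)
  expect_equal(sc2$score, 0.5)

  # brute-force oracle on a planted-block orthogroup
  sim <- simulate_orthogroups(n_orthogroups = 1, seed = 17)
  og3 <- sim$orthogroups[[1]]
  p <- design_params()
  sc3 <- score_conservation(og3, p)
  oracle <- brute_window_scores(og3, p)
  expect_equal(sc3$score, unname(oracle[, "score"]), tolerance = 1e-12)
  expect_equal(sc3$eligible, oracle[, "eligible"] == 1)
  # the best eligible windows lie inside the planted block
  tr <- sim$truth
  best <- sc3[sc3$eligible & sc3$score == max(sc3$score[sc3$eligible]), ]
  expect_true(all(best$start >= tr$block_aa_start &
                  best$end <= tr$block_aa_end))
})

test_that("window scores are invariant under row permutation", {
  sim <- simulate_orthogroups(n_orthogroups = 1, seed = 23)
  og <- sim$orthogroups[[1]]
  perm <- sample(seq_along(og$taxa))
  og2 <- orthogroup_alignment(og$ortholog_id, og$aa_rows[perm],
                              og$nt_rows[perm], validate = FALSE)
  expect_equal(score_conservation(og)$score, score_conservation(og2)$score)
})

test_that("a too-long window yields an empty result with a warning", {
  rows <- setNames(rep(rand_cds(10), 3), paste0("t", 1:3))
  og <- orthogroup_alignment("og1", vapply(rows, anchorkit:::translate_nt,
                                           character(1)), rows)
  expect_warning(sc <- score_conservation(og, design_params()), "longer")
  expect_identical(nrow(sc), 0L)
})

test_that("target excision merges windows and applies the length filter", {
  p <- design_params()
  # 30-aa fully conserved alignment: merged region is 90 nt < 120 -> dropped
  rows <- setNames(rep(rand_cds(30), 8), paste0("t", 1:8))
  og <- orthogroup_alignment("og1", vapply(rows, anchorkit:::translate_nt,
                                           character(1)), rows)
  sc <- score_conservation(og, p)
  expect_length(excise_targets(og, sc, p), 0)
  # with the length floor at 90 nt the same windows merge into one region
  p90 <- design_params(min_target_len_nt = 90L, bait_len = 90L)
  regs <- excise_targets(og, sc, p90)
  expect_length(regs, 1)
  expect_identical(c(regs[[1]]$aa_start, regs[[1]]$aa_end), c(1L, 30L))
  expect_identical(c(regs[[1]]$nt_start, regs[[1]]$nt_end), c(1L, 90L))
})

test_that("excised regions track planted conserved blocks", {
  p <- design_params()
  sim <- simulate_orthogroups(n_orthogroups = 5, seed = 31)
  for (id in names(sim$orthogroups)) {
    og <- sim$orthogroups[[id]]
    tr <- sim$truth[sim$truth$orthogroup == id, ]
    regs <- excise_targets(og, score_conservation(og, p), p)
    expect_length(regs, 1)
    r <- regs[[1]]
    expect_lte(abs(r$aa_start - tr$block_aa_start), p$window_len_aa)
    expect_lte(abs(r$aa_end - tr$block_aa_end), p$window_len_aa)
    # codon arithmetic: NT span is 3x the AA span, on codon boundaries
    expect_identical(r$nt_start, 3L * (r$aa_start - 1L) + 1L)
    expect_identical(r$nt_end, 3L * r$aa_end)
    expect_identical((r$nt_end - r$nt_start + 1L) %% 3L, 0L)
  }
})

test_that("representation selection enforces the min-taxa rule", {
  p <- design_params()
  full <- strrep("A", 120)
  gappy <- paste0(strrep("A", 60), strrep("-", 60))  # 50% non-gap
  r5 <- mk_region(setNames(c(rep(full, 5), rep(gappy, 3)), paste0("t", 1:8)))
  kept <- select_targets(list(r5), p)
  expect_length(kept, 1)
  expect_setequal(kept[[1]]$represented_taxa, paste0("t", 1:5))
  r4 <- mk_region(setNames(c(rep(full, 4), rep(gappy, 4)), paste0("t", 1:8)))
  expect_length(select_targets(list(r4), p), 0)
})

test_that("selection is monotone in the min-taxa threshold", {
  sim <- simulate_orthogroups(n_orthogroups = 10, seed = 37)
  p <- design_params()
  regs <- unlist(lapply(sim$orthogroups, function(og)
    excise_targets(og, score_conservation(og, p), p)), recursive = FALSE)
  prev <- character(0)
  for (k in 8:3) {
    kept <- select_targets(regs, design_params(min_ref_taxa = k))
    ids <- vapply(kept, `[[`, character(1), "ortholog_id")
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("bait tiling covers every position with the documented step", {
  p <- design_params()
  tile1 <- function(L) {
    r <- mk_region(setNames(rand_dna(L), "t1"), represented = "t1")
    tile_baits(r, p)
  }
  bs <- tile1(100)
  expect_identical(bs$step_nt, 87L)
  expect_identical(bs$baits$start, 1L)
  bs274 <- tile1(274)
  expect_identical(bs274$baits$start, c(1L, 88L, 175L))
  bs275 <- tile1(275)
  expect_identical(bs275$baits$start, c(1L, 88L, 175L, 176L))
  expect_true(all(nchar(bs275$baits$sequence) == 100))

  set.seed(43)
  for (L in sample(100:2000, 30)) {
    bs <- tile1(L)
    covered <- rep(FALSE, L)
    for (s in bs$baits$start) covered[s:(s + p$bait_len - 1)] <- TRUE
    expect_true(all(covered))
    n <- nrow(bs$baits)
    expect_lte(n * p$bait_len / L, p$tiling_factor + p$bait_len / L + 1e-9)
  }
})

test_that("duplicate bait sequences are removed and short spans skipped", {
  p <- design_params()
  s <- rand_dna(200)
  r <- mk_region(setNames(c(s, s), c("t1", "t2")),
                 represented = c("t1", "t2"))
  bs <- tile_baits(r, p)
  expect_identical(anyDuplicated(bs$baits$sequence), 0L)
  expect_true(all(bs$baits$taxon == "t1"))
  r2 <- mk_region(setNames(c(rand_dna(150), rand_dna(60)), c("t1", "t2")),
                  represented = c("t1", "t2"))
  expect_warning(bs2 <- tile_baits(r2, p), "shorter than bait length")
  expect_true(all(bs2$baits$taxon == "t1"))
})

test_that("design outputs round-trip through FASTA/TSV export", {
  sim <- simulate_orthogroups(n_orthogroups = 2, seed = 47)
  d <- withr::local_tempdir()
  des <- design_baits(sim$orthogroups[[1]])
  if (length(des$regions) > 0) {
    write_design(des$regions, des$bait_sets, d)
    tgt <- read_fasta(file.path(d, "targets.fasta"))
    expect_true(all(grepl("^og\\d+\\|t\\d+\\|\\d+-\\d+$", names(tgt))))
    baits <- read_fasta(file.path(d, "baits.fasta"))
    expect_true(all(nchar(baits) == 100))
  }
})
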