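# small helper: split loci with given taxa subsets and probe widths
mk_loci <- function(spec, width = 30L) {
  lapply(names(spec), function(id) {
    taxa <- spec[[id]]
    probe <- setNames(rep(rand_cds(width %/% 3L), length(taxa)), taxa)
    mk_split(probe, id = id)
  })
}

test_that("completeness filtering uses a strict at-least (ceiling) rule", {
  taxa <- paste0("s", 1:10)
  loci <- mk_loci(list(L1 = taxa[1:5], L2 = taxa[1:4], L3 = taxa[1:7],
                       L4 = taxa[1:8]))
  keep50 <- filter_by_completeness(loci, taxa, matrix_params(0.5))
  expect_setequal(vapply(keep50, `[[`, character(1), "locus_id"),
                  c("L1", "L3", "L4"))
  # 7 of 10 at 75% requires ceiling(7.5) = 8 -> dropped
  keep75 <- filter_by_completeness(loci, taxa, matrix_params(0.75))
  expect_setequal(vapply(keep75, `[[`, character(1), "locus_id"), "L4")
  # nesting: the 75% set is contained in the 50% set
  expect_true(all(vapply(keep75, `[[`, character(1), "locus_id") %in%
                  vapply(keep50, `[[`, character(1), "locus_id")))
})

test_that("concatenation is width-additive, ordered, and fills missing taxa", {
  set.seed(503)
  taxa <- paste0("s", 1:4)
  loci <- mk_loci(list(B = taxa, A = taxa[1:3]), width = 30L)
  b <- concatenate_loci(loci, taxa, matrix_params())
  expect_identical(anchorkit:::matrix_width(b), 60L)
  # lexicographic locus order: A first
  expect_identical(b$map$locus, c("A", "B"))
  # taxon missing from A is all-'?' over A's columns
  expect_identical(substring(b$seqs[["s4"]], 1, 30), strrep("?", 30))
  # ungapped content conserved per taxon and locus
  for (sp in loci) for (tx in sp$taxa) {
    blk <- b$map[b$map$locus == sp$locus_id, ]
    expect_identical(substring(b$seqs[[tx]], blk$start, blk$end),
                     unname(sp$probe[[tx]]))
  }
})

test_that("partitions are stride-3 per locus plus one flank partition", {
  taxa <- paste0("s", 1:3)
  probe <- setNames(rep(rand_cds(100), 3), taxa)
  lf <- setNames(rep(strrep("A", 11), 3), taxa)
  rf <- setNames(rep(strrep("C", 7), 3), taxa)
  sp <- mk_split(probe, id = "locus1")
  sp$left_flank <- lf; sp$right_flank <- rf
  b <- concatenate_loci(list(sp), taxa, matrix_params(include_flanks = TRUE))
  parts <- define_partitions(b)
  expect_identical(parts$name, c("locus1_pos1", "locus1_pos2",
                                 "locus1_pos3", "flanks"))
  expect_identical(parts$spec[1:3],
                   c("1-300\\3", "2-300\\3", "3-300\\3"))
  expect_identical(parts$cols[[1]], seq.int(1L, 300L, 3L))
  # flank partition covers both flank blocks
  expect_identical(parts$ncol[4], 18L)
  # partition columns tile the matrix exactly
  allcols <- sort(unlist(parts$cols))
  expect_identical(allcols, seq_len(anchorkit:::matrix_width(b)))
  # pos1/pos2/pos3 of a locus are disjoint and union to the locus interval
  expect_identical(sort(unlist(parts$cols[1:3])), 1:300)
})

test_that("small partitions are pruned at the 80-column boundary", {
  taxa <- paste0("s", 1:3)
  loci <- list(mk_split(setNames(rep(rand_cds(79), 3), taxa), id = "short"),
               mk_split(setNames(rep(rand_cds(80), 3), taxa), id = "long"))
  b <- concatenate_loci(loci, taxa)
  parts <- define_partitions(b)
  res <- drop_small_partitions(parts, matrix_params(min_partition_len = 80L))
  expect_setequal(res$removed$name,
                  paste0("short_pos", 1:3))
  expect_setequal(res$kept$name, paste0("long_pos", 1:3))
  expect_identical(res$removed_columns, sum(res$removed$ncol))
  expect_identical(res$removed_columns + sum(res$kept$ncol),
                   anchorkit:::matrix_width(b))
})

test_that("third-position stripping removes exactly one third of probe columns", {
  set.seed(509)
  taxa <- paste0("s", 1:3)
  probe <- setNames(rep(rand_cds(100), 3), taxa)
  sp <- mk_split(probe, id = "L1")
  sp$left_flank <- setNames(rep(strrep("A", 50), 3), taxa)
  b <- concatenate_loci(list(sp), taxa, matrix_params(include_flanks = TRUE))
  s <- strip_third_positions(b)
  pm <- s$map[s$map$kind == "probe", ]
  expect_identical(pm$end - pm$start + 1L, 200L)
  fm <- s$map[s$map$kind == "flank", ]
  expect_identical(fm$end - fm$start + 1L, 50L)   # flanks untouched
  # stripped rows = positions 1 and 2 of every codon
  keep <- sort(c(seq(1, 300, 3), seq(2, 300, 3)))
  expect_identical(substring(s$seqs[["s1"]], pm$start, pm$end),
                   paste0(strsplit(probe[[1]], "")[[1]][keep], collapse = ""))
  expect_error(strip_third_positions(s), "already stripped")
  expect_error(translate_matrix(s), "translate before stripping")
})

test_that("translation follows the codon ambiguity rules", {
  taxa <- c("s1", "s2", "s3")
  probe <- c(s1 = "ATGAAA", s2 = "ATGNAA", s3 = "ATG---")
  b <- concatenate_loci(list(mk_split(probe, id = "L1")), c(taxa, "s4"))
  aa <- translate_matrix(b)
  expect_identical(unname(aa$seqs[c("s1", "s2", "s3", "s4")]),
                   c("MK", "MX", "M-", "??"))
  expect_identical(aa$type, "AA")
  expect_identical(anchorkit:::matrix_width(aa), 2L)
})

test_that("matrix translation is compositional over loci", {
  set.seed(521)
  taxa <- paste0("s", 1:5)
  loci <- mk_loci(list(L1 = taxa, L2 = taxa[2:5], L3 = taxa[1:4]),
                  width = 60L)
  b <- concatenate_loci(loci, taxa)
  aa <- translate_matrix(b)
  for (tx in taxa) {
    per_locus <- vapply(sort(c("L1", "L2", "L3")), function(id) {
      sp <- loci[[which(vapply(loci, `[[`, character(1), "locus_id") == id)]]
      if (tx %in% sp$taxa) anchorkit:::translate_nt(sp$probe[[tx]])
      else strrep("?", nchar(sp$probe[[1]]) %/% 3L)
    }, character(1))
    expect_identical(unname(aa$seqs[[tx]]), paste0(per_locus, collapse = ""))
  }
})

test_that("matrix, partition and map exports round-trip exactly", {
  set.seed(523)
  taxa <- paste0("s", 1:6)
  loci <- mk_loci(list(L1 = taxa, L2 = taxa[1:4]), width = 90L)
  loci[[1]]$right_flank <- setNames(rep(strrep("G", 12), 6), taxa)
  b <- concatenate_loci(loci, taxa, matrix_params(include_flanks = TRUE))
  d <- withr::local_tempdir()
  for (fmt in c("phylip", "fasta")) {
    mp <- file.path(d, paste0("m.", fmt))
    write_supermatrix(b, mp, format = fmt)
    write_coordinate_map(b, file.path(d, "map.tsv"))
    b2 <- import_bundle(mp, file.path(d, "map.tsv"))
    expect_identical(b2$seqs, b$seqs)
    expect_identical(as.data.frame(b2$map), as.data.frame(b$map))
  }
  parts <- define_partitions(b)
  write_partitions(parts, file.path(d, "parts.txt"))
  p2 <- read_partitions(file.path(d, "parts.txt"),
                        anchorkit:::matrix_width(b))
  expect_identical(p2$name, parts$name)
  expect_identical(lapply(p2$cols, as.integer),
                   lapply(parts$cols, as.integer))
})
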