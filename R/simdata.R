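SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

random_sense_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

# replace each codon independently with probability `rate` by a random sense
# codon (per-site uniform replacement; controls identity without a full
# continuous-time model)
mutate_codons <- function(codons, rate) {
  hit <- stats::runif(length(codons)) < rate
  codons[hit] <- random_sense_codons(sum(hit))
  codons
}

# substitute each base independently with probability `rate` by one of the
# three other bases (expected identity = 1 - rate)
mutate_nt <- function(seq, rate) {
  chars <- str_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste0(chars, collapse = "")
}

#' Simulate orthogroups with planted conserved blocks
#'
#' Each orthogroup is a spacer-block-spacer coding layout evolved from a
#' random ancestor CDS along a star tree: the central block mutates at
#' `conserved_rate` per amino-acid site, the spacers at `spacer_rate`
#' (per-site uniform codon replacement, so coding sequences stay stop-free).
#' Each orthogroup contains a random subset of the reference taxa (between
#' `min_taxa_present` and `n_taxa` rows), emulating incomplete ortholog
#' recovery.
#'
#' @param n_orthogroups number of orthogroups.
#' @param n_taxa size of the reference taxon universe.
#' @param block_aa,spacer_aa planted block and spacer lengths in codons.
#' @param conserved_rate,spacer_rate per-site replacement probabilities.
#' @param min_taxa_present minimum taxa per orthogroup.
#' @param seed RNG seed (mandatory; generation is byte-reproducible).
#' @return list with `orthogroups` (list of [orthogroup_alignment()]) and
#'   `truth` (tibble: orthogroup, block AA span, NT span, n_taxa_present).
#' @export
simulate_orthogroups <- function(n_orthogroups = 20L, n_taxa = 8L,
                                 block_aa = 60L, spacer_aa = 40L,
                                 conserved_rate = 0.02, spacer_rate = 1.0,
                                 min_taxa_present = 4L, seed) {
  stopifnot(block_aa > 0, spacer_aa >= 0, min_taxa_present >= 2,
            min_taxa_present <= n_taxa)
  withr::with_seed(seed, {
    taxa <- sprintf("t%02d", seq_len(n_taxa))
    ogs <- list(); truth <- list()
    n_aa <- 2L * spacer_aa + block_aa
    block_start <- spacer_aa + 1L
    block_end <- spacer_aa + block_aa
    rates <- rep(c(spacer_rate, conserved_rate, spacer_rate),
                 c(spacer_aa, block_aa, spacer_aa))
    for (i in seq_len(n_orthogroups)) {
      id <- sprintf("og%03d", i)
      anc <- random_sense_codons(n_aa)
      n_present <- sample(min_taxa_present:n_taxa, 1L)
      present <- sort(sample(taxa, n_present))
      nt_rows <- vapply(present, function(tx) {
        cod <- anc
        for (j in seq_len(n_aa))
          if (stats::runif(1L) < rates[j]) cod[j] <- random_sense_codons(1L)
        paste0(cod, collapse = "")
      }, character(1))
      aa_rows <- vapply(nt_rows, translate_nt, character(1))
      names(aa_rows) <- present
      ogs[[id]] <- orthogroup_alignment(id, aa_rows, nt_rows,
                                        validate = FALSE)
      truth[[id]] <- tibble::tibble(
        orthogroup = id, block_aa_start = block_start,
        block_aa_end = block_end,
        block_nt_start = 3L * (block_start - 1L) + 1L,
        block_nt_end = 3L * block_end,
        n_taxa_present = n_present)
    }
    list(orthogroups = ogs, truth = do.call(rbind, truth))
  })
}

#' Simulate contig sets with planted matches, paralogs and decoys
#'
#' Per target, one full-length mutated copy at the requested identity is
#' planted (expected 1:1 acceptance).  Targets named in `multi_target_pair`
#' get no 1:1 copy but a single chimeric contig spanning both (triggering
#' the multi-target contig filter); `paralog_target` gets a second
#' independent copy (triggering the multi-contig target filter).  Decoys are
#' random sequences rejection-sampled to share no `seed_len`-mer with any
#' target.
#'
#' @param targets named character vector of target sequences.
#' @param identity planted contig identity (substitution-only).
#' @param multi_target_pair two target ids to fuse into one chimeric contig,
#'   or `NULL`.
#' @param paralog_target target id receiving a planted paralog, or `NULL`.
#' @param n_decoys number of decoy contigs.
#' @param seed_len k-mer length the decoys must avoid sharing.
#' @param seed RNG seed.
#' @return list with `contigs` (named character vector) and `truth` (list:
#'   `accepted`, `unmatched`, `rejected_targets`, `rejected_contigs`).
#' @export
simulate_contigs <- function(targets, identity = 0.85,
                             multi_target_pair = NULL, paralog_target = NULL,
                             n_decoys = 20L, seed_len = 15L, seed) {
  stopifnot(length(targets) >= 1L, identity > 0, identity <= 1)
  if (!is.null(multi_target_pair))
    stopifnot(length(multi_target_pair) == 2L,
              all(multi_target_pair %in% names(targets)))
  if (!is.null(paralog_target))
    stopifnot(paralog_target %in% names(targets),
              !(paralog_target %in% multi_target_pair))
  withr::with_seed(seed, {
    rate <- 1 - identity
    contigs <- character(0)
    plain <- setdiff(names(targets), multi_target_pair)
    for (ti in plain)
      contigs[[paste0("c_", ti)]] <- mutate_nt(targets[[ti]], rate)
    if (!is.null(multi_target_pair))
      contigs[["multi_1"]] <- paste0(
        mutate_nt(targets[[multi_target_pair[1L]]], rate),
        mutate_nt(targets[[multi_target_pair[2L]]], rate))
    if (!is.null(paralog_target))
      contigs[["paralog_1"]] <- mutate_nt(targets[[paralog_target]], rate)
    target_kmers <- unique(unlist(lapply(targets, kmer_set, k = seed_len)))
    mean_len <- as.integer(round(mean(nchar(targets))))
    for (d in seq_len(n_decoys)) {
      repeat {
        s <- paste0(sample(c("A", "C", "G", "T"), mean_len, replace = TRUE),
                    collapse = "")
        if (length(intersect(kmer_set(s, seed_len), target_kmers)) == 0L)
          break
      }
      contigs[[sprintf("decoy_%02d", d)]] <- s
    }
    truth <- list(
      accepted = sort(setdiff(names(targets),
                              c(multi_target_pair, paralog_target))),
      unmatched = sort(multi_target_pair %||% character(0)),
      rejected_targets = sort(paralog_target %||% character(0)),
      rejected_contigs = if (is.null(multi_target_pair)) character(0)
        else "multi_1")
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate per-assembler match tables for reconciliation
#'
#' Each assembler recovers a random subset of the targets with a random
#' fragment length; at least one assembler recovers every target.  Used to
#' exercise longest-fragment reconciliation.
#'
#' @param targets character vector of target ids.
#' @param assemblers assembler names.
#' @param len_range fragment length range.
#' @param recover_prob per-assembler recovery probability.
#' @param seed RNG seed.
#' @return named list of `match_table`-shaped objects (accepted tibbles
#'   only).
#' @export
simulate_assembly_tables <- function(targets,
                                     assemblers = c("abyss", "abyss_merged",
                                                    "skesa", "spades"),
                                     len_range = c(150L, 600L),
                                     recover_prob = 0.7, seed) {
  withr::with_seed(seed, {
    out <- lapply(assemblers, function(asm) {
      got <- targets[stats::runif(length(targets)) < recover_prob]
      tibble::tibble(
        target = got,
        contig = paste0(asm, "_", got),
        identity = 1, coverage = 1,
        length = sample(len_range[1L]:len_range[2L], length(got),
                        replace = TRUE))
    })
    names(out) <- assemblers
    # guarantee every target is recovered somewhere
    missing <- setdiff(targets, unlist(lapply(out, `[[`, "target")))
    if (length(missing) > 0L)
      out[[1L]] <- rbind(out[[1L]], tibble::tibble(
        target = missing, contig = paste0(assemblers[1L], "_", missing),
        identity = 1, coverage = 1,
        length = sample(len_range[1L]:len_range[2L], length(missing),
                        replace = TRUE)))
    lapply(out, function(acc)
      structure(list(accepted = acc[order(acc$target), , drop = FALSE],
                     rejected_contigs = tibble::tibble(contig = character(0),
                                                       reason = character(0)),
                     rejected_targets = tibble::tibble(target = character(0),
                                                       reason = character(0)),
                     unmatched = character(0)), class = "match_table"))
  })
}

#' Simulate a locus alignment with planted flanks and frameshifts
#'
#' A coding core of `core_codons` flanked by `flank_codons` codons on each
#' side, all evolved from one ancestor at a low rate so the alignment is
#' consensus-consistent; demarcation features are then planted at recorded
#' positions: an in-frame stop codon in one row of a flank, a gap run of
#' length `gap_len` (not divisible by 3) in one row of a flank, and
#' optionally a 1-nt frameshift gap inside the core of one row.
#'
#' @param n_taxa rows.
#' @param core_codons,flank_codons lengths in codons.
#' @param rate per-codon replacement probability.
#' @param plant_stop_left,plant_stop_right plant a stop codon in the
#'   left/right flank.
#' @param plant_gap_left,plant_gap_right plant a mod-3-breaking gap run in
#'   the left/right flank.
#' @param gap_len planted gap run length (`gap_len %% 3 != 0`).
#' @param plant_frameshift plant a single 1-nt gap inside the core of one
#'   row.
#' @param seed RNG seed.
#' @return list with `locus` (a [locus_alignment()] whose `core` is the
#'   coding core) and `truth`: expected probe boundaries
#'   (`probe_start`/`probe_end`, innermost planted trigger + 1), planted
#'   feature positions, and the frameshift row/column with its expected
#'   mask span.
#' @export
simulate_locus_with_flanks <- function(n_taxa = 10L, core_codons = 30L,
                                       flank_codons = 10L, rate = 0.02,
                                       plant_stop_left = TRUE,
                                       plant_stop_right = TRUE,
                                       plant_gap_left = FALSE,
                                       plant_gap_right = FALSE,
                                       gap_len = 4L,
                                       plant_frameshift = FALSE, seed) {
  stopifnot(gap_len %% 3L != 0L, flank_codons >= 4L || !(plant_stop_left ||
              plant_stop_right || plant_gap_left || plant_gap_right))
  withr::with_seed(seed, {
    taxa <- sprintf("s%02d", seq_len(n_taxa))
    n_cod <- core_codons + 2L * flank_codons
    anc <- random_sense_codons(n_cod)
    rows <- vapply(taxa, function(tx)
      paste0(mutate_codons(anc, rate), collapse = ""), character(1))
    width <- 3L * n_cod
    core <- c(3L * flank_codons + 1L, 3L * (flank_codons + core_codons))
    set_codon <- function(row, cod_idx, value) {
      s <- 3L * (cod_idx - 1L) + 1L
      paste0(substring(row, 1L, s - 1L), value, substring(row, s + 3L, width))
    }
    truth <- list(stop_left = NA_integer_, stop_right = NA_integer_,
                  gap_left = NA_integer_, gap_right = NA_integer_)
    lb <- integer(0); rb <- integer(0)
    # planted features go into distinct rows so one can never overwrite
    # another and the recorded truth stays exact
    free_rows <- sample(taxa)
    take_row <- function() {
      tx <- free_rows[1L]; free_rows <<- free_rows[-1L]; tx
    }
    if (plant_stop_left) {
      cod <- sample(2:(flank_codons - 1L), 1L)   # strictly inside left flank
      tx <- take_row()
      rows[[tx]] <- set_codon(rows[[tx]], cod, "TAA")
      truth$stop_left <- 3L * (cod - 1L) + 1L
      lb <- c(lb, 3L * cod)                      # innermost col of the codon
    }
    if (plant_stop_right) {
      cod <- sample((flank_codons + core_codons + 2L):(n_cod - 1L), 1L)
      tx <- take_row()
      rows[[tx]] <- set_codon(rows[[tx]], cod, "TAA")
      truth$stop_right <- 3L * (cod - 1L) + 1L
      rb <- c(rb, 3L * (cod - 1L) + 1L)
    }
    if (plant_gap_left) {
      gs <- sample(seq.int(4L, core[1L] - 1L - gap_len), 1L)
      tx <- take_row()
      chars <- str_chars(rows[[tx]])
      chars[gs:(gs + gap_len - 1L)] <- "-"
      rows[[tx]] <- paste0(chars, collapse = "")
      truth$gap_left <- gs
      lb <- c(lb, gs + gap_len - 1L)
    }
    if (plant_gap_right) {
      gs <- sample(seq.int(core[2L] + 4L, width - gap_len - 2L), 1L)
      tx <- take_row()
      chars <- str_chars(rows[[tx]])
      chars[gs:(gs + gap_len - 1L)] <- "-"
      rows[[tx]] <- paste0(chars, collapse = "")
      truth$gap_right <- gs
      rb <- c(rb, gs)
    }
    truth$probe_start <- if (length(lb) > 0L) max(lb) + 1L else 1L
    truth$probe_end <- if (length(rb) > 0L) min(rb) - 1L else width
    truth$frameshift_row <- NA_character_
    truth$frameshift_col <- NA_integer_
    if (plant_frameshift) {
      tx <- take_row()
      col <- sample(seq.int(core[1L] + 9L, core[2L] - 9L), 1L)
      chars <- str_chars(rows[[tx]])
      chars[col] <- "-"
      rows[[tx]] <- paste0(chars, collapse = "")
      truth$frameshift_row <- tx
      truth$frameshift_col <- col
    }
    list(locus = locus_alignment(sprintf("locus_seed%d", seed), rows,
                                 core = core),
         truth = truth)
  })
}

# evolve a vector of state indices along a branch under the k-state
# equal-rates model
evolve_states <- function(states, t, k) {
  p_change <- (k - 1) / k * (1 - exp(-k * t / (k - 1)))
  hit <- which(stats::runif(length(states)) < p_change)
  if (length(hit) > 0L)
    states[hit] <- vapply(states[hit], function(s)
      sample(seq_len(k)[-s], 1L), integer(1))
  states
}

#' Simulate a quartet alignment under JC69
#'
#' Exact Jukes-Cantor simulation on the 5-branch unrooted quartet tree
#' `((a,b),(c,d))` (topology T1 relabels as requested): uniform root states
#' at the first internal node, then transition-probability sampling along
#' each branch.
#'
#' @param n_sites alignment length.
#' @param t_internal internal branch length (expected substitutions/site);
#'   0 gives a star tree.
#' @param t_terminal terminal branch length (shared by the four tips).
#' @param taxa four tip names, in the order `(a, b, c, d)`.
#' @param topology 1, 2 or 3: which unrooted topology the data are
#'   simulated under (`ab|cd`, `ac|bd`, `ad|bc`).
#' @param seed RNG seed.
#' @return list with `alignment` (named character vector of four sequences)
#'   and `truth` (topology, branch lengths, seed).
#' @export
simulate_quartet_alignment <- function(n_sites = 1000L, t_internal = 0.2,
                                       t_terminal = 0.05,
                                       taxa = c("a", "b", "c", "d"),
                                       topology = 1L, seed) {
  stopifnot(length(taxa) == 4L, topology %in% 1:3)
  withr::with_seed(seed, {
    k <- 4L
    alpha <- c("A", "C", "G", "T")
    u <- sample.int(k, n_sites, replace = TRUE)
    v <- evolve_states(u, t_internal, k)
    pair1 <- switch(topology, c(1L, 2L), c(1L, 3L), c(1L, 4L))
    pair2 <- setdiff(1:4, pair1)
    tips <- vector("list", 4L)
    for (i in pair1) tips[[i]] <- evolve_states(u, t_terminal, k)
    for (i in pair2) tips[[i]] <- evolve_states(v, t_terminal, k)
    alignment <- vapply(tips, function(s) paste0(alpha[s], collapse = ""),
                        character(1))
    names(alignment) <- taxa
    list(alignment = alignment,
         truth = list(topology = topology, t_internal = t_internal,
                      t_terminal = t_terminal, n_sites = n_sites,
                      seed = seed))
  })
}

#' Simulate a clustered alignment for four-cluster likelihood mapping
#'
#' Four clusters of `n_per_cluster` taxa hang off the four tips of a quartet
#' scaffold simulated as in [simulate_quartet_alignment()]; within-cluster
#' tips evolve from their cluster ancestor along `t_within`.  Every
#' one-per-cluster quartet then carries the scaffold's internal-branch
#' signal.
#'
#' @param n_per_cluster taxa per cluster.
#' @param t_within within-cluster terminal branch length.
#' @inheritParams simulate_quartet_alignment
#' @return list with `alignment`, `clusters` (named vector taxon ->
#'   `C1`-`C4`) and `truth`.
#' @export
simulate_cluster_alignment <- function(n_per_cluster = 2L, n_sites = 1000L,
                                       t_internal = 0.2, t_terminal = 0.05,
                                       t_within = 0.02, topology = 1L,
                                       seed) {
  withr::with_seed(seed, {
    k <- 4L
    alpha <- c("A", "C", "G", "T")
    u <- sample.int(k, n_sites, replace = TRUE)
    v <- evolve_states(u, t_internal, k)
    pair1 <- switch(topology, c(1L, 2L), c(1L, 3L), c(1L, 4L))
    anc <- vector("list", 4L)
    for (i in pair1) anc[[i]] <- evolve_states(u, t_terminal, k)
    for (i in setdiff(1:4, pair1)) anc[[i]] <- evolve_states(v, t_terminal, k)
    alignment <- character(0); clusters <- character(0)
    for (ci in 1:4) {
      for (j in seq_len(n_per_cluster)) {
        nm <- sprintf("c%d_%d", ci, j)
        alignment[[nm]] <- paste0(
          alpha[evolve_states(anc[[ci]], t_within, k)], collapse = "")
        clusters[[nm]] <- paste0("C", ci)
      }
    }
    list(alignment = alignment, clusters = clusters,
         truth = list(topology = topology, t_internal = t_internal,
                      t_terminal = t_terminal, t_within = t_within,
                      n_sites = n_sites, seed = seed))
  })
}
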