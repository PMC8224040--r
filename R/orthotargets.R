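#' Bait design parameters
#'
#' Tunables for conserved-window detection, target excision/selection and
#' bait tiling.  Defaults follow the published design: 100-nt baits at 1.15X
#' tiling, targets kept when represented in at least five reference taxa.
#'
#' @param window_len_aa sliding-window length, in amino-acid columns.
#' @param conservation_threshold minimum mean modal-residue frequency for a
#'   window to count as conserved (0-1].
#' @param max_gap_fraction a window is ineligible if any of its columns has a
#'   gap fraction above this value.
#' @param min_target_len_nt minimum excised region length in nucleotides
#'   (multiple of 3).
#' @param min_ref_taxa minimum number of represented reference taxa for a
#'   target to be selected.
#' @param representation_min_nongap a taxon represents a region when its
#'   non-gap fraction within the region is at least this value.
#' @param bait_len bait length in nucleotides.
#' @param tiling_factor average per-base bait coverage of a target; the tiling
#'   step is `round(bait_len / tiling_factor)`.
#' @return an object of class `design_params`.
#' @export
design_params <- function(window_len_aa = 20L,
                          conservation_threshold = 0.7,
                          max_gap_fraction = 0.2,
                          min_target_len_nt = 120L,
                          min_ref_taxa = 5L,
                          representation_min_nongap = 0.9,
                          bait_len = 100L,
                          tiling_factor = 1.15) {
  stopifnot(window_len_aa >= 1, min_target_len_nt >= 1,
            min_target_len_nt %% 3 == 0, min_ref_taxa >= 1, bait_len >= 1,
            tiling_factor > 0, conservation_threshold > 0,
            conservation_threshold <= 1, max_gap_fraction >= 0,
            max_gap_fraction <= 1, representation_min_nongap >= 0,
            representation_min_nongap <= 1)
  if (min_target_len_nt < bait_len)
    stop("min_target_len_nt must be >= bait_len")
  structure(list(window_len_aa = as.integer(window_len_aa),
                 conservation_threshold = conservation_threshold,
                 max_gap_fraction = max_gap_fraction,
                 min_target_len_nt = as.integer(min_target_len_nt),
                 min_ref_taxa = as.integer(min_ref_taxa),
                 representation_min_nongap = representation_min_nongap,
                 bait_len = as.integer(bait_len),
                 tiling_factor = tiling_factor),
            class = "design_params")
}

#' Paired amino-acid / nucleotide orthogroup alignment
#'
#' Container for one single-copy ortholog across the reference taxa: a gapped
#' amino-acid alignment and the codon-threaded nucleotide alignment (each NT
#' row exactly 3x its AA row, gaps expanded to `---`).
#'
#' @param ortholog_id ortholog identifier.
#' @param aa_rows named character vector of gapped AA sequences (equal length).
#' @param nt_rows named character vector of gapped NT sequences; if omitted,
#'   rows are threaded from `cds_rows`.
#' @param cds_rows named character vector of unaligned coding sequences used
#'   to thread `nt_rows` when those are not supplied.
#' @param validate check the threading invariant (each NT row, ungapped and
#'   translated, reproduces its ungapped AA row).
#' @return an object of class `orthogroup_alignment` with fields
#'   `ortholog_id`, `taxa`, `aa_rows`, `nt_rows`.
#' @export
orthogroup_alignment <- function(ortholog_id, aa_rows, nt_rows = NULL,
                                 cds_rows = NULL, validate = TRUE) {
  aa_rows <- toupper(aa_rows)
  if (is.null(names(aa_rows)) || anyDuplicated(names(aa_rows)))
    stop("aa_rows must be uniquely named by taxon")
  if (length(unique(nchar(aa_rows))) > 1L)
    stop("AA rows of '", ortholog_id, "' have unequal lengths")
  if (is.null(nt_rows)) {
    if (is.null(cds_rows)) stop("supply nt_rows or cds_rows")
    cds_rows <- toupper(cds_rows)
    missing <- setdiff(names(aa_rows), names(cds_rows))
    if (length(missing) > 0L)
      stop("no CDS for taxa: ", paste(missing, collapse = ", "))
    nt_rows <- vapply(names(aa_rows), function(tx) {
      thread_nucleotides(aa_rows[[tx]], cds_rows[[tx]],
                         ortholog_id = ortholog_id, taxon = tx)
    }, character(1))
  } else {
    nt_rows <- toupper(nt_rows)
    if (!setequal(names(aa_rows), names(nt_rows)))
      stop("aa_rows and nt_rows name different taxa")
    nt_rows <- nt_rows[names(aa_rows)]
    if (any(nchar(nt_rows) != 3L * nchar(aa_rows)))
      stop("each NT row must be exactly 3x its AA row")
    if (validate) {
      for (tx in names(aa_rows)) {
        tr <- translate_nt(ungap(nt_rows[[tx]]))
        if (!identical(tr, ungap(aa_rows[[tx]])))
          stop("NT row of taxon '", tx, "' in '", ortholog_id,
               "' does not translate to its AA row")
      }
    }
  }
  structure(list(ortholog_id = ortholog_id, taxa = names(aa_rows),
                 aa_rows = aa_rows, nt_rows = nt_rows),
            class = "orthogroup_alignment")
}

#' Thread codons onto a gapped amino-acid row
#'
#' Reproduces the Tranalign operation: each residue of the gapped AA row is
#' replaced by its codon from the unaligned CDS, and each gap by `---`.  A
#' terminal stop codon on the CDS is stripped before threading; internal
#' stops and any residue/codon disagreement are errors.
#'
#' @param aa_row gapped amino-acid sequence.
#' @param cds unaligned coding sequence for the same taxon.
#' @param ortholog_id,taxon identifiers used in error messages.
#' @return the gapped nucleotide row (length `3 * nchar(aa_row)`).
#' @export
thread_nucleotides <- function(aa_row, cds, ortholog_id = NULL, taxon = NULL) {
  aa_row <- toupper(aa_row); cds <- toupper(cds)
  who <- paste0(if (!is.null(ortholog_id)) paste0(" in '", ortholog_id, "'"),
                if (!is.null(taxon)) paste0(" for taxon '", taxon, "'"))
  aa <- str_chars(aa_row)
  n_res <- sum(aa != "-")
  if (nchar(cds) == 3L * n_res + 3L &&
      substring(cds, nchar(cds) - 2L) %in% STOP_CODONS)
    cds <- substring(cds, 1L, nchar(cds) - 3L)
  if (nchar(cds) != 3L * n_res)
    stop("threading length mismatch", who, ": ", n_res,
         " residues vs CDS of ", nchar(cds), " nt")
  codons <- codons_of(cds)
  trans <- translate_codons(codons)
  res <- aa[aa != "-"]
  bad <- which(trans != res)
  if (length(bad) > 0L)
    stop("threading translation mismatch", who, " at residue ", bad[1L],
         ": codon ", codons[bad[1L]], " (", trans[bad[1L]], ") vs ", res[bad[1L]])
  out <- character(length(aa))
  out[aa == "-"] <- "---"
  out[aa != "-"] <- codons
  paste0(out, collapse = "")
}

#' Sliding-window conservation scores on an amino-acid alignment
#'
#' For every window start the score is the mean, over window columns, of the
#' modal-residue frequency among non-gap rows.  Windows containing any column
#' whose gap fraction exceeds `max_gap_fraction` are flagged ineligible.
#'
#' @param og an [orthogroup_alignment()].
#' @param params a [design_params()].
#' @return tibble with columns `start`, `end` (AA columns, 1-based closed),
#'   `score` and `eligible`; zero rows (with a warning) when the window is
#'   longer than the alignment.
#' @export
score_conservation <- function(og, params = design_params()) {
  if (length(og$taxa) < 2L) stop("need at least 2 taxa to score conservation")
  m <- seqs_to_matrix(og$aa_rows)
  L <- ncol(m); w <- params$window_len_aa
  if (w > L) {
    warning("window (", w, " aa) longer than alignment (", L, " aa)")
    return(tibble::tibble(start = integer(0), end = integer(0),
                          score = numeric(0), eligible = logical(0)))
  }
  n <- nrow(m)
  gap_frac <- colSums(m == "-") / n
  col_score <- vapply(seq_len(L), function(j) {
    col <- m[, j]; col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(tabulate(factor(col))) / length(col)
  }, numeric(1))
  cs <- c(0, cumsum(col_score))
  bad <- c(0, cumsum(gap_frac > params$max_gap_fraction))
  starts <- seq_len(L - w + 1L)
  tibble::tibble(
    start = starts,
    end = starts + w - 1L,
    score = (cs[starts + w] - cs[starts]) / w,
    eligible = (bad[starts + w] - bad[starts]) == 0
  )
}

#' Excise conserved target regions from the nucleotide alignment
#'
#' Eligible windows scoring at least `conservation_threshold` are merged when
#' overlapping or adjacent, AA intervals are converted to NT intervals (x3),
#' and regions shorter than `min_target_len_nt` are dropped.
#'
#' @param og an [orthogroup_alignment()].
#' @param scores output of [score_conservation()] on the same orthogroup.
#' @param params a [design_params()].
#' @return list of `target_region` objects (possibly empty), non-overlapping
#'   and sorted by position.  Each carries the AA and NT spans (1-based
#'   closed), the gapped NT sub-alignment and per-taxon ungapped sequences.
#' @export
excise_targets <- function(og, scores, params = design_params()) {
  pass <- scores$eligible & scores$score >= params$conservation_threshold
  if (!any(pass)) return(list())
  iv <- merge_intervals(cbind(scores$start[pass], scores$end[pass]))
  out <- list()
  for (i in seq_len(nrow(iv))) {
    aa_start <- iv[i, 1L]; aa_end <- iv[i, 2L]
    nt_start <- 3L * (aa_start - 1L) + 1L; nt_end <- 3L * aa_end
    if (nt_end - nt_start + 1L < params$min_target_len_nt) next
    gapped <- substring(og$nt_rows, nt_start, nt_end)
    names(gapped) <- names(og$nt_rows)
    out[[length(out) + 1L]] <- structure(
      list(ortholog_id = og$ortholog_id,
           aa_start = aa_start, aa_end = aa_end,
           nt_start = nt_start, nt_end = nt_end,
           gapped_nt = gapped,
           seqs = setNames(ungap(gapped), names(gapped)),
           represented_taxa = NULL),
      class = "target_region")
  }
  out
}

#' Select target regions by reference-taxon representation
#'
#' A taxon represents a region when its non-gap fraction within the region's
#' NT span is at least `representation_min_nongap`; regions represented in at
#' least `min_ref_taxa` taxa are kept and record their represented taxa.
#'
#' @param regions list of `target_region` objects from [excise_targets()].
#' @param params a [design_params()].
#' @return the kept regions, each with `represented_taxa` filled in.
#' @export
select_targets <- function(regions, params = design_params()) {
  kept <- list()
  for (r in regions) {
    width <- r$nt_end - r$nt_start + 1L
    nongap <- nchar(r$seqs) / width
    rep_tx <- names(nongap)[nongap >= params$representation_min_nongap]
    if (length(rep_tx) >= params$min_ref_taxa) {
      r$represented_taxa <- rep_tx
      kept[[length(kept) + 1L]] <- r
    }
  }
  kept
}

#' Tile baits across a target region
#'
#' For each represented taxon's ungapped span sequence of length `L`, baits of
#' `bait_len` nt are placed at starts `1, 1 + step, 1 + 2 step, ...` with
#' `step = round(bait_len / tiling_factor)` (87 nt for the 100-nt / 1.15X
#' defaults); when the last bait does not end at `L` one extra right-aligned
#' bait is added, so every position is covered.  Duplicate bait sequences are
#' removed across taxa.
#'
#' @param region a selected `target_region` (from [select_targets()]).
#' @param params a [design_params()].
#' @return an object of class `bait_set`: tibble of baits (`taxon`, `start`,
#'   `sequence`), the tiling step, and the source region.
#' @export
tile_baits <- function(region, params = design_params()) {
  if (is.null(region$represented_taxa))
    stop("region has no represented_taxa; run select_targets() first")
  step <- as.integer(round(params$bait_len / params$tiling_factor))
  bl <- params$bait_len
  rows <- list()
  for (tx in region$represented_taxa) {
    s <- region$seqs[[tx]]
    L <- nchar(s)
    if (L < bl) {
      warning("taxon '", tx, "' span (", L, " nt) shorter than bait length in ",
              region$ortholog_id, "; skipped")
      next
    }
    starts <- seq.int(1L, L - bl + 1L, by = step)
    if (starts[length(starts)] + bl - 1L < L) starts <- c(starts, L - bl + 1L)
    rows[[tx]] <- tibble::tibble(taxon = tx, start = starts,
                                 sequence = substring(s, starts, starts + bl - 1L))
  }
  baits <- do.call(rbind, unname(rows)) %||%
    tibble::tibble(taxon = character(0), start = integer(0), sequence = character(0))
  baits <- baits[!duplicated(baits$sequence), , drop = FALSE]
  structure(list(region = region, baits = baits, step_nt = step, bait_len = bl),
            class = "bait_set")
}

#' Run the full bait design for one orthogroup
#'
#' Convenience wrapper: [score_conservation()] then [excise_targets()],
#' [select_targets()] and [tile_baits()].
#'
#' @param og an [orthogroup_alignment()].
#' @param params a [design_params()].
#' @return list with `regions` (selected target regions) and `bait_sets`
#'   (one per region).
#' @export
design_baits <- function(og, params = design_params()) {
  sc <- score_conservation(og, params)
  regions <- select_targets(excise_targets(og, sc, params), params)
  list(regions = regions, bait_sets = lapply(regions, tile_baits, params = params))
}

#' Export target regions and baits
#'
#' Targets are written as FASTA with headers `orthologID|taxon|start-end`
#' (NT alignment coordinates, 1-based inclusive) plus a TSV table; baits as a
#' multi-FASTA with headers `orthologID|taxon|offset`.
#'
#' @param regions list of selected `target_region` objects.
#' @param bait_sets list of `bait_set` objects (parallel to `regions`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design <- function(regions, bait_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tseqs <- character(0); tmeta <- list()
  for (r in regions) {
    for (tx in r$represented_taxa) {
      tseqs[[paste0(r$ortholog_id, "|", tx, "|", r$nt_start, "-", r$nt_end)]] <-
        r$seqs[[tx]]
    }
    tmeta[[length(tmeta) + 1L]] <- tibble::tibble(
      ortholog = r$ortholog_id, aa_start = r$aa_start, aa_end = r$aa_end,
      nt_start = r$nt_start, nt_end = r$nt_end,
      n_taxa = length(r$represented_taxa),
      taxa = paste(r$represented_taxa, collapse = ","))
  }
  write_fasta(tseqs, file.path(dir, "targets.fasta"))
  write_tsv_plain(do.call(rbind, tmeta) %||%
                    tibble::tibble(ortholog = character(0)),
                  file.path(dir, "targets.tsv"))
  bseqs <- character(0)
  for (bs in bait_sets) {
    ids <- paste0(bs$region$ortholog_id, "|", bs$baits$taxon, "|", bs$baits$start)
    bseqs[ids] <- bs$baits$sequence
  }
  write_fasta(bseqs, file.path(dir, "baits.fasta"))
  invisible(dir)
}
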