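#' Locus QC parameters
#'
#' @param min_seq_len minimum number of unambiguous bases (`A/C/G/T`) a row
#'   must keep to survive; the default 9 implements the "shorter than 9 bp
#'   after trimming" removal rule.
#' @param outlier_max_divergence rows whose translated probe region has
#'   identity to the AA consensus below this value are removed as
#'   contaminants/misalignments.
#' @param flank_consensus_window window, in codons, for the consensus-
#'   agreement flank trigger.
#' @param flank_consensus_floor a window with mean AA agreement to the column
#'   consensus below this value demarcates a flank.
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_seq_len = 9L, outlier_max_divergence = 0.5,
                      flank_consensus_window = 10L,
                      flank_consensus_floor = 0.5) {
  stopifnot(min_seq_len >= 1, flank_consensus_window >= 1)
  structure(list(min_seq_len = as.integer(min_seq_len),
                 outlier_max_divergence = outlier_max_divergence,
                 flank_consensus_window = as.integer(flank_consensus_window),
                 flank_consensus_floor = flank_consensus_floor),
            class = "qc_params")
}

#' Aligned locus with optional probe-matching core
#'
#' @param locus_id locus identifier.
#' @param rows named character vector of gapped NT sequences (equal lengths,
#'   alphabet `A/C/G/T/N/-`).
#' @param core optional 1-based closed column interval `c(start, end)` of the
#'   probe-matching core (the region matched to the target during capture);
#'   defaults to the full alignment.
#' @param ref_aa optional reference amino-acid profile for the target region,
#'   used only to break reading-frame ties.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, rows, core = NULL, ref_aa = NULL) {
  rows <- toupper(rows)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be uniquely named by taxon")
  if (length(unique(nchar(rows))) > 1L)
    stop("rows of '", locus_id, "' have unequal lengths")
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad))
    stop("rows of '", locus_id, "' contain symbols outside A/C/G/T/N/-: ",
         paste(names(rows)[bad], collapse = ", "))
  width <- nchar(rows[[1L]])
  if (is.null(core)) core <- c(1L, width)
  stopifnot(length(core) == 2L, core[1L] >= 1L, core[2L] <= width,
            core[1L] <= core[2L])
  structure(list(locus_id = locus_id, rows = rows, width = width,
                 core = as.integer(core), ref_aa = ref_aa),
            class = "locus_alignment")
}

# codon start columns of frame `f` (0/1/2) intersected with [from, to]
codon_starts <- function(f, from, to, width) {
  s <- seq.int(f + 1L, width, by = 3L)
  s[s >= from & s + 2L <= to]
}

# per-row stop counts within [from, to] for one frame; codons containing a
# gap or N are not counted
frame_stop_counts <- function(rows, f, from, to) {
  width <- nchar(rows[[1L]])
  starts <- codon_starts(f, from, to, width)
  vapply(rows, function(r) {
    if (length(starts) == 0L) return(0L)
    sum(substring(r, starts, starts + 2L) %in% STOP_CODONS)
  }, integer(1))
}

#' Infer the reading frame of a locus alignment
#'
#' The frame offset (0, 1 or 2: codons begin at alignment column
#' `offset + 1`) is chosen to minimise in-frame stop codons summed over rows
#' within the probe-matching core.  Ties are broken by maximal agreement with
#' the reference AA profile (when available), then by the smallest offset.
#' When every row contains a stop in all three frames, the locus is flagged
#' unresolvable (routed to manual inspection).
#'
#' @param locus a [locus_alignment()].
#' @return list with `frame` (integer offset or `NA` if unresolvable),
#'   `unresolvable`, and `stop_counts` (total stops per frame).
#' @export
infer_reading_frame <- function(locus) {
  if (!any(n_unambiguous(locus$rows) >= 30L))
    stop("locus '", locus$locus_id,
         "' has no row with >= 30 unambiguous bases")
  per_row <- vapply(0:2, function(f)
    frame_stop_counts(locus$rows, f, locus$core[1L], locus$core[2L]),
    integer(length(locus$rows)))
  per_row <- matrix(per_row, ncol = 3L)
  totals <- as.integer(colSums(per_row))
  if (all(apply(per_row >= 1L, 1L, all)))
    return(list(frame = NA_integer_, unresolvable = TRUE,
                stop_counts = totals))
  best <- which(totals == min(totals)) - 1L
  if (length(best) > 1L && !is.null(locus$ref_aa)) {
    agree <- vapply(best, function(f) {
      aa <- vapply(locus$rows, function(r) {
        starts <- codon_starts(f, locus$core[1L], locus$core[2L], locus$width)
        paste0(translate_codons(substring(r, starts, starts + 2L)),
               collapse = "")
      }, character(1))
      ref <- str_chars(locus$ref_aa)
      mean(vapply(aa, function(a) {
        ac <- str_chars(a); n <- min(length(ac), length(ref))
        if (n == 0L) return(0)
        mean(ac[seq_len(n)] == ref[seq_len(n)])
      }, numeric(1)))
    }, numeric(1))
    best <- best[order(-agree, best)]
  }
  list(frame = best[1L], unresolvable = FALSE, stop_counts = totals)
}

# per-codon consensus agreement for the whole alignment in frame f:
# returns tibble(start, agreement) with NA agreement where < 2 informative rows
codon_agreement <- function(rows, f) {
  width <- nchar(rows[[1L]])
  starts <- codon_starts(f, 1L, width, width)
  aam <- vapply(rows, function(r)
    translate_codons(substring(r, starts, starts + 2L)),
    character(length(starts)))
  aam <- matrix(aam, nrow = length(starts))
  agreement <- vapply(seq_along(starts), function(i) {
    aa <- aam[i, ]
    aa <- aa[!(aa %in% c("-", "X", "?"))]
    if (length(aa) == 0L) return(NA_real_)
    tab <- table(aa)
    cons <- names(tab)[which.max(tab)]   # ties: alphabetical (table order)
    mean(aa == cons)
  }, numeric(1))
  tibble::tibble(start = starts, agreement = agreement)
}

#' Detect non-coding flank boundaries
#'
#' Scanning outward from the probe-matching core, a boundary is placed at the
#' innermost column where any of the following demarcations occurs: (a) an
#' in-frame stop codon in at least one row; (b) a gap run whose length is not
#' divisible by 3; (c) a `flank_consensus_window`-codon window whose mean AA
#' agreement with the column consensus falls below `flank_consensus_floor`.
#' Columns outside the boundaries are flank; when no demarcation exists the
#' flanks are empty.
#'
#' @param locus a [locus_alignment()].
#' @param frame resolved frame offset (0/1/2), e.g. from
#'   [infer_reading_frame()].
#' @param params a [qc_params()].
#' @return list with `probe_start`, `probe_end` (1-based closed columns of
#'   the probe region) and a `triggers` tibble (`side`, `kind`, `col`).
#' @export
detect_flanks <- function(locus, frame, params = qc_params()) {
  stopifnot(frame %in% 0:2)
  width <- locus$width
  core <- locus$core
  trig <- list()
  add <- function(side, kind, col)
    trig[[length(trig) + 1L]] <<- tibble::tibble(side = side, kind = kind,
                                                 col = as.integer(col))
  # (a) in-frame stop codons outside the core
  for (side in c("left", "right")) {
    rng <- if (side == "left") c(1L, core[1L] - 1L) else c(core[2L] + 1L, width)
    if (rng[1L] > rng[2L]) next
    starts <- codon_starts(frame, rng[1L], rng[2L], width)
    for (s in starts) {
      if (any(substring(locus$rows, s, s + 2L) %in% STOP_CODONS))
        add(side, "stop", if (side == "left") s + 2L else s)
    }
  }
  # (b) gap runs with length %% 3 != 0, lying outside the core
  for (tx in names(locus$rows)) {
    runs <- char_runs(str_chars(locus$rows[[tx]]))
    runs <- runs[runs$length %% 3L != 0L, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      if (runs$end[i] < core[1L]) add("left", "gap", runs$end[i])
      else if (runs$start[i] > core[2L]) add("right", "gap", runs$start[i])
    }
  }
  # (c) low-consensus windows of whole codons outside the core
  ca <- codon_agreement(locus$rows, frame)
  w <- params$flank_consensus_window
  cod_left <- ca[ca$start + 2L < core[1L], , drop = FALSE]
  cod_right <- ca[ca$start > core[2L], , drop = FALSE]
  scan_windows <- function(cod, side) {
    n <- nrow(cod)
    if (n < w) return()
    for (i in seq_len(n - w + 1L)) {
      a <- cod$agreement[i:(i + w - 1L)]
      if (all(is.na(a))) next
      if (mean(a, na.rm = TRUE) < params$flank_consensus_floor) {
        if (side == "left") add(side, "consensus", cod$start[i + w - 1L] + 2L)
        else add(side, "consensus", cod$start[i])
      }
    }
  }
  scan_windows(cod_left, "left")
  scan_windows(cod_right, "right")
  triggers <- do.call(rbind, trig) %||%
    tibble::tibble(side = character(0), kind = character(0), col = integer(0))
  lb <- triggers$col[triggers$side == "left"]
  rb <- triggers$col[triggers$side == "right"]
  list(probe_start = if (length(lb) > 0L) max(lb) + 1L else 1L,
       probe_end = if (length(rb) > 0L) min(rb) - 1L else width,
       triggers = triggers)
}

#' Split a locus into left flank, codon-aligned probe region and right flank
#'
#' The probe region is trimmed so that its first column is codon position
#' one in the resolved frame (1-2 leading columns are moved to the left
#' flank when needed) and its length is a multiple of 3 (trailing remainder
#' moved to the right flank).
#'
#' @param locus a [locus_alignment()].
#' @param frame resolved frame offset (0/1/2).
#' @param boundaries output of [detect_flanks()].
#' @return an object of class `split_locus` (fields `locus_id`, `taxa`,
#'   `left_flank`, `probe`, `right_flank`, `frame`, `probe_span`, `masks`),
#'   or `NULL` with a warning when the probe region is shorter than one
#'   codon.
#' @export
split_locus <- function(locus, frame, boundaries) {
  ps <- boundaries$probe_start; pe <- boundaries$probe_end
  shift <- (3L - ((ps - (frame + 1L)) %% 3L)) %% 3L
  ps2 <- ps + shift
  n_codons <- max(0L, (pe - ps2 + 1L) %/% 3L)
  if (n_codons < 1L) {
    warning("locus '", locus$locus_id,
            "' probe region shorter than one codon; dropped")
    return(NULL)
  }
  pe2 <- ps2 + 3L * n_codons - 1L
  structure(list(
    locus_id = locus$locus_id,
    taxa = names(locus$rows),
    left_flank = substring(locus$rows, 1L, ps2 - 1L) |>
      setNames(names(locus$rows)),
    probe = substring(locus$rows, ps2, pe2) |> setNames(names(locus$rows)),
    right_flank = substring(locus$rows, pe2 + 1L, locus$width) |>
      setNames(names(locus$rows)),
    frame = as.integer(frame),
    probe_span = c(ps2, pe2),
    masks = NULL), class = "split_locus")
}

#' Mask frameshifted stretches in the probe region
#'
#' Within each row, a gap run whose length is not divisible by 3 breaks the
#' reading frame; that run and everything downstream of it in the row is
#' replaced by `N`, up to the end of the next compensating gap run that
#' restores the frame (cumulative shift divisible by 3) or, failing that, to
#' the end of the probe region.  In-frame gap runs are untouched and other
#' rows are unaffected.  Alignment dimensions never change.
#'
#' @param split a `split_locus` from [split_locus()].
#' @return the `split_locus` with masked probe rows and per-row mask
#'   intervals recorded in `$masks`.
#' @export
mask_frameshifts <- function(split) {
  masks <- list()
  probe <- split$probe
  for (tx in names(probe)) {
    chars <- str_chars(probe[[tx]])
    runs <- char_runs(chars)
    iv <- list()
    open_at <- NA_integer_; pending <- 0L
    for (i in seq_len(nrow(runs))) {
      if (is.na(open_at)) {
        if (runs$length[i] %% 3L != 0L) {
          open_at <- runs$start[i]
          pending <- runs$length[i] %% 3L
        }
      } else {
        pending <- (pending + runs$length[i]) %% 3L
        if (pending == 0L) {
          iv[[length(iv) + 1L]] <- c(open_at, runs$end[i])
          open_at <- NA_integer_
        }
      }
    }
    if (!is.na(open_at)) iv[[length(iv) + 1L]] <- c(open_at, length(chars))
    if (length(iv) > 0L) {
      for (r in iv) chars[r[1L]:r[2L]] <- "N"
      probe[[tx]] <- paste0(chars, collapse = "")
      masks[[tx]] <- do.call(rbind, iv)
    }
  }
  split$probe <- probe
  split$masks <- masks
  split
}

# modal AA per probe codon over informative rows; ties alphabetical
probe_consensus_aa <- function(probe) {
  aam <- vapply(probe, function(r) translate_codons(codons_of(r)),
                character(nchar(probe[[1L]]) %/% 3L))
  aam <- matrix(aam, ncol = length(probe), dimnames = list(NULL, names(probe)))
  cons <- apply(aam, 1L, function(aa) {
    aa <- aa[!(aa %in% c("-", "X", "?"))]
    if (length(aa) == 0L) return(NA_character_)
    tab <- table(aa)
    names(tab)[which.max(tab)]
  })
  list(consensus = cons, aa_matrix = aam)
}

#' Drop very short rows and consensus outliers
#'
#' Rows with fewer than `min_seq_len` unambiguous bases (across flanks and
#' probe region) are removed; rows whose translated probe region agrees with
#' the AA consensus on less than `outlier_max_divergence` of comparable
#' positions are removed as contaminants.
#'
#' @param split a `split_locus`.
#' @param params a [qc_params()].
#' @return list with `split` (surviving rows; `NULL` when none survive) and
#'   `report` (tibble: taxon, reason, value).
#' @export
drop_short_and_outliers <- function(split, params = qc_params()) {
  full <- paste0(split$left_flank, split$probe, split$right_flank)
  names(full) <- split$taxa
  nu <- n_unambiguous(full)
  report <- list()
  short <- names(nu)[nu < params$min_seq_len]
  for (tx in short)
    report[[length(report) + 1L]] <- tibble::tibble(
      taxon = tx, reason = "short", value = as.numeric(nu[[tx]]))
  keep <- setdiff(split$taxa, short)
  if (length(keep) > 0L) {
    pc <- probe_consensus_aa(split$probe[keep])
    ident <- vapply(keep, function(tx) {
      aa <- pc$aa_matrix[, tx]
      ok <- !is.na(pc$consensus) & !(aa %in% c("-", "X", "?"))
      if (!any(ok)) return(NA_real_)
      mean(aa[ok] == pc$consensus[ok])
    }, numeric(1))
    out <- keep[!is.na(ident) & ident < params$outlier_max_divergence]
    for (tx in out)
      report[[length(report) + 1L]] <- tibble::tibble(
        taxon = tx, reason = "outlier", value = ident[[tx]])
    keep <- setdiff(keep, out)
  }
  report <- do.call(rbind, report) %||%
    tibble::tibble(taxon = character(0), reason = character(0),
                   value = numeric(0))
  if (length(keep) == 0L) return(list(split = NULL, report = report))
  split$taxa <- keep
  split$left_flank <- split$left_flank[keep]
  split$probe <- split$probe[keep]
  split$right_flank <- split$right_flank[keep]
  split$masks <- split$masks[intersect(names(split$masks %||% list()), keep)]
  list(split = split, report = report)
}

#' Run the full locus QC pipeline
#'
#' [infer_reading_frame()], [detect_flanks()], [split_locus()],
#' [mask_frameshifts()] and [drop_short_and_outliers()] in sequence.
#'
#' @param locus a [locus_alignment()].
#' @param params a [qc_params()].
#' @return list with `split` (a QC'd `split_locus`, or `NULL` when the locus
#'   is dropped), `frame` (the frame inference), `boundaries` and `report`.
#' @export
qc_locus <- function(locus, params = qc_params()) {
  fr <- infer_reading_frame(locus)
  if (fr$unresolvable)
    return(list(split = NULL, frame = fr, boundaries = NULL,
                report = tibble::tibble(taxon = NA_character_,
                                        reason = "unresolvable_frame",
                                        value = NA_real_)))
  bounds <- detect_flanks(locus, fr$frame, params)
  sp <- split_locus(locus, fr$frame, bounds)
  if (is.null(sp))
    return(list(split = NULL, frame = fr, boundaries = bounds,
                report = tibble::tibble(taxon = NA_character_,
                                        reason = "probe_too_short",
                                        value = NA_real_)))
  sp <- mask_frameshifts(sp)
  res <- drop_short_and_outliers(sp, params)
  list(split = res$split, frame = fr, boundaries = bounds,
       report = res$report)
}

#' Reassemble a split locus into a plain locus alignment
#'
#' Concatenates left flank, probe region and right flank (restoring the
#' original column span) and records the probe span as the new core.  Useful
#' for idempotence checks and for re-running QC on edited loci.
#'
#' @param split a `split_locus`.
#' @return a [locus_alignment()].
#' @export
unsplit_locus <- function(split) {
  rows <- paste0(split$left_flank, split$probe, split$right_flank)
  names(rows) <- split$taxa
  locus_alignment(split$locus_id, rows, core = split$probe_span)
}
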