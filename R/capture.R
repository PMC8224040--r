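#' Capture-matching parameters
#'
#' Identity/coverage thresholds and local-alignment scoring used when matching
#' assembled contigs to bait targets.  The 0.80 identity / 0.82 coverage
#' defaults are the Phyluce matching defaults used for contaminant exclusion.
#'
#' @param min_identity minimum fraction of identical aligned columns.
#' @param min_coverage minimum fraction of the target covered by the local
#'   alignment.
#' @param seed_len length of the exact shared k-mer required before any
#'   alignment is attempted.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext gap penalties (negative; a gap of length L scores
#'   `gap_open + L * gap_ext`).
#' @return an object of class `capture_params`.
#' @export
capture_params <- function(min_identity = 0.80, min_coverage = 0.82,
                           seed_len = 15L, match = 1, mismatch = -1,
                           gap_open = -2, gap_ext = -1) {
  stopifnot(min_identity > 0, min_identity <= 1, min_coverage > 0,
            min_coverage <= 1, seed_len >= 1, gap_open <= 0, gap_ext <= 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 seed_len = as.integer(seed_len), match = match,
                 mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext),
            class = "capture_params")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

capture_submat <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- params$match
  m
}

#' Local alignment of a contig against a target
#'
#' A hit is only attempted when query and subject share at least one exact
#' k-mer of `seed_len` (otherwise `NULL` is returned); the alignment itself is
#' an optimal local alignment with affine gaps under the scoring in
#' `params`.  Identity is the fraction of identical columns over all aligned
#' columns (gap columns included); coverage is the fraction of the subject
#' spanned by the alignment.
#'
#' @param query contig sequence.
#' @param subject target sequence.
#' @param params a [capture_params()].
#' @return a `capture_hit` (list with `identity`, `coverage`, `score`,
#'   `query_span`, `subject_span`) or `NULL` when no seed exists.
#' @export
align_local <- function(query, subject, params = capture_params()) {
  query <- toupper(query); subject <- toupper(subject)
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  if (length(intersect(kmer_set(query, params$seed_len),
                       kmer_set(subject, params$seed_len))) == 0L)
    return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = capture_submat(params),
    gapOpening = -params$gap_open, gapExtension = -params$gap_ext)
  ap <- str_chars(as.character(Biostrings::alignedPattern(pa)))
  as_ <- str_chars(as.character(Biostrings::alignedSubject(pa)))
  ncols <- length(ap)
  matches <- sum(ap == as_ & ap != "-")
  sub_span <- c(Biostrings::start(Biostrings::subject(pa)),
                Biostrings::end(Biostrings::subject(pa)))
  structure(list(
    identity = matches / ncols,
    coverage = (sub_span[2L] - sub_span[1L] + 1L) / nchar(subject),
    score = Biostrings::score(pa),
    query_span = c(Biostrings::start(Biostrings::pattern(pa)),
                   Biostrings::end(Biostrings::pattern(pa))),
    subject_span = sub_span), class = "capture_hit")
}

#' Match assembled contigs to bait targets with ambiguity filters
#'
#' All contig-target pairs sharing a seed are aligned; hits below the
#' identity or coverage thresholds are discarded.  Two ambiguity filters are
#' then applied in order: contigs with passing hits to two or more distinct
#' targets are rejected (`multi_target`); then targets with passing hits from
#' two or more distinct surviving contigs are rejected (`multi_contig`).  The
#' remaining one-to-one pairs are accepted.
#'
#' @param contigs named character vector of contig sequences.
#' @param targets named character vector of target sequences.
#' @param params a [capture_params()].
#' @return an object of class `match_table`: tibbles `accepted` (target,
#'   contig, identity, coverage, length), `rejected_contigs` and
#'   `rejected_targets` (with `reason` codes), and the character vector
#'   `unmatched` of remaining targets.
#' @export
match_contigs <- function(contigs, targets, params = capture_params()) {
  if (anyDuplicated(names(contigs))) stop("duplicate contig ids")
  if (anyDuplicated(names(targets))) stop("duplicate target ids")
  hits <- list()
  for (ci in names(contigs)) {
    for (ti in names(targets)) {
      h <- align_local(contigs[[ci]], targets[[ti]], params)
      if (is.null(h)) next
      if (h$identity >= params$min_identity && h$coverage >= params$min_coverage)
        hits[[length(hits) + 1L]] <- tibble::tibble(
          contig = ci, target = ti, identity = h$identity,
          coverage = h$coverage, score = h$score)
    }
  }
  hits <- do.call(rbind, hits) %||%
    tibble::tibble(contig = character(0), target = character(0),
                   identity = numeric(0), coverage = numeric(0),
                   score = numeric(0))
  multi_target <- unique(hits$contig[ave(as.integer(factor(hits$target)),
                                         hits$contig,
                                         FUN = function(x) length(unique(x))) >= 2L])
  surviving <- hits[!(hits$contig %in% multi_target), , drop = FALSE]
  tgt_contigs <- tapply(surviving$contig, surviving$target,
                        function(x) length(unique(x)))
  multi_contig <- names(tgt_contigs)[tgt_contigs >= 2L]
  ok <- surviving[!(surviving$target %in% multi_contig), , drop = FALSE]
  accepted <- tibble::tibble(
    target = ok$target, contig = ok$contig, identity = ok$identity,
    coverage = ok$coverage,
    length = nchar(ungap(contigs[ok$contig])))
  accepted <- accepted[order(accepted$target), , drop = FALSE]
  unmatched <- setdiff(names(targets), c(accepted$target, multi_contig))
  structure(list(
    accepted = accepted,
    rejected_contigs = tibble::tibble(contig = multi_target,
                                      reason = rep("multi_target",
                                                   length(multi_target))),
    rejected_targets = tibble::tibble(target = multi_contig,
                                      reason = rep("multi_contig",
                                                   length(multi_contig))),
    unmatched = sort(unmatched)), class = "match_table")
}

#' Reconcile per-assembler match tables by longest fragment
#'
#' Across the accepted matches of several assemblers, the contig of maximal
#' ungapped length is retained per target; ties are broken by the
#' lexicographically smallest assembler name.
#'
#' @param per_assembler named list of `match_table` objects, one per
#'   assembler.
#' @return tibble with one row per recovered target: `target`, `assembler`,
#'   `contig`, `length`, sorted by target.
#' @export
reconcile_assemblies <- function(per_assembler) {
  if (length(per_assembler) < 1L) stop("need at least one assembler")
  if (is.null(names(per_assembler)) || any(names(per_assembler) == ""))
    stop("per_assembler must be named by assembler")
  rows <- lapply(names(per_assembler), function(asm) {
    acc <- per_assembler[[asm]]$accepted
    if (nrow(acc) == 0L) return(NULL)
    tibble::tibble(target = acc$target, assembler = asm,
                   contig = acc$contig, length = acc$length)
  })
  all <- do.call(rbind, rows)
  if (is.null(all))
    return(tibble::tibble(target = character(0), assembler = character(0),
                          contig = character(0), length = integer(0)))
  all <- all[order(all$target, -all$length, all$assembler), , drop = FALSE]
  all[!duplicated(all$target), , drop = FALSE]
}

#' Per-sample and per-locus recovery summary
#'
#' @param reconciled named list, one reconciliation tibble
#'   (from [reconcile_assemblies()]) per sample.
#' @return list with `samples` (sample, n_loci, mean_length; sorted by
#'   sample) and `loci` (target, n_samples).
#' @export
recovery_summary <- function(reconciled) {
  samples <- tibble::tibble(
    sample = names(reconciled),
    n_loci = unname(vapply(reconciled, nrow, integer(1))),
    mean_length = unname(vapply(reconciled, function(x)
      if (nrow(x) == 0L) NA_real_ else mean(x$length), numeric(1))))
  samples <- samples[order(samples$sample), , drop = FALSE]
  tgt <- unlist(lapply(reconciled, function(x) unique(x$target)),
                use.names = FALSE)
  loci <- if (length(tgt) == 0L) {
    tibble::tibble(target = character(0), n_samples = integer(0))
  } else {
    tab <- table(tgt)
    tibble::tibble(target = names(tab), n_samples = as.integer(tab))
  }
  list(samples = samples, loci = loci)
}
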