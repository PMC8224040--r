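#' Supermatrix parameters
#'
#' @param completeness_fraction a locus is kept when at least this fraction
#'   of the taxon universe is present (the study's 50% and 75% sets);
#'   rounding is `ceiling` (strict "at least").
#' @param include_flanks append flank blocks after the probe blocks.
#' @param min_partition_len partitions with fewer columns are pruned (the
#'   "smaller than 80 bp" rule).
#' @param missing_symbol fill symbol for taxa absent from a locus; `-` stays
#'   reserved for alignment gaps.
#' @return an object of class `matrix_params`.
#' @export
matrix_params <- function(completeness_fraction = 0.5, include_flanks = FALSE,
                          min_partition_len = 80L, missing_symbol = "?") {
  stopifnot(completeness_fraction > 0, completeness_fraction <= 1,
            nchar(missing_symbol) == 1L, min_partition_len >= 0)
  structure(list(completeness_fraction = completeness_fraction,
                 include_flanks = isTRUE(include_flanks),
                 min_partition_len = as.integer(min_partition_len),
                 missing_symbol = missing_symbol),
            class = "matrix_params")
}

#' Filter loci by taxon completeness
#'
#' A locus is kept iff the number of taxa present (rows surviving QC) is at
#' least `ceiling(completeness_fraction * |universe|)`.
#'
#' @param loci list of `split_locus` objects.
#' @param taxa character vector: the taxon universe.
#' @param params a [matrix_params()].
#' @return the kept loci.
#' @export
filter_by_completeness <- function(loci, taxa, params = matrix_params()) {
  stopifnot(length(taxa) > 0L)
  need <- ceiling(params$completeness_fraction * length(taxa))
  Filter(function(sp) sum(sp$taxa %in% taxa) >= need, loci)
}

#' Concatenate loci into a supermatrix
#'
#' Loci are concatenated in lexicographic locus-id order; taxa absent from a
#' locus are filled with `missing_symbol` across its columns.  Probe blocks
#' come first; when `include_flanks` is set, non-empty flank blocks are
#' appended after all probe blocks (also in locus order, left then right).
#' An exact coordinate map is kept.
#'
#' @param loci list of `split_locus` objects.
#' @param taxa taxon universe; defaults to the union over loci.
#' @param params a [matrix_params()].
#' @return an object of class `supermatrix_bundle`: `taxa`, `seqs` (named
#'   character vector of concatenated rows), `map` (tibble: block, locus,
#'   kind, start, end), `missing_symbol`, `stripped`, `type`.
#' @export
concatenate_loci <- function(loci, taxa = NULL, params = matrix_params()) {
  ids <- vapply(loci, function(x) x$locus_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  loci <- loci[order(ids)]
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(loci, `[[`, "taxa"))))
  for (sp in loci) if (anyDuplicated(sp$taxa))
    stop("duplicate taxon within locus '", sp$locus_id, "'")
  blocks <- list()
  for (sp in loci)
    blocks[[paste0(sp$locus_id, ":probe")]] <-
      list(locus = sp$locus_id, kind = "probe", rows = sp$probe)
  if (params$include_flanks) {
    for (sp in loci) {
      if (nchar(sp$left_flank[[1L]]) > 0L)
        blocks[[paste0(sp$locus_id, ":flank_L")]] <-
          list(locus = sp$locus_id, kind = "flank", rows = sp$left_flank)
      if (nchar(sp$right_flank[[1L]]) > 0L)
        blocks[[paste0(sp$locus_id, ":flank_R")]] <-
          list(locus = sp$locus_id, kind = "flank", rows = sp$right_flank)
    }
  }
  parts <- setNames(rep(list(character(0)), length(taxa)), taxa)
  map <- list(); at <- 1L
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    w <- nchar(b$rows[[1L]])
    fill <- strrep(params$missing_symbol, w)
    for (tx in taxa)
      parts[[tx]] <- c(parts[[tx]], if (tx %in% names(b$rows)) b$rows[[tx]] else fill)
    map[[length(map) + 1L]] <- tibble::tibble(
      block = bn, locus = b$locus, kind = b$kind,
      start = at, end = at + w - 1L)
    at <- at + w
  }
  structure(list(
    taxa = taxa,
    seqs = vapply(parts, paste0, character(1), collapse = ""),
    map = do.call(rbind, map) %||%
      tibble::tibble(block = character(0), locus = character(0),
                     kind = character(0), start = integer(0), end = integer(0)),
    missing_symbol = params$missing_symbol,
    stripped = FALSE, type = "DNA"), class = "supermatrix_bundle")
}

matrix_width <- function(bundle) {
  if (nrow(bundle$map) == 0L) 0L else max(bundle$map$end)
}

#' Define gene-by-codon-position and flank partitions
#'
#' Each probe block yields three stride-3 partitions (`<locus>_pos1..3`,
#' probe blocks start at codon position one); all flank columns, from any
#' number of flank blocks, form the single partition `flanks`.
#'
#' @param bundle a `supermatrix_bundle`.
#' @return tibble of class `partition_set`: `name`, `kind`, `spec` (RAxML
#'   range notation, 1-based inclusive), `ncol` and a `cols` list-column of
#'   column indices.
#' @export
define_partitions <- function(bundle) {
  if (isTRUE(bundle$stripped))
    stop("partitions must be defined before third positions are stripped")
  rows <- list()
  probe <- bundle$map[bundle$map$kind == "probe", , drop = FALSE]
  for (i in seq_len(nrow(probe))) {
    s <- probe$start[i]; e <- probe$end[i]
    if ((e - s + 1L) %% 3L != 0L)
      stop("probe block of locus '", probe$locus[i],
           "' is not divisible by 3")
    for (k in 1:3) {
      cols <- seq.int(s + k - 1L, e, by = 3L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0(probe$locus[i], "_pos", k), kind = "codon",
        spec = sprintf("%d-%d\\3", s + k - 1L, e),
        ncol = length(cols), cols = list(cols))
    }
  }
  flank <- bundle$map[bundle$map$kind == "flank", , drop = FALSE]
  if (nrow(flank) > 0L) {
    cols <- unlist(lapply(seq_len(nrow(flank)),
                          function(i) seq.int(flank$start[i], flank$end[i])))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = "flanks", kind = "flank",
      spec = paste(sprintf("%d-%d", flank$start, flank$end), collapse = ", "),
      ncol = length(cols), cols = list(cols))
  }
  out <- do.call(rbind, rows) %||%
    tibble::tibble(name = character(0), kind = character(0),
                   spec = character(0), ncol = integer(0), cols = list())
  class(out) <- c("partition_set", class(out))
  out
}

#' Prune tiny partitions
#'
#' Partitions with fewer than `min_partition_len` columns (which typically
#' hold a single codon position of one short gene and break downstream ML
#' runs) are removed.
#'
#' @param partitions a `partition_set`.
#' @param params a [matrix_params()].
#' @return list with `kept`, `removed` (both `partition_set`s) and
#'   `removed_columns` (total column count pruned).
#' @export
drop_small_partitions <- function(partitions, params = matrix_params()) {
  small <- partitions$ncol < params$min_partition_len
  list(kept = partitions[!small, , drop = FALSE],
       removed = partitions[small, , drop = FALSE],
       removed_columns = sum(partitions$ncol[small]))
}

# subset bundle columns, renumbering the map
subset_columns <- function(bundle, keep) {
  m <- seqs_to_matrix(bundle$seqs)[, keep, drop = FALSE]
  old2new <- integer(matrix_width(bundle)); old2new[keep] <- seq_along(keep)
  map <- bundle$map
  new_map <- list()
  for (i in seq_len(nrow(map))) {
    cols <- old2new[seq.int(map$start[i], map$end[i])]
    cols <- cols[cols > 0L]
    if (length(cols) == 0L) next
    new_map[[length(new_map) + 1L]] <- tibble::tibble(
      block = map$block[i], locus = map$locus[i], kind = map$kind[i],
      start = min(cols), end = max(cols))
  }
  bundle$seqs <- matrix_to_seqs(m)
  bundle$map <- do.call(rbind, new_map)
  bundle
}

#' Strip third codon positions from probe blocks
#'
#' Every third-position column of every probe block is deleted (flank columns
#' are untouched) and the coordinate map updated.  The resulting bundle no
#' longer has codon structure, so [translate_matrix()] refuses it.
#'
#' @param bundle a `supermatrix_bundle`.
#' @return the stripped bundle (probe width exactly 2/3 of the original).
#' @export
strip_third_positions <- function(bundle) {
  if (isTRUE(bundle$stripped)) stop("bundle already stripped")
  drop <- integer(0)
  probe <- bundle$map[bundle$map$kind == "probe", , drop = FALSE]
  for (i in seq_len(nrow(probe))) {
    if ((probe$end[i] - probe$start[i] + 1L) %% 3L != 0L)
      stop("probe block of locus '", probe$locus[i],
           "' is not divisible by 3")
    drop <- c(drop, seq.int(probe$start[i] + 2L, probe$end[i], by = 3L))
  }
  out <- subset_columns(bundle, setdiff(seq_len(matrix_width(bundle)), drop))
  out$stripped <- TRUE
  out
}

#' Translate the probe blocks to amino acids
#'
#' Probe blocks are translated under the standard genetic code; codons
#' containing `N` become `X`, codons containing a gap become `-`, all-missing
#' codons stay `?`.  Flank blocks (non-coding) are excluded, matching the
#' convention that amino-acid matrices carry no flanking data.
#'
#' @param bundle an unstripped `supermatrix_bundle`.
#' @return a new `supermatrix_bundle` of `type = "AA"` with probe blocks
#'   only and an AA-coordinate map.
#' @export
translate_matrix <- function(bundle) {
  if (isTRUE(bundle$stripped))
    stop("cannot translate a matrix with third positions stripped; ",
         "translate before stripping")
  probe <- bundle$map[bundle$map$kind == "probe", , drop = FALSE]
  parts <- setNames(rep(list(character(0)), length(bundle$taxa)), bundle$taxa)
  map <- list(); at <- 1L
  for (i in seq_len(nrow(probe))) {
    s <- probe$start[i]; e <- probe$end[i]
    if ((e - s + 1L) %% 3L != 0L)
      stop("probe block of locus '", probe$locus[i],
           "' is not divisible by 3")
    for (tx in bundle$taxa) {
      block <- substring(bundle$seqs[[tx]], s, e)
      parts[[tx]] <- c(parts[[tx]], translate_nt(block))
    }
    w <- (e - s + 1L) %/% 3L
    map[[length(map) + 1L]] <- tibble::tibble(
      block = probe$block[i], locus = probe$locus[i], kind = "probe",
      start = at, end = at + w - 1L)
    at <- at + w
  }
  structure(list(
    taxa = bundle$taxa,
    seqs = vapply(parts, paste0, character(1), collapse = ""),
    map = do.call(rbind, map),
    missing_symbol = bundle$missing_symbol,
    stripped = FALSE, type = "AA"), class = "supermatrix_bundle")
}

#' Export and import supermatrices
#'
#' `write_supermatrix()` writes relaxed PHYLIP or FASTA; `write_partitions()`
#' writes a RAxML-style partition file (`DNA, locus1_pos1 = 1-300\3`, 1-based
#' inclusive); `write_coordinate_map()` writes the block map as TSV.
#' `read_supermatrix()`, `read_partitions()` and `import_bundle()` invert
#' them; `import_bundle(matrix, map)` reproduces the original bundle exactly.
#'
#' @param bundle a `supermatrix_bundle`.
#' @param path output (or input) file path.
#' @param format `"phylip"` or `"fasta"`.
#' @return paths invisibly for writers; for readers, the parsed object.
#' @export
write_supermatrix <- function(bundle, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") return(write_fasta(bundle$seqs, path))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(length(bundle$taxa), matrix_width(bundle)), con)
  writeLines(paste(names(bundle$seqs), bundle$seqs, sep = "  "), con)
  invisible(path)
}

#' @rdname write_supermatrix
#' @export
read_supermatrix <- function(path) {
  lines <- readLines(path)
  if (startsWith(lines[1L], ">")) return(read_fasta(path))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines[-1L], "[ \t]+")
  setNames(vapply(fields, `[[`, character(1), 2L),
           vapply(fields, `[[`, character(1), 1L))
}

#' @rdname write_supermatrix
#' @param partitions a `partition_set` tibble.
#' @param type model prefix written before each partition (e.g. `DNA`,
#'   `WAG`).
#' @export
write_partitions <- function(partitions, path, type = "DNA") {
  writeLines(sprintf("%s, %s = %s", type, partitions$name, partitions$spec),
             path)
  invisible(path)
}

#' @rdname write_supermatrix
#' @param width total matrix width, needed to expand open-ended strides.
#' @export
read_partitions <- function(path, width) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed partition line: ", ln)
    name <- m[2L]
    cols <- integer(0)
    for (piece in strsplit(m[3L], ",")[[1L]]) {
      pm <- regmatches(piece,
                       regexec("^\\s*(\\d+)-(\\d+)(\\\\(\\d+))?\\s*$", piece))[[1L]]
      if (length(pm) == 0L) stop("malformed partition range: ", piece)
      by <- if (pm[5L] == "") 1L else as.integer(pm[5L])
      cols <- c(cols, seq.int(as.integer(pm[2L]), as.integer(pm[3L]), by = by))
    }
    tibble::tibble(name = name, spec = trimws(m[3L]), ncol = length(cols),
                   cols = list(cols))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition_set", class(out))
  out
}

#' @rdname write_supermatrix
#' @export
write_coordinate_map <- function(bundle, path) {
  write_tsv_plain(bundle$map, path)
}

#' @rdname write_supermatrix
#' @param matrix_path,map_path files written by `write_supermatrix()` and
#'   `write_coordinate_map()`.
#' @param missing_symbol,stripped,type bundle metadata to restore.
#' @export
import_bundle <- function(matrix_path, map_path, missing_symbol = "?",
                          stripped = FALSE, type = "DNA") {
  seqs <- read_supermatrix(matrix_path)
  map <- tibble::as_tibble(read.table(map_path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
  map$start <- as.integer(map$start); map$end <- as.integer(map$end)
  structure(list(taxa = names(seqs), seqs = seqs, map = map,
                 missing_symbol = missing_symbol, stripped = stripped,
                 type = type), class = "supermatrix_bundle")
}
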