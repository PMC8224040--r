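#' @keywords internal
"_PACKAGE"

#' @importFrom stats optimize setNames
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# split one string into a character vector of single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# named character vector of equal-length strings -> character matrix (rows = taxa)
seqs_to_matrix <- function(rows) {
  w <- nchar(rows)
  if (length(unique(w)) > 1L)
    stop("sequences have unequal lengths (", paste(unique(w), collapse = ", "), ")")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

matrix_to_seqs <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(m)
  out
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

n_unambiguous <- function(x) {
  vapply(x, function(s) sum(str_chars(s) %in% c("A", "C", "G", "T")), integer(1))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# cut a sequence into consecutive codons from position `from`; trailing partial
# codon dropped
codons_of <- function(seq, from = 1L) {
  n <- nchar(seq)
  starts <- seq.int(from, by = 3L, length.out = max(0L, (n - from + 1L) %/% 3L))
  if (length(starts) == 0L) return(character(0))
  substring(seq, starts, starts + 2L)
}

# translate a vector of codon strings; "???" -> "?", codon containing "-" -> "-",
# other non-standard codons (N etc.) -> "X", stops -> "*"
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- rep("X", length(codons))
  out[grepl("-", codons, fixed = TRUE)] <- "-"
  out[codons == "???"] <- "?"
  known <- codons %in% names(gc)
  out[known] <- unname(gc[codons[known]])
  out
}

translate_nt <- function(seq, from = 1L) {
  paste0(translate_codons(codons_of(seq, from)), collapse = "")
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that upper-cases the
#' sequences.  Gap (`-`), ambiguity (`N`) and missing (`?`) symbols are kept
#' verbatim, so the same reader serves alignments and unaligned sequence sets.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

# merge 1-based closed intervals that overlap or are adjacent;
# `iv` is a 2-column matrix (start, end), assumed start <= end
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L] + 1L) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

# maximal runs of `ch` in a character vector; tibble(start, end, length)
char_runs <- function(chars, ch = "-") {
  r <- rle(chars == ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
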