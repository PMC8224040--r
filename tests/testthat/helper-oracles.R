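# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

sense_codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

rand_cds <- function(n_codons)
  paste0(sample(sense_codons, n_codons, replace = TRUE), collapse = "")

# mutate `n_sub` interior positions (never the first/last `anchor` bases) to a
# different base, so the optimal local alignment is the full-span diagonal and
# its identity is exactly 1 - n_sub / nchar(seq); the default anchor also
# guarantees a shared 15-mer seed
mutate_interior <- function(seq, n_sub, anchor = 16L) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample((anchor + 1L):(length(chars) - anchor), n_sub)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste0(chars, collapse = "")
}

# Full Smith-Waterman with affine gaps and traceback, written independently of
# the package (plain dynamic programming).  A gap of length L costs
# go + L * ge, matching the package's scoring convention.
sw_oracle <- function(query, subject, match = 1, mismatch = -1,
                      go = 2, ge = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in query (consumes subject)
  F_ <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consumes query)
  ptr <- matrix(0L, n + 1, m + 1)   # 0 stop, 1 diag, 2 E, 3 F
  Eopen <- matrix(FALSE, n + 1, m + 1)
  Fopen <- matrix(FALSE, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      e_open <- H[i, j - 1] - go - ge
      e_ext <- E[i, j - 1] - ge
      E[i, j] <- max(e_open, e_ext)
      Eopen[i, j] <- e_open >= e_ext
      f_open <- H[i - 1, j] - go - ge
      f_ext <- F_[i - 1, j] - ge
      F_[i, j] <- max(f_open, f_ext)
      Fopen[i, j] <- f_open >= f_ext
      d <- H[i - 1, j - 1] + if (q[i - 1] == s[j - 1]) match else mismatch
      h <- max(0, d, E[i, j], F_[i, j])
      H[i, j] <- h
      ptr[i, j] <- if (h == 0) 0L else if (h == d) 1L
        else if (h == E[i, j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best == 0) return(NULL)
  i <- bi; j <- bj; state <- "H"
  ncols <- 0L; matches <- 0L; jmin <- bj - 1L; jmax <- bj - 1L
  repeat {
    if (state == "H") {
      p <- ptr[i, j]
      if (p == 0L) break
      if (p == 1L) {
        ncols <- ncols + 1L
        if (q[i - 1] == s[j - 1]) matches <- matches + 1L
        jmin <- j - 1L
        i <- i - 1L; j <- j - 1L
      } else if (p == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      ncols <- ncols + 1L
      jmin <- j - 1L
      if (Eopen[i, j]) state <- "H"
      j <- j - 1L
    } else {
      ncols <- ncols + 1L
      if (Fopen[i, j]) state <- "H"
      i <- i - 1L
    }
  }
  list(score = best, identity = matches / ncols,
       coverage = (jmax - jmin + 1) / m)
}

# brute-force window conservation scores: direct loops, no cumulative sums
brute_window_scores <- function(og, params) {
  m <- do.call(rbind, strsplit(og$aa_rows, ""))
  L <- ncol(m); w <- params$window_len_aa
  t(vapply(seq_len(L - w + 1L), function(s) {
    cols <- s:(s + w - 1L)
    sc <- mean(vapply(cols, function(j) {
      col <- m[, j]; col <- col[col != "-"]
      if (length(col) == 0) return(0)
      max(table(col)) / length(col)
    }, numeric(1)))
    gap_ok <- all(vapply(cols, function(j)
      mean(m[, j] == "-") <= params$max_gap_fraction, logical(1)))
    c(score = sc, eligible = as.numeric(gap_ok))
  }, numeric(2)))
}

# brute-force in-frame stop counter on a locus alignment
brute_stop_counts <- function(rows, frame, from, to) {
  width <- nchar(rows[[1]])
  total <- 0L
  for (r in rows) {
    s <- frame + 1L
    while (s + 2L <= width) {
      if (s >= from && s + 2L <= to &&
          substring(r, s, s + 2L) %in% c("TAA", "TAG", "TGA"))
        total <- total + 1L
      s <- s + 3L
    }
  }
  total
}

# sets of tip labels below each internal non-root node
clade_sets <- function(tree) {
  nt <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "|"),
                 character(1))
  sets[-1]  # drop the root clade (all tips)
}

# hand-built target_region for select/tile unit tests
mk_region <- function(seqs, nt_start = 1L, represented = NULL) {
  width <- max(nchar(seqs))
  structure(list(ortholog_id = "ogX", aa_start = 1L,
                 aa_end = width %/% 3L, nt_start = nt_start,
                 nt_end = nt_start + width - 1L,
                 gapped_nt = seqs, seqs = gsub("-", "", seqs),
                 represented_taxa = represented),
            class = "target_region")
}

# hand-built split_locus (probe region only, empty flanks)
mk_split <- function(probe, id = "LX", frame = 0L) {
  empty <- setNames(rep("", length(probe)), names(probe))
  structure(list(locus_id = id, taxa = names(probe), left_flank = empty,
                 probe = probe, right_flank = empty, frame = frame,
                 probe_span = c(1L, nchar(probe[[1]])), masks = NULL),
            class = "split_locus")
}
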