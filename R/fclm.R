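#' Read a taxon-to-cluster assignment table
#'
#' Expects a two-column TSV (`taxon<TAB>cluster`) with cluster labels
#' `c1`-`c4` (case-insensitive) or `ignore`.
#'
#' @param path TSV path.
#' @return named character vector taxon -> cluster label (`C1`-`C4`,
#'   `ignore`).
#' @export
read_clusters <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, col.names = c("taxon", "cluster"))
  cl <- toupper(df$cluster)
  cl[cl == "IGNORE"] <- "ignore"
  bad <- !(cl %in% c("C1", "C2", "C3", "C4", "ignore"))
  if (any(bad))
    stop("invalid cluster labels: ", paste(unique(df$cluster[bad]),
                                           collapse = ", "))
  setNames(cl, df$taxon)
}

#' Enumerate quartets across four taxon clusters
#'
#' One taxon from each cluster, the full Cartesian product
#' `C1 x C2 x C3 x C4` in deterministic order (C4 varying fastest); taxa
#' labelled `ignore` are excluded.
#'
#' @param clusters named character vector taxon -> `C1`-`C4`/`ignore` (see
#'   [read_clusters()]).
#' @param alignment_taxa optional taxon names of the alignment, used to check
#'   that every clustered taxon is present.
#' @return tibble with columns `a`, `b`, `c`, `d` (members of C1-C4).
#' @export
enumerate_quartets <- function(clusters, alignment_taxa = NULL) {
  clusters <- clusters[clusters != "ignore"]
  if (!is.null(alignment_taxa)) {
    missing <- setdiff(names(clusters), alignment_taxa)
    if (length(missing) > 0L)
      stop("clustered taxa absent from alignment: ",
           paste(missing, collapse = ", "))
  }
  grp <- lapply(c("C1", "C2", "C3", "C4"),
                function(k) names(clusters)[clusters == k])
  empty <- vapply(grp, length, integer(1)) == 0L
  if (any(empty))
    stop("empty cluster: ", paste(c("C1", "C2", "C3", "C4")[empty],
                                  collapse = ", "))
  g <- expand.grid(d = grp[[4L]], c = grp[[3L]], b = grp[[2L]], a = grp[[1L]],
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(match(g$a, grp[[1L]]), match(g$b, grp[[2L]]),
               match(g$c, grp[[3L]]), match(g$d, grp[[4L]])), , drop = FALSE]
  tibble::tibble(a = g$a, b = g$b, c = g$c, d = g$d)
}

fclm_alphabet <- function(model) {
  switch(model,
         jc = c("A", "C", "G", "T"),
         poisson = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
         stop("unknown model: ", model))
}

# k-state equal-rates transition probabilities at branch length t
# (expected substitutions per site)
eqrates_pmatrix <- function(t, k) {
  e <- exp(-k * t / (k - 1))
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

# log-likelihood of an unrooted quartet ((x1,x2),(x3,x4)) with tip branch
# lengths b[1..4] and internal branch b[5]; `pat` is an n x 4 integer matrix
# of state indices, `cnt` the pattern counts
quartet_loglik <- function(b, pat, cnt, k) {
  P <- lapply(b[1:4], eqrates_pmatrix, k = k)
  P5 <- eqrates_pmatrix(b[5L], k)
  A <- P[[1L]][pat[, 1L], , drop = FALSE]
  B <- P[[2L]][pat[, 2L], , drop = FALSE]
  C <- P[[3L]][pat[, 3L], , drop = FALSE]
  D <- P[[4L]][pat[, 4L], , drop = FALSE]
  site <- rowSums((A * B) * ((C * D) %*% P5)) / k
  sum(cnt * log(site))
}

cyclic_ascent <- function(b, pat, cnt, k, lower, upper, max_sweeps, tol) {
  ll <- quartet_loglik(b, pat, cnt, k)
  for (sweep in seq_len(max_sweeps)) {
    for (j in 1:5) {
      opt <- optimize(function(x) {
        b2 <- b; b2[j] <- x
        quartet_loglik(b2, pat, cnt, k)
      }, interval = c(lower, upper), maximum = TRUE, tol = tol * upper / 100)
      b[j] <- opt$maximum
    }
    ll_new <- quartet_loglik(b, pat, cnt, k)
    if (ll_new - ll <= tol * (abs(ll) + 1) * 1e-3) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(loglik = ll, branches = b)
}

# deterministic multi-start: the all-0.1 start plus two internal-branch
# variants, guarding against the boundary local optimum at internal ~ 0
optimize_quartet <- function(pat, cnt, k, lower = 1e-8, upper = 10,
                             init = 0.1, max_sweeps = 100L, tol = 1e-6) {
  best <- NULL
  for (b5 in c(init, 0.5, 0.01)) {
    fit <- cyclic_ascent(c(rep(init, 4L), b5), pat, cnt, k,
                         lower, upper, max_sweeps, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Maximised log-likelihoods of the three quartet topologies
#'
#' For a quartet `(a, b, c, d)` the three unrooted topologies are
#' `T1 = (ab|cd)`, `T2 = (ac|bd)` and `T3 = (ad|bc)`.  Each topology's
#' likelihood is maximised over its five branch lengths by Felsenstein
#' pruning plus cyclic one-dimensional (Brent) optimisation, deterministic
#' initialisation at 0.1, bounds `[1e-8, 10]`.  Columns with a gap or
#' ambiguity in any of the four taxa are skipped (complete-case deletion).
#'
#' @param alignment named character vector of aligned sequences.
#' @param quartet character vector of four taxon names (one per cluster).
#' @param model `"jc"` (nucleotide, JC69) or `"poisson"` (amino acid, equal
#'   rates).
#' @return numeric triple `(l1, l2, l3)` with attribute `n_sites` (usable
#'   columns); all `NA` with a warning when no usable column exists.
#' @export
quartet_log_likelihoods <- function(alignment, quartet,
                                    model = c("jc", "poisson")) {
  model <- match.arg(model)
  alpha <- fclm_alphabet(model)
  k <- length(alpha)
  rows <- alignment[quartet]
  if (anyNA(names(rows))) stop("quartet taxa missing from alignment")
  m <- seqs_to_matrix(rows)
  idx <- matrix(match(m, alpha), nrow = 4L)
  usable <- colSums(is.na(idx)) == 0L
  if (!any(usable)) {
    warning("quartet ", paste(quartet, collapse = ","),
            ": no column where all four taxa are unambiguous; skipped")
    out <- c(NA_real_, NA_real_, NA_real_)
    attr(out, "n_sites") <- 0L
    return(out)
  }
  idx <- idx[, usable, drop = FALSE]
  key <- apply(idx, 2L, paste, collapse = ".")
  cnt <- table(key)
  pat <- do.call(rbind, lapply(strsplit(names(cnt), ".", fixed = TRUE),
                               as.integer))
  cnt <- as.numeric(cnt)
  orders <- list(c(1L, 2L, 3L, 4L),  # T1 = (ab|cd)
                 c(1L, 3L, 2L, 4L),  # T2 = (ac|bd)
                 c(1L, 4L, 2L, 3L))  # T3 = (ad|bc)
  # canonicalise within and between pairs by taxon name, so relabelled
  # quartets optimise the same objective in the same column order
  canonical <- function(o) {
    p1 <- o[1:2][order(quartet[o[1:2]])]
    p2 <- o[3:4][order(quartet[o[3:4]])]
    if (quartet[p2[1L]] < quartet[p1[1L]]) c(p2, p1) else c(p1, p2)
  }
  out <- vapply(orders, function(o)
    optimize_quartet(pat[, canonical(o), drop = FALSE], cnt, k)$loglik,
    numeric(1))
  attr(out, "n_sites") <- sum(cnt)
  out
}

#' Posterior topology weights from log-likelihoods
#'
#' Numerically stable softmax: `p_i = exp(l_i - logsumexp(l))`.
#'
#' @param l numeric triple of log-likelihoods.
#' @return simplex point `(p1, p2, p3)` summing to 1.
#' @export
posterior_weights <- function(l) {
  stopifnot(length(l) == 3L, all(is.finite(l)))
  mx <- max(l)
  w <- exp(l - mx - log(sum(exp(l - mx))))
  unname(w)
}

fclm_attractors <- rbind(
  R1 = c(1, 0, 0), R2 = c(0, 1, 0), R3 = c(0, 0, 1),
  R12 = c(0.5, 0.5, 0), R13 = c(0.5, 0, 0.5), R23 = c(0, 0.5, 0.5),
  Rc = c(1, 1, 1) / 3)

#' Assign a simplex point to one of the seven likelihood-mapping regions
#'
#' Nearest attractor by Euclidean distance among the three corners
#' (`R1`-`R3`, resolved), three edge midpoints (`R12`, `R13`, `R23`, partly
#' resolved) and the centre (`Rc`, unresolved).  Exact ties go to the more
#' resolved region (corner > edge > centre), then to the lowest index.
#'
#' @param p simplex point from [posterior_weights()].
#' @return region label, one of `R1 R2 R3 R12 R13 R23 Rc`.
#' @export
assign_region <- function(p) {
  stopifnot(length(p) == 3L, all(p >= -1e-9), abs(sum(p) - 1) < 1e-6)
  d2 <- rowSums((fclm_attractors - matrix(p, 7L, 3L, byrow = TRUE))^2)
  rownames(fclm_attractors)[which.min(d2)]
}

#' Run four-cluster likelihood mapping
#'
#' Enumerates all quartets across the four clusters, maximises the three
#' topology likelihoods per quartet, maps the posterior weights onto the
#' 2-simplex and assigns each quartet to one of the seven regions.
#'
#' @param alignment named character vector of aligned sequences (NT or AA).
#' @param clusters named cluster assignment (see [read_clusters()]).
#' @param model `"jc"` or `"poisson"`.
#' @return tibble with one row per quartet: taxa `a`-`d`, `l1`-`l3`,
#'   `p1`-`p3`, `region`, `n_sites`.  Quartets with no usable columns carry
#'   `NA` and no region.
#' @export
run_fclm <- function(alignment, clusters, model = c("jc", "poisson")) {
  model <- match.arg(model)
  q <- enumerate_quartets(clusters, names(alignment))
  res <- lapply(seq_len(nrow(q)), function(i) {
    l <- quartet_log_likelihoods(alignment,
                                 c(q$a[i], q$b[i], q$c[i], q$d[i]), model)
    base <- tibble::tibble(a = q$a[i], b = q$b[i], c = q$c[i], d = q$d[i])
    if (anyNA(l))
      return(cbind(base, tibble::tibble(
        l1 = NA_real_, l2 = NA_real_, l3 = NA_real_,
        p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
        region = NA_character_, n_sites = attr(l, "n_sites"))))
    p <- posterior_weights(l)
    cbind(base, tibble::tibble(
      l1 = l[1L], l2 = l[2L], l3 = l[3L],
      p1 = p[1L], p2 = p[2L], p3 = p[3L],
      region = assign_region(p), n_sites = attr(l, "n_sites")))
  })
  do.call(rbind, res)
}

#' Summarise FcLM results over the seven simplex regions
#'
#' @param results per-quartet tibble from [run_fclm()].
#' @return object of class `fclm_result`: per-region counts and proportions,
#'   aggregate resolved (`R1+R2+R3`), partly-resolved (`R12+R13+R23`) and
#'   unresolved (`Rc`) fractions, `n_quartets` (scored) and `n_skipped`.
#' @export
fclm_summary <- function(results) {
  scored <- results[!is.na(results$region), , drop = FALSE]
  if (nrow(scored) == 0L) stop("no scored quartets")
  regions <- rownames(fclm_attractors)
  counts <- setNames(integer(7L), regions)
  tab <- table(factor(scored$region, levels = regions))
  counts[names(tab)] <- as.integer(tab)
  props <- counts / nrow(scored)
  structure(list(
    counts = counts, proportions = props,
    resolved = sum(props[c("R1", "R2", "R3")]),
    partly_resolved = sum(props[c("R12", "R13", "R23")]),
    unresolved = props[["Rc"]],
    n_quartets = nrow(scored),
    n_skipped = sum(is.na(results$region))), class = "fclm_result")
}

#' @export
print.fclm_result <- function(x, ...) {
  cat("Four-cluster likelihood mapping:", x$n_quartets, "quartets")
  if (x$n_skipped > 0L) cat(" (", x$n_skipped, " skipped)", sep = "")
  cat("\n")
  for (r in names(x$counts))
    cat(sprintf("  %-3s %5d  %6.1f%%\n", r, x$counts[[r]],
                100 * x$proportions[[r]]))
  cat(sprintf("  resolved %.1f%%, partly %.1f%%, unresolved %.1f%%\n",
              100 * x$resolved, 100 * x$partly_resolved,
              100 * x$unresolved))
  invisible(x)
}
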