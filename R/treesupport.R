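#' Parse dual support labels from a newick tree
#'
#' Internal node labels are interpreted as `UFB/SHT` percentage pairs
#' (IQ-TREE convention, order configurable) or single local posterior
#' probabilities (ASTRAL).  UFB and SHT are kept on the percent scale,
#' LPP as a fraction.
#'
#' @param tree a newick string, a file path, or an `ape` `phylo`.
#' @param format label convention: `"ufb-sht"` (default), `"sht-ufb"` or
#'   `"lpp"`.
#' @return the `phylo` with classes `c("support_tree", "phylo")`, a
#'   `support` attribute (tibble: `node`, `ufb`, `sht`, `lpp`; internal
#'   nodes only) and a `support_format` attribute.
#' @export
parse_support <- function(tree, format = c("ufb-sht", "sht-ufb", "lpp")) {
  format <- match.arg(format)
  if (is.character(tree)) {
    tree <- if (grepl("(", tree, fixed = TRUE))
      ape::read.tree(text = tree) else ape::read.tree(tree)
  }
  stopifnot(inherits(tree, "phylo"))
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  labels <- tree$node.label %||% rep("", nn)
  ufb <- sht <- lpp <- rep(NA_real_, nn)
  for (i in seq_len(nn)) {
    lab <- labels[i]
    if (is.na(lab) || lab == "") next
    parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop("malformed support label '", lab, "' at node ", nt + i)
    if (format == "lpp") {
      if (length(vals) != 1L || vals < 0 || vals > 1)
        stop("malformed LPP label '", lab, "' at node ", nt + i)
      lpp[i] <- vals
    } else {
      if (length(vals) != 2L)
        stop("malformed support label '", lab, "' at node ", nt + i,
             ": expected two '/'-separated values")
      if (any(vals < 0 | vals > 100))
        stop("support out of range in label '", lab, "' at node ", nt + i)
      if (format == "ufb-sht") { ufb[i] <- vals[1L]; sht[i] <- vals[2L] }
      else { sht[i] <- vals[1L]; ufb[i] <- vals[2L] }
    }
  }
  attr(tree, "support") <- tibble::tibble(node = nt + seq_len(nn),
                                          ufb = ufb, sht = sht, lpp = lpp)
  attr(tree, "support_format") <- format
  class(tree) <- c("support_tree", "phylo")
  tree
}

#' Classify node support
#'
#' Implements the study's support classes: strong when both UFB and SHT are
#' at least 95 or LPP is at least 0.95; otherwise moderate when UFB >= 95
#' and SHT >= 80, or LPP >= 0.85; otherwise weak when exactly one of
#' UFB >= 95 / SHT >= 80 holds; otherwise none.  Absent values never
#' satisfy a condition.  `three_class = TRUE` folds moderate into weak
#' (figure-legend style strong/weak/unsupported reporting).
#'
#' @param ufb,sht ultrafast-bootstrap and SH-aLRT supports in percent
#'   (0-100), `NA` when absent; vectorised.
#' @param lpp local posterior probability as a fraction (0-1), `NA` when
#'   absent.
#' @param three_class fold moderate into weak.
#' @return ordered factor with levels `none < weak < moderate < strong`.
#' @export
classify_support <- function(ufb = NA_real_, sht = NA_real_, lpp = NA_real_,
                             three_class = FALSE) {
  n <- max(length(ufb), length(sht), length(lpp))
  ufb <- rep_len(ufb, n); sht <- rep_len(sht, n); lpp <- rep_len(lpp, n)
  u95 <- !is.na(ufb) & ufb >= 95
  s95 <- !is.na(sht) & sht >= 95
  s80 <- !is.na(sht) & sht >= 80
  l95 <- !is.na(lpp) & lpp >= 0.95
  l85 <- !is.na(lpp) & lpp >= 0.85
  cls <- rep("none", n)
  cls[xor(u95, s80)] <- "weak"
  cls[(u95 & s80) | l85] <- "moderate"
  cls[(u95 & s95) | l95] <- "strong"
  if (three_class) cls[cls == "moderate"] <- "weak"
  factor(cls, levels = c("none", "weak", "moderate", "strong"),
         ordered = TRUE)
}

#' Classify every internal node of a support tree
#'
#' @param tree a `support_tree` from [parse_support()].
#' @param three_class see [classify_support()].
#' @return tibble `node`, `ufb`, `sht`, `lpp`, `class`.
#' @export
classify_tree_support <- function(tree, three_class = FALSE) {
  s <- attr(tree, "support")
  if (is.null(s)) stop("tree has no parsed support; use parse_support()")
  s$class <- classify_support(s$ufb, s$sht, s$lpp, three_class = three_class)
  s
}

# rebuild a newick string, splicing out the internal nodes in `drop`
# (their children reattach to the parent; the dropped edge's length is
# discarded, children keep their own lengths)
build_newick <- function(tree, drop = integer(0)) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- NULL
  if (!is.null(tree$edge.length))
    elen <- setNames(tree$edge.length, tree$edge[, 2L])
  lenstr <- function(node) {
    if (is.null(elen) || node == root) return("")
    paste0(":", format(elen[[as.character(node)]], digits = 15))
  }
  rec <- function(node) {
    if (node <= nt)
      return(paste0(tree$tip.label[node], lenstr(node)))
    parts <- unlist(lapply(kids[[as.character(node)]], rec))
    if (node != root && node %in% drop) return(parts)
    lab <- tree$node.label[node - nt] %||% ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(parts, collapse = ","), ")", lab, lenstr(node))
  }
  paste0(rec(root), ";")
}

#' Collapse branches with very low bootstrap support
#'
#' Internal edges whose child node has UFB below `min_ufb` are contracted
#' into polytomies (the pre-coalescent "collapse nodes below 10 UFB" step);
#' leaf edges and the root are never touched.
#'
#' @param tree a `support_tree` from [parse_support()] (or a newick
#'   string/path, parsed with `format`).
#' @param min_ufb collapse threshold, percent; edges with `ufb < min_ufb`
#'   are contracted.
#' @param assume_supported treat internal edges without a UFB value as
#'   supported instead of erroring.
#' @param format label convention, used when `tree` is not yet parsed.
#' @return the collapsed tree, re-parsed as a `support_tree`.
#' @export
collapse_low_support <- function(tree, min_ufb = 10,
                                 assume_supported = FALSE,
                                 format = c("ufb-sht", "sht-ufb", "lpp")) {
  format <- match.arg(format)
  if (!inherits(tree, "support_tree")) tree <- parse_support(tree, format)
  fmt <- attr(tree, "support_format")
  s <- attr(tree, "support")
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  internal <- s$node[s$node != root]
  missing <- internal[is.na(s$ufb[match(internal, s$node)])]
  if (length(missing) > 0L && !assume_supported)
    stop("internal edges without UFB annotation (nodes ",
         paste(missing, collapse = ", "),
         "); set assume_supported = TRUE to keep them")
  drop <- s$node[!is.na(s$ufb) & s$ufb < min_ufb & s$node != root]
  parse_support(build_newick(tree, drop = drop), format = fmt)
}

#' Write a support tree as newick
#'
#' @param tree a `support_tree` (or plain `phylo`).
#' @param path output path; when `NULL` the newick string is returned.
#' @return the path (invisibly) or the newick string.
#' @export
write_support_tree <- function(tree, path = NULL) {
  s <- build_newick(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}
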