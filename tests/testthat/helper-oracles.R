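# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain loops and textbook formulas only.

# exhaustive per-window literal-comparison scanner
oracle_scan <- function(sequence, pattern, max_mismatch) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  res <- data.frame(start = integer(), mismatches = integer())
  n_win <- length(chars) - pattern$span + 1L
  if (n_win < 1L) return(res)
  for (s in seq_len(n_win)) {
    m <- 0L
    for (k in seq_along(pattern$literal_pos)) {
      if (chars[s + pattern$literal_pos[k] - 1L] != pattern$literal_res[k]) m <- m + 1L
    }
    if (m <= max_mismatch) res <- rbind(res, data.frame(start = s, mismatches = m))
  }
  res[order(res$mismatches, res$start), , drop = FALSE]
}

# two-pass product-moment correlation, straight from the formula
oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# exhaustive both-strand window scan of one promoter against an element table
oracle_scan_promoter <- function(sequence, elements) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  window_matches <- function(win, cons) {
    for (k in seq_along(cons)) {
      ch <- win[k]
      if (ch == "N") {
        if (cons[k] != "N") return(FALSE)
      } else if (!(ch %in% oracle_iupac_sets[[cons[k]]])) {
        return(FALSE)
      }
    }
    TRUE
  }
  acc <- list()
  for (i in seq_len(nrow(elements))) {
    for (orient in c("+", "-")) {
      cons_str <- if (orient == "+") toupper(elements$consensus[i])
                  else oracle_revcomp(toupper(elements$consensus[i]))
      cons <- strsplit(cons_str, "", fixed = TRUE)[[1]]
      n_win <- length(chars) - length(cons) + 1L
      if (n_win < 1L) next
      hit <- logical(n_win)
      for (s in seq_len(n_win)) {
        hit[s] <- window_matches(chars[s:(s + length(cons) - 1L)], cons)
      }
      if (any(hit)) {
        acc[[length(acc) + 1L]] <- data.frame(element = elements$name[i],
                                              start = which(hit), strand = orient)
      }
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(element = character(), start = integer(), strand = character()))
  }
  do.call(rbind, acc)
}

# random unrooted binary tree with positive branch lengths and its additive metric
rand_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = sort(sprintf("T%02d", seq_len(n_taxa))))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
  dm <- ape::cophenetic.phylo(tr)
  labs <- sort(rownames(dm))
  list(tree = tr, dm = dm[labs, labs])
}

split_set <- function(tree) {
  k <- cadfam::tree_bipartitions(tree)
  sort(k[!is.na(k)])
}

# least-squares branch-length fit of a fixed topology to a distance matrix
ls_fit_rss <- function(tree, dm) {
  labs <- rownames(dm)
  n <- length(labs)
  tipsets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tipsets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    tipsets[[po$edge[e, 1]]] <- c(tipsets[[po$edge[e, 1]]], tipsets[[po$edge[e, 2]]])
  }
  pairs <- t(utils::combn(labs, 2))
  A <- matrix(0, nrow = nrow(pairs), ncol = nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    below <- tipsets[[tree$edge[e, 2]]]
    sep <- xor(pairs[, 1] %in% below, pairs[, 2] %in% below)
    A[sep, e] <- 1
  }
  b <- dm[pairs]
  fit <- stats::lm.fit(A, b)
  sum(fit$residuals^2)
}

# exhaustive least-squares topology search (n <= 6)
ls_best_splits <- function(dm) {
  labs <- rownames(dm)
  cand <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(cand, ls_fit_rss, numeric(1), dm = dm)
  split_set(cand[[which.min(rss)]])
}

# tree-path metric of a phylo tree, in a fixed label order
path_metric <- function(tree, labs) {
  ape::cophenetic.phylo(tree)[labs, labs]
}
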