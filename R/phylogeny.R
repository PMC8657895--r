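#' Read an aligned FASTA into a tibble
#'
#' @param path Aligned amino-acid FASTA (gap character `-` allowed).
#' @return Tibble with columns `id`, `sequence`; all sequences are checked to
#'   have equal length.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate ids in alignment \"%s\".", path))
  }
  aln <- tibble(id = ids, sequence = toupper(as.character(set)))
  .check_alignment(aln)
  aln
}

.check_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "sequence") %in% names(aln)))
  lens <- nchar(aln$sequence)
  if (length(unique(lens)) != 1L) {
    abort("Alignment sequences must all have the same length.")
  }
  if (anyDuplicated(aln$id)) abort("Alignment ids must be unique.")
  invisible(aln)
}

.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(aln$sequence), "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Pairwise distances from an alignment
#'
#' Computes the proportion of differing residues per pair over shared
#' (ungapped) columns, optionally with a Poisson correction
#' `d = -ln(1 - p)` appropriate for protein distances.
#'
#' @param aln Alignment tibble (`id`, `sequence`), e.g. from
#'   [read_alignment()].
#' @param model `"poisson"` (default) or `"p"` for the raw p-distance.
#' @param gap_handling `"pairwise"` deletion (default; each pair compared
#'   over the columns where neither has a gap) or `"complete"` deletion
#'   (columns with any gap dropped for all pairs).
#' @return Symmetric numeric matrix (zero diagonal) with taxon labels, in
#'   substitutions per site.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p"),
                              gap_handling = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  .check_alignment(aln)
  m <- .aln_matrix(aln)
  if (gap_handling == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) abort("No gap-free columns under complete deletion.")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared)) {
        abort(sprintf("No shared ungapped columns between \"%s\" and \"%s\".",
                      rownames(m)[i], rownames(m)[j]))
      }
      p <- mean(m[i, shared] != m[j, shared])
      if (model == "poisson") {
        if (p >= 1) {
          abort(sprintf("Saturated distance (p = 1) between \"%s\" and \"%s\" under the Poisson model.",
                        rownames(m)[i], rownames(m)[j]))
        }
        d[i, j] <- d[j, i] <- -log(1 - p)
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

.check_dist <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("Distance matrix must be square.")
  if (is.null(rownames(dm))) abort("Distance matrix must carry taxon labels.")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    abort("Distance matrix must be symmetric.")
  }
  if (any(!is.finite(dm))) abort("Distance matrix entries must be finite.")
  if (any(abs(diag(dm)) > 1e-12)) abort("Distance matrix diagonal must be zero.")
  invisible(dm)
}

.nwk_label <- function(x) {
  if (grepl("[](){}:;,'\\[[:space:]]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

.nwk_len <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined (ties broken by the
#' lowest index pair in the current matrix order), branch lengths are
#' estimated by the usual rate-corrected formulas with negative estimates
#' clamped to zero, and the matrix is reduced. For an additive input metric
#' the returned tree's path-length metric reproduces the input exactly.
#'
#' @param dm Symmetric distance matrix with taxon labels (n >= 3).
#' @return An unrooted [ape::phylo] tree (basal trichotomy, binary
#'   elsewhere) with branch lengths.
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(dm) {
  .check_dist(dm)
  n <- nrow(dm)
  if (n < 3L) abort("Neighbor joining needs at least 3 taxa.")
  d <- dm
  # build with placeholder labels, restore the real ones afterwards so that
  # labels with Newick metacharacters survive untouched
  labels <- rownames(dm)
  placeholders <- sprintf("t%d", seq_len(n))
  frag <- placeholders

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_)
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], .nwk_len(li), frag[j], .nwk_len(lj))

    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d2 <- d[others, others, drop = FALSE]
    d2 <- rbind(cbind(d2, new_d), c(new_d, 0))
    frag <- c(frag[others], new_frag)
    rownames(d2) <- colnames(d2) <- paste0("node", seq_len(nrow(d2)))
    d <- d2
  }

  a <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  b <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  c_ <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], .nwk_len(a), frag[2], .nwk_len(b), frag[3], .nwk_len(c_))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[match(tree$tip.label, placeholders)]
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the taxa into two groups of
#' size >= 2. Splits are canonicalized label-wise (the side not containing
#' the lexicographically first taxon, labels sorted and joined by `|`), so
#' keys are invariant to taxon order and rooting.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector indexed by node number (tips then internal
#'   nodes); `NA` for tips and for nodes whose edge gives a trivial split.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- min(tree$tip.label)
  keys <- rep(NA_character_, n + tree$Nnode)
  for (v in (n + 1L):(n + tree$Nnode)) {
    side <- desc[[v]]
    if (length(side) >= 2L && length(side) <= n - 2L) {
      s <- if (anchor %in% side) setdiff(tree$tip.label, side) else side
      keys[v] <- paste(sort(s), collapse = "|")
    }
  }
  keys
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds distances and the
#' NJ tree per replicate, and tallies how often each internal bipartition of
#' the full-data tree occurs among the replicate trees. Support percentages
#' are mapped onto the full-data tree (not a consensus tree) as internal
#' node labels. Replicates whose resampled distance matrix is undefined
#' (saturated or no shared columns for some pair) are skipped and counted;
#' more than 50% skipped is an error.
#'
#' @inheritParams pairwise_distance
#' @param replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed RNG seed; the same seed gives identical results.
#' @return A `cad_phylo` object: list with `tree` (full-data NJ tree whose
#'   internal node labels carry support percentages in \[0, 100\]),
#'   `support` (tibble `bipartition`, `support`), `replicates`, `n_skipped`,
#'   `model` and `seed`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L,
                              model = c("poisson", "p"), seed = 1L,
                              gap_handling = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) abort("`replicates` must be >= 1.")
  .check_alignment(aln)
  if (nrow(aln) < 3L) abort("Bootstrap needs at least 3 taxa.")

  full_tree <- neighbor_joining(pairwise_distance(aln, model, gap_handling))
  keys <- tree_bipartitions(full_tree)
  target <- keys[!is.na(keys)]
  counts <- setNames(rep(0L, length(target)), target)

  m <- .aln_matrix(aln)
  n_col <- ncol(m)
  n_skipped <- 0L
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(replicates)) {
      cols <- sample.int(n_col, n_col, replace = TRUE)
      rep_aln <- tibble(
        id = rownames(m),
        sequence = apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      )
      rep_tree <- tryCatch(
        neighbor_joining(pairwise_distance(rep_aln, model, gap_handling)),
        error = function(e) NULL
      )
      if (is.null(rep_tree)) {
        n_skipped <- n_skipped + 1L
        next
      }
      rk <- tree_bipartitions(rep_tree)
      hit <- intersect(target, rk[!is.na(rk)])
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (n_skipped > replicates / 2) {
    abort(sprintf("%d of %d bootstrap replicates had undefined distances.",
                  n_skipped, replicates))
  }
  used <- replicates - n_skipped
  support <- round(100 * counts / used, 6)

  n_tip <- length(full_tree$tip.label)
  labels <- character(full_tree$Nnode)
  for (v in seq_len(full_tree$Nnode)) {
    k <- keys[n_tip + v]
    labels[v] <- if (is.na(k)) "" else format(support[[k]])
  }
  full_tree$node.label <- labels

  structure(
    list(
      tree = full_tree,
      support = tibble(bipartition = names(support), support = unname(support)),
      replicates = replicates,
      n_skipped = n_skipped,
      model = model,
      seed = as.integer(seed)
    ),
    class = "cad_phylo"
  )
}

#' @export
print.cad_phylo <- function(x, ...) {
  cat(sprintf(
    "<cad_phylo: %d taxa, %s-model NJ, %d bootstrap replicates (%d skipped), seed %d>\n",
    length(x$tree$tip.label), x$model, x$replicates, x$n_skipped, x$seed
  ))
  print(x$tree)
  invisible(x)
}

#' @describeIn bootstrap_support `tidy()` returns the per-bipartition
#'   support table.
#' @param x A `cad_phylo` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cad_phylo <- function(x, ...) {
  x$support
}

#' @describeIn bootstrap_support `glance()` returns a one-row summary of the
#'   bootstrap run.
#' @exportS3Method generics::glance
glance.cad_phylo <- function(x, ...) {
  tibble(
    n_taxa = length(x$tree$tip.label),
    replicates = x$replicates,
    n_skipped = x$n_skipped,
    model = x$model,
    seed = x$seed,
    min_support = if (nrow(x$support)) min(x$support$support) else NA_real_,
    mean_support = if (nrow(x$support)) mean(x$support$support) else NA_real_
  )
}

#' Plot a bootstrapped NJ tree
#'
#' Unrooted tree plot with bootstrap support percentages at internal nodes.
#'
#' @param x A `cad_phylo` object (or a bare [ape::phylo]).
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_phylogeny <- function(x, ...) {
  tree <- if (inherits(x, "cad_phylo")) x$tree else x
  ape::plot.phylo(tree, type = "unrooted", ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", cex = 0.8, col = "firebrick")
  }
  invisible(tree)
}

#' Write a tree to Newick
#'
#' Branch lengths are written with 15 significant digits and any bootstrap
#' supports stored as internal node labels are preserved, so
#' `ape::read.tree()` round-trips topology, lengths and supports. Labels
#' containing Newick metacharacters (parentheses, commas, colons,
#' semicolons, quotes or whitespace) are single-quoted.
#'
#' @param tree An [ape::phylo] or `cad_phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "cad_phylo")) tree <- tree$tree
  if (!inherits(tree, "phylo") || length(tree$tip.label) == 0L) {
    abort("`tree` must be a non-empty phylo object.")
  }
  writeLines(phylo_to_newick(tree), con = path)
  invisible(path)
}

#' Serialize a phylo tree to a Newick string
#'
#' @inheritParams write_newick
#' @return Single Newick string ending in `";"`.
#' @export
phylo_to_newick <- function(tree) {
  if (inherits(tree, "cad_phylo")) tree <- tree$tree
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, edge_idx) {
    if (node <= n_tip) {
      lab <- .nwk_label(tree$tip.label[node])
    } else {
      parts <- vapply(kids[[as.character(node)]], function(e) {
        rec(tree$edge[e, 2], e)
      }, character(1))
      nlab <- if (!is.null(tree$node.label)) tree$node.label[node - n_tip] else ""
      lab <- paste0("(", paste(parts, collapse = ","), ")",
                    if (is.na(nlab)) "" else .nwk_label(nlab))
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length)) {
      paste0(lab, ":", .nwk_len(tree$edge.length[edge_idx]))
    } else {
      lab
    }
  }
  paste0(rec(n_tip + 1L, NULL), ";")
}

#' Write a distance matrix to TSV
#'
#' @param dm Labelled symmetric matrix from [pairwise_distance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- bind_cols(tibble(taxon = rownames(dm)), as_tibble(dm))
  readr::write_tsv(df, path)
  invisible(path)
}
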