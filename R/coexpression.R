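#' Pearson correlation between two expression profiles
#'
#' Standard product-moment correlation, the co-expression measure used to
#' relate two genes' expression across a tissue panel.
#'
#' @param x,y Numeric profiles of equal length (>= 3), each with non-zero
#'   variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("Profiles must have equal length.")
  if (length(x) < 3L) abort("Profiles must have length >= 3.")
  if (anyNA(x) || anyNA(y)) abort("Profiles must not contain missing values.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Undefined correlation: zero-variance profile.")
  }
  stats::cor(x, y)
}

#' Build a Pearson co-expression network
#'
#' Computes the PCC for every unordered gene pair (or, when `seed_genes` is
#' given, every pair involving at least one seed gene) over the sample
#' columns, and classifies pairs as positively co-expressed when
#' `pcc >= pos_threshold` and negatively when `pcc <= neg_threshold`
#' (defaults 0.7 and -0.5; boundaries inclusive). Only classified pairs are
#' returned. Zero-variance genes cannot be correlated and are skipped with
#' a warning naming them. Raw PCCs are thresholded directly — no p-values
#' or multiple-testing correction.
#'
#' @param em Filtered FPKM tibble (`gene_id` + sample columns); apply
#'   [expression_filter()] first.
#' @param pos_threshold Positive-edge threshold in (0, 1\].
#' @param neg_threshold Negative-edge threshold in \[-1, 0).
#' @param seed_genes Optional character vector restricting evaluation to
#'   seed x universe pairs (e.g. the CAD genes against all lignin genes).
#' @return A `coexpression_network` tibble of edges, sorted by
#'   `(gene_a, gene_b)` with `gene_a < gene_b`: columns `gene_a`, `gene_b`,
#'   `pcc`, `sign_class` (`"positive"`/`"negative"`). Attributes record the
#'   thresholds, the genes used and the number of pairs evaluated.
#' @export
build_network <- function(em, pos_threshold = 0.7, neg_threshold = -0.5,
                          seed_genes = NULL) {
  em <- .check_fpkm(em)
  if (!(pos_threshold > 0 && pos_threshold <= 1) || !(neg_threshold < 0 && neg_threshold >= -1)) {
    abort("Thresholds must satisfy -1 <= neg_threshold < 0 < pos_threshold <= 1.")
  }
  m <- .fpkm_matrix(em)
  if (nrow(m) < 2L) abort("Need at least 2 genes to build a network.")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("Skipping zero-variance gene(s): %s.",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) < 2L) abort("Fewer than 2 genes with non-zero variance.")
  }
  genes <- rownames(m)
  if (!is.null(seed_genes)) {
    missing <- setdiff(seed_genes, genes)
    if (length(missing) > 0L) {
      warn(sprintf("Seed gene(s) not in the matrix (or zero-variance): %s.",
                   paste(missing, collapse = ", ")))
    }
    seed_genes <- intersect(seed_genes, genes)
    if (length(seed_genes) == 0L) abort("No seed genes present in the matrix.")
  }

  cc <- stats::cor(t(m))
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  a <- genes[pairs[, 1]]
  b <- genes[pairs[, 2]]
  if (!is.null(seed_genes)) {
    keep <- a %in% seed_genes | b %in% seed_genes
    pairs <- pairs[keep, , drop = FALSE]
    a <- a[keep]; b <- b[keep]
  }
  pcc <- cc[pairs]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  edges <- tibble(gene_a = a, gene_b = b, pcc = pcc) |>
    mutate(sign_class = dplyr::case_when(
      pcc >= pos_threshold ~ "positive",
      pcc <= neg_threshold ~ "negative",
      TRUE ~ "none"
    )) |>
    filter(.data$sign_class != "none") |>
    arrange(.data$gene_a, .data$gene_b)

  inform(sprintf(
    "Evaluated %d gene pairs: %d positive (PCC >= %g), %d negative (PCC <= %g).",
    length(pcc), sum(edges$sign_class == "positive"), pos_threshold,
    sum(edges$sign_class == "negative"), neg_threshold
  ))
  attr(edges, "pos_threshold") <- pos_threshold
  attr(edges, "neg_threshold") <- neg_threshold
  attr(edges, "genes") <- genes
  attr(edges, "n_pairs") <- length(pcc)
  class(edges) <- c("coexpression_network", class(edges))
  edges
}

#' @describeIn build_network `glance()` summarises the network in one row.
#' @param x A `coexpression_network` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.coexpression_network <- function(x, ...) {
  tibble(
    n_genes = length(attr(x, "genes")),
    n_pairs_evaluated = attr(x, "n_pairs"),
    n_positive = sum(x$sign_class == "positive"),
    n_negative = sum(x$sign_class == "negative"),
    pos_threshold = attr(x, "pos_threshold"),
    neg_threshold = attr(x, "neg_threshold")
  )
}

#' @describeIn build_network `autoplot()` draws the network on a circular
#'   layout: red edges positive, blue edges negative.
#' @param object A `coexpression_network` object.
#' @exportS3Method ggplot2::autoplot
autoplot.coexpression_network <- function(object, ...) {
  genes <- sort(unique(c(object$gene_a, object$gene_b)))
  theta <- seq(0, 2 * pi, length.out = length(genes) + 1L)[seq_along(genes)]
  layout <- tibble(gene = genes, gx = cos(theta), gy = sin(theta))
  seg <- as_tibble(object) |>
    left_join(rename(layout, xa = "gx", ya = "gy"), by = c(gene_a = "gene")) |>
    left_join(rename(layout, xb = "gx", yb = "gy"), by = c(gene_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   colour = .data$sign_class, linewidth = abs(.data$pcc)),
      alpha = 0.7
    ) +
    ggplot2::geom_point(data = layout, ggplot2::aes(x = .data$gx, y = .data$gy)) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.12 * .data$gx, y = 1.12 * .data$gy,
                                    label = .data$gene), size = 3) +
    ggplot2::scale_colour_manual(values = c(positive = "firebrick", negative = "steelblue")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "co-expression", title = "Pearson co-expression network")
}

#' Export a co-expression network
#'
#' Writes the edge list either as TSV (`gene_a`, `gene_b`, `pcc`,
#' `sign_class`; header always written, so an empty network gives a
#' header-only file) or as Cytoscape-readable SIF with relation tokens
#' `pos` / `neg`. Edges are written in their deterministic
#' `(gene_a, gene_b)` order.
#'
#' @param edges A `coexpression_network` (or compatible) edge tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- arrange(as_tibble(edges), .data$gene_a, .data$gene_b)
  if (format == "tsv") {
    readr::write_tsv(edges[, c("gene_a", "gene_b", "pcc", "sign_class")], path)
  } else {
    rel <- ifelse(edges$sign_class == "positive", "pos", "neg")
    writeLines(sprintf("%s %s %s", edges$gene_a, rel, edges$gene_b), con = path)
  }
  invisible(path)
}

#' Read a network edge-list TSV written by [export_network()]
#'
#' @param path TSV path.
#' @return Edge tibble (`gene_a`, `gene_b`, `pcc`, `sign_class`).
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    pcc = readr::col_double(),
    sign_class = readr::col_character()
  ))
}
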