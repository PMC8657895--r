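#' Read a gene x sample FPKM matrix from TSV
#'
#' @param path Tab-separated file: header row of sample names, first column
#'   gene identifiers, remaining columns non-negative FPKM values.
#' @return Tibble with first column `gene_id` and one numeric column per
#'   sample.
#' @export
read_fpkm <- function(path) {
  em <- readr::read_tsv(path, show_col_types = FALSE)
  names(em)[1] <- "gene_id"
  em$gene_id <- as.character(em$gene_id)
  .check_fpkm(em)
}

.check_fpkm <- function(em) {
  stopifnot(is.data.frame(em))
  if (names(em)[1] != "gene_id") {
    abort("FPKM table must have `gene_id` as its first column.")
  }
  if (ncol(em) < 2L) abort("FPKM table has no sample columns.")
  if (anyDuplicated(em$gene_id)) abort("Duplicate gene ids in FPKM table.")
  if (anyDuplicated(names(em))) abort("Duplicate sample names in FPKM table.")
  vals <- as.matrix(em[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) abort("FPKM values must be numeric and non-missing.")
  if (any(vals < 0)) abort("FPKM values must be non-negative.")
  as_tibble(em)
}

.fpkm_matrix <- function(em) {
  m <- as.matrix(em[, -1, drop = FALSE])
  rownames(m) <- em$gene_id
  m
}

#' Filter genes by minimum expression breadth
#'
#' Keeps genes expressed at or above `min_fpkm` in at least `min_samples`
#' samples. The defaults implement the usual cutoff for calling a gene
#' expressed across a 26-tissue panel: at least 0.05 FPKM in more than six
#' (i.e. >= 7) tissues.
#'
#' @param em FPKM tibble (`gene_id` + sample columns).
#' @param min_fpkm Expression threshold in FPKM (default 0.05).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 7).
#' @return The filtered tibble, gene order preserved. Warns (does not error)
#'   when no gene survives. Idempotent.
#' @export
expression_filter <- function(em, min_fpkm = 0.05, min_samples = 7L) {
  em <- .check_fpkm(em)
  n_samples <- ncol(em) - 1L
  if (min_samples > n_samples) {
    abort(sprintf("`min_samples` (%d) exceeds the number of samples (%d).",
                  min_samples, n_samples))
  }
  m <- .fpkm_matrix(em)
  keep <- rowSums(m >= min_fpkm) >= min_samples
  if (!any(keep)) {
    warn("No genes pass the expression filter.")
  }
  em[keep, , drop = FALSE]
}

#' Log-scale an FPKM matrix for heatmap display
#'
#' Applies `log2(FPKM + 1)`, a monotone transform that maps 0 to 0.
#'
#' @inheritParams expression_filter
#' @return Tibble of the same shape with transformed values.
#' @export
heatmap_matrix <- function(em) {
  em <- .check_fpkm(em)
  mutate(em, across(-"gene_id", ~ log2(.x + 1)))
}

#' Plot a log2 expression heatmap
#'
#' @param hm Output of [heatmap_matrix()] (or any `gene_id` + numeric
#'   columns tibble).
#' @return A ggplot tile plot.
#' @export
plot_expression_heatmap <- function(hm) {
  long <- tidyr::pivot_longer(hm, -"gene_id", names_to = "sample", values_to = "log2_fpkm")
  long$gene_id <- factor(long$gene_id, levels = rev(unique(hm$gene_id)))
  long$sample <- factor(long$sample, levels = setdiff(names(hm), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$log2_fpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2(FPKM+1)",
                  title = "Expression across samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fold change between treated and control expression
#'
#' Computes `fc = (treated + pseudocount) / (control + pseudocount)` and
#' calls the direction with a symmetric two-fold rule: `up` when
#' `fc >= up_threshold`, `down` when `fc <= 1/up_threshold`, otherwise
#' `unchanged`. The pseudocount keeps ratios finite when the control is
#' zero, as happens for genes silent under control conditions but strongly
#' induced by stress.
#'
#' @param control,treated Non-negative FPKM values (vectors are paired
#'   element-wise).
#' @param pseudocount Added to both numerator and denominator; must be
#'   positive when either value can be zero. Default 0.1 FPKM.
#' @param up_threshold Fold-change call threshold (default 2).
#' @return Tibble with columns `control`, `treated`, `fc` (> 0) and
#'   `direction`.
#' @examples
#' fold_change(2, 8, pseudocount = 0)   # fc 4, up
#' fold_change(0, 10)                   # fc 101, up
#' @export
fold_change <- function(control, treated, pseudocount = 0.1, up_threshold = 2) {
  if (length(control) != length(treated)) abort("`control` and `treated` lengths differ.")
  if (anyNA(control) || anyNA(treated) || any(!is.finite(control)) || any(!is.finite(treated))) {
    abort("Expression values must be finite and non-missing.")
  }
  if (any(control < 0) || any(treated < 0)) abort("Expression values must be non-negative.")
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  if (pseudocount == 0 && any(control == 0 | treated == 0)) {
    abort("`pseudocount` must be positive when values can be zero.")
  }
  fc <- (treated + pseudocount) / (control + pseudocount)
  tibble(
    control = control,
    treated = treated,
    fc = fc,
    direction = dplyr::case_when(
      fc >= up_threshold ~ "up",
      fc <= 1 / up_threshold ~ "down",
      TRUE ~ "unchanged"
    )
  )
}

#' Call stress-responsive genes by fold change
#'
#' For each treatment condition x timepoint, replicate FPKM values are
#' averaged (arithmetic mean), compared to the matched control at the same
#' timepoint, and genes are called up/down by the two-fold rule of
#' [fold_change()]. Genes whose maximum FPKM across all samples is below
#' `low_expr` are flagged too low for analysis and excluded from calls
#' (direction `NA`).
#'
#' @param em FPKM tibble (`gene_id` + one column per sample).
#' @param design Tibble mapping samples to the experiment: columns `sample`,
#'   `condition` (controls labelled `control_label`), `timepoint`,
#'   `replicate`.
#' @param pseudocount,up_threshold Passed to [fold_change()].
#' @param low_expr Low-expression cutoff in FPKM (default 1).
#' @param control_label Condition label identifying control samples.
#' @return A `stress_response` tibble: one row per gene x condition x
#'   timepoint with `gene_id`, `condition`, `timepoint`, `control_mean`,
#'   `treated_mean`, `fc`, `direction` and `low_expression_flag`.
#' @export
stress_response_table <- function(em, design, pseudocount = 0.1, up_threshold = 2,
                                  low_expr = 1, control_label = "control") {
  em <- .check_fpkm(em)
  design <- as_tibble(design)
  need <- c("sample", "condition", "timepoint", "replicate")
  if (!all(need %in% names(design))) {
    abort(sprintf("`design` must have columns %s.", paste(need, collapse = ", ")))
  }
  missing_samples <- setdiff(design$sample, names(em))
  if (length(missing_samples) > 0L) {
    abort(sprintf("Design sample(s) absent from the FPKM table: %s.",
                  paste(missing_samples, collapse = ", ")))
  }
  if (!any(design$condition == control_label)) {
    abort(sprintf("No control samples (condition == \"%s\") in the design.", control_label))
  }

  m <- .fpkm_matrix(em)[, design$sample, drop = FALSE]
  too_low <- unname(apply(m, 1L, max) < low_expr)

  groups <- distinct(design, .data$condition, .data$timepoint)
  means <- map(seq_len(nrow(groups)), function(g) {
    sel <- design$sample[design$condition == groups$condition[g] &
                           design$timepoint == groups$timepoint[g]]
    rowMeans(m[, sel, drop = FALSE])
  })
  names(means) <- paste(groups$condition, groups$timepoint, sep = "\r")

  trt <- filter(groups, .data$condition != control_label)
  rows <- map(seq_len(nrow(trt)), function(g) {
    cond <- trt$condition[g]; tp <- trt$timepoint[g]
    ctrl_key <- paste(control_label, tp, sep = "\r")
    if (!ctrl_key %in% names(means)) {
      abort(sprintf("Condition \"%s\" at %s has no matched control.", cond, tp))
    }
    fcs <- fold_change(means[[ctrl_key]], means[[paste(cond, tp, sep = "\r")]],
                       pseudocount = pseudocount, up_threshold = up_threshold)
    tibble(
      gene_id = em$gene_id,
      condition = cond,
      timepoint = tp,
      control_mean = fcs$control,
      treated_mean = fcs$treated,
      fc = fcs$fc,
      direction = ifelse(too_low, NA_character_, fcs$direction),
      low_expression_flag = too_low
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("stress_response", class(out))
  out
}

#' @describeIn stress_response_table `autoplot()` draws a gene x condition
#'   tile map of log2 fold changes (crossed-out tiles: too low for
#'   analysis).
#' @param object A `stress_response` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.stress_response <- function(object, ...) {
  df <- mutate(as_tibble(object),
               cell = paste(.data$condition, .data$timepoint),
               log2fc = ifelse(.data$low_expression_flag, NA_real_, log2(.data$fc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene_id, fill = .data$log2fc)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC",
                  title = "Stress response relative to control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an FPKM-shaped tibble to TSV
#'
#' @param em Tibble with `gene_id` + value columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(em, path) {
  readr::write_tsv(em, path)
  invisible(path)
}
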