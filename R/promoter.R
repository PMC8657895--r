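.iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Default cis-acting element table
#'
#' The stress- and hormone-responsive promoter elements scanned in CAD
#' gene-family studies: ABRE, CGTCA-motif, GARE-motif, LTR, MBS, MRE, MYB,
#' P-box, TCA-element, TCT-motif and TGACG-motif. The consensus sequences
#' shipped here are PlantCARE-derived defaults — reasonable working
#' consensi, not fixed facts — and can be replaced wholesale via
#' [read_cis_elements()] or by passing any tibble with the same columns.
#'
#' @param path Optional TSV with columns `name`, `consensus`, `note`
#'   overriding the built-in table.
#' @return Tibble with columns `name` (unique), `consensus` (IUPAC DNA) and
#'   `note`.
#' @export
cad_cis_elements <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_cis_elements(path))
  }
  read_cis_elements(system.file("extdata", "cis_elements.tsv", package = "cadfam",
                                mustWork = TRUE))
}

#' Read a cis-element table from TSV
#'
#' @param path TSV with columns `name`, `consensus`, `note`.
#' @return Validated element tibble (see [cad_cis_elements()]).
#' @export
read_cis_elements <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("name", "consensus") %in% names(tab))) {
    abort("Element table must have columns `name` and `consensus`.")
  }
  if (!("note" %in% names(tab))) tab$note <- NA_character_
  .check_elements(tab)
  as_tibble(tab[, c("name", "consensus", "note")])
}

.check_elements <- function(elements) {
  if (anyDuplicated(elements$name)) {
    abort(sprintf("Duplicate element names: %s.",
                  paste(unique(elements$name[duplicated(elements$name)]), collapse = ", ")))
  }
  cons <- toupper(elements$consensus)
  if (any(is.na(cons) | !nzchar(cons))) abort("Element consensi must be non-empty.")
  ok <- names(.iupac_sets())
  for (i in seq_along(cons)) {
    bad <- setdiff(strsplit(cons[i], "", fixed = TRUE)[[1]], ok)
    if (length(bad) > 0L) {
      abort(sprintf("Element \"%s\" consensus contains non-IUPAC character(s): %s.",
                    elements$name[i], paste(bad, collapse = ", ")))
    }
  }
  invisible(elements)
}

# base x code match table; subject N matches only consensus N
.iupac_match_table <- function() {
  sets <- .iupac_sets()
  bases <- c("A", "C", "G", "T", "N")
  tab <- matrix(FALSE, nrow = length(bases), ncol = length(sets),
                dimnames = list(bases, names(sets)))
  for (code in names(sets)) {
    tab[sets[[code]], code] <- TRUE
  }
  tab["N", ] <- FALSE
  tab["N", "N"] <- TRUE
  tab
}

# all exact forward-orientation matches of one consensus in a char vector
.match_consensus <- function(chars, consensus, tab) {
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  len <- length(cons)
  n_win <- length(chars) - len + 1L
  if (n_win < 1L) return(integer())
  ok <- rep(TRUE, n_win)
  for (k in seq_len(len)) {
    ok <- ok & tab[cbind(chars[seq_len(n_win) + k - 1L], cons[k])]
  }
  which(ok)
}

#' Scan a promoter sequence for cis-acting elements
#'
#' Reports every exact IUPAC-consensus match of each configured element on
#' the requested strand(s). Minus-strand hits are found by matching the
#' reverse complement of the consensus against the given sequence and are
#' reported in forward coordinates (`start` is the leftmost base of the
#' matched window on the supplied strand); `matched_sequence` is given in
#' element orientation, i.e. reverse-complemented for minus-strand hits.
#' An N in the promoter matches only an N in the consensus. Overlapping
#' matches are all reported.
#'
#' @param sequence Promoter DNA string over A/C/G/T/N (case-insensitive);
#'   conventionally a 2 kb upstream region.
#' @param elements Element table (see [cad_cis_elements()]).
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble sorted by `(start, element)` with columns `element`,
#'   `start` (1-based), `strand` and `matched_sequence`.
#' @examples
#' scan_promoter("AACGTCATT", strands = "both")
#' @export
scan_promoter <- function(sequence, elements = cad_cis_elements(),
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  .check_elements(elements)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    abort(sprintf("Promoter sequence contains invalid character(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  tab <- .iupac_match_table()

  rows <- list()
  for (i in seq_len(nrow(elements))) {
    cons <- toupper(elements$consensus[i])
    len <- nchar(cons)
    fwd <- .match_consensus(chars, cons, tab)
    if (length(fwd) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        element = elements$name[i], start = fwd, strand = "+",
        matched_sequence = substring(s, fwd, fwd + len - 1L)
      )
    }
    if (strands == "both") {
      rev_hits <- .match_consensus(chars, .revcomp(cons), tab)
      if (length(rev_hits) > 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          element = elements$name[i], start = rev_hits, strand = "-",
          matched_sequence = vapply(
            substring(s, rev_hits, rev_hits + len - 1L), .revcomp, character(1),
            USE.NAMES = FALSE
          )
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(element = character(), start = integer(),
                  strand = character(), matched_sequence = character()))
  }
  out <- list_rbind(rows)
  out$start <- as.integer(out$start)
  arrange(out, .data$start, .data$element)
}

#' Scan a set of promoters
#'
#' @param promoters Data frame with columns `id` and `sequence`, e.g. read
#'   with [read_promoter_fasta()].
#' @inheritParams scan_promoter
#' @return Tibble of hits with a leading `gene_id` column, one block per
#'   promoter in input order.
#' @export
scan_promoter_set <- function(promoters, elements = cad_cis_elements(),
                              strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(is.data.frame(promoters), all(c("id", "sequence") %in% names(promoters)))
  rows <- map(seq_len(nrow(promoters)), function(i) {
    hits <- scan_promoter(promoters$sequence[[i]], elements = elements, strands = strands)
    if (nrow(hits) > 0L) mutate(hits, gene_id = as.character(promoters$id[[i]]), .before = 1L)
    else NULL
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(gene_id = character(), element = character(), start = integer(),
                  strand = character(), matched_sequence = character()))
  }
  out
}

#' Read promoter sequences from FASTA
#'
#' @param path DNA FASTA, one record per gene.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_promoter_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate ids in FASTA \"%s\".", path))
  }
  tibble(id = ids, sequence = toupper(as.character(set)))
}

#' Tabulate element hits into a gene x element count matrix
#'
#' @param hits Hit table from [scan_promoter_set()].
#' @param genes Character vector of gene ids defining the rows (keeps
#'   all-zero rows for genes without hits); defaults to the genes present in
#'   `hits`.
#' @param elements Element table defining the columns; defaults to
#'   [cad_cis_elements()].
#' @return Tibble with `gene_id` and one non-negative integer count column
#'   per element; row sums equal the number of hits per gene.
#' @export
element_count_matrix <- function(hits, genes = NULL, elements = cad_cis_elements()) {
  genes <- genes %||% unique(hits$gene_id)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(elements),
                   dimnames = list(genes, elements$name))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$gene_id, levels = genes),
                 factor(hits$element, levels = elements$name))
    counts[] <- as.integer(tab)
  }
  bind_cols(tibble(gene_id = genes), as_tibble(counts))
}

#' Plot a gene x element count matrix
#'
#' Bubble plot of per-gene cis-element counts, the usual way promoter scans
#' of gene families are summarized.
#'
#' @param counts Output of [element_count_matrix()].
#' @return A ggplot object.
#' @export
plot_element_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, -"gene_id",
                              names_to = "element", values_to = "count")
  ggplot2::ggplot(filter(long, .data$count > 0),
                  ggplot2::aes(x = .data$element, y = .data$gene_id,
                               size = .data$count, colour = .data$element)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = NULL, size = "occurrences",
                  title = "Cis-acting elements in promoter regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
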