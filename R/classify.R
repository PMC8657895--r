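#' Scan a protein for windows matching a signature-site pattern
#'
#' Slides the fixed-span pattern window along the sequence and reports every
#' start position at which the number of mismatched literal positions is at
#' most `max_mismatch`. Wildcard positions accept any residue (including the
#' unknown residue X); an X in the protein at a literal position always counts
#' as a mismatch (conservative classification).
#'
#' @param sequence Amino-acid string (20 standard letters plus X,
#'   case-insensitive).
#' @param pattern A [parse_site_pattern()] object.
#' @param max_mismatch Mismatch budget at literal positions; must be smaller
#'   than the number of literal positions in the pattern.
#'
#' @return Tibble with one row per matching window, sorted by
#'   `(mismatches, start)`: columns `pattern_name`, `start` (1-based),
#'   `mismatches`, `matched_subsequence`. Proteins shorter than the pattern
#'   span yield zero rows.
#' @examples
#' pat <- parse_site_pattern("GHE(X)2G(X)5V", "catalytic_zn")
#' scan_sites("GHEKLGSTACDV", pat, max_mismatch = 0)
#' @export
scan_sites <- function(sequence, pattern, max_mismatch = 2L) {
  stopifnot(inherits(pattern, "site_pattern"))
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L) {
    abort("`max_mismatch` must be a non-negative integer.")
  }
  if (max_mismatch >= pattern$n_literal) {
    abort(sprintf(
      "`max_mismatch` (%d) must be smaller than the number of literal positions (%d) in pattern \"%s\".",
      max_mismatch, pattern$n_literal, pattern$raw
    ))
  }
  seq_u <- .check_protein_seq(sequence)
  chars <- strsplit(seq_u, "", fixed = TRUE)[[1]]

  empty <- tibble(
    pattern_name = character(), start = integer(),
    mismatches = integer(), matched_subsequence = character()
  )
  mism <- .window_mismatches(chars, pattern)
  if (length(mism) == 0L) {
    return(empty)
  }

  hit <- which(mism <= max_mismatch)
  if (length(hit) == 0L) {
    return(empty)
  }
  out <- tibble(
    pattern_name = pattern$name,
    start = hit,
    mismatches = as.integer(mism[hit]),
    matched_subsequence = substring(seq_u, hit, hit + pattern$span - 1L)
  )
  arrange(out, .data$mismatches, .data$start)
}

# literal-position mismatch count for every window of the pattern span;
# integer(0) when the sequence is shorter than the span
.window_mismatches <- function(chars, pattern) {
  n_win <- length(chars) - pattern$span + 1L
  if (n_win < 1L) return(integer())
  idx <- outer(seq_len(n_win) - 1L, pattern$literal_pos, "+")
  obs <- matrix(chars[idx], nrow = n_win)
  rowSums(obs != matrix(pattern$literal_res, nrow = n_win,
                        ncol = pattern$n_literal, byrow = TRUE))
}

.check_tolerance <- function(tolerance, patterns) {
  nm <- names(patterns)
  if (anyDuplicated(nm)) {
    abort(sprintf("Duplicate pattern names: %s.",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(tolerance) == 1L && is.null(names(tolerance))) {
    tolerance <- setNames(rep(as.integer(tolerance), length(nm)), nm)
  } else {
    if (is.null(names(tolerance)) || !setequal(names(tolerance), nm)) {
      abort("A per-site `tolerance` must be named after the patterns.")
    }
    tolerance <- setNames(as.integer(tolerance[nm]), nm)
  }
  if (anyNA(tolerance) || any(tolerance < 0L)) {
    abort("`tolerance` entries must be non-negative integers.")
  }
  tolerance
}

#' Classify proteins as CAD-family members by their signature sites
#'
#' A protein is called CAD when all three signature sites — catalytic
#' Zn-binding, structural Zn-binding and NADP(H)-binding — are each present
#' within the per-site mismatch tolerance. For each site the best match
#' (fewest mismatched literal positions; ties broken by smallest start) is
#' reported as evidence.
#'
#' @param proteins Data frame with columns `id` and `sequence` (one row per
#'   protein; ids must be unique).
#' @param patterns Named list of [parse_site_pattern()] objects; default the
#'   three CAD sites from [cad_site_patterns()].
#' @param tolerance Mismatch budget: a single integer applied to every site,
#'   or a named integer vector with one budget per pattern. The default of 2
#'   accepts sites carrying minor mutations.
#'
#' @return A `cad_classification` tibble with one row per protein, in input
#'   order: `protein_id`, `is_cad`, and per pattern `<name>_start`,
#'   `<name>_mismatches` (NA when the site is absent at that budget). The
#'   tolerance used is stored in the `tolerance` attribute.
#' @seealso [classify_fasta()] to read proteins from a FASTA file,
#'   [scan_sites()] for the underlying window scan.
#' @examples
#' prot <- tibble::tibble(
#'   id = "toy",
#'   sequence = strrep("A", 30)
#' )
#' classify_proteins(prot, tolerance = 1)
#' @export
classify_proteins <- function(proteins, patterns = cad_site_patterns(), tolerance = 2L) {
  if (!is.data.frame(proteins) || !all(c("id", "sequence") %in% names(proteins))) {
    abort("`proteins` must be a data frame with columns `id` and `sequence`.")
  }
  ids <- as.character(proteins$id)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate protein ids: %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tolerance <- .check_tolerance(tolerance, patterns)

  n <- length(ids)
  nms <- names(patterns)
  starts <- matrix(NA_integer_, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  mms <- starts
  for (i in seq_len(n)) {
    chars <- strsplit(.check_protein_seq(proteins$sequence[[i]], ids[i]), "",
                      fixed = TRUE)[[1]]
    for (k in seq_along(patterns)) {
      mism <- .window_mismatches(chars, patterns[[k]])
      ok <- which(mism <= tolerance[[k]])
      if (length(ok) > 0L) {
        best <- ok[which.min(mism[ok])]  # fewest mismatches, then smallest start
        starts[i, k] <- best
        mms[i, k] <- as.integer(mism[best])
      }
    }
  }
  evid <- setNames(
    vector("list", 2L * length(nms)),
    as.vector(rbind(paste0(nms, "_start"), paste0(nms, "_mismatches")))
  )
  for (k in seq_along(nms)) {
    evid[[paste0(nms[k], "_start")]] <- unname(starts[, k])
    evid[[paste0(nms[k], "_mismatches")]] <- unname(mms[, k])
  }
  out <- bind_cols(
    tibble(protein_id = ids, is_cad = rowSums(!is.na(starts)) == length(nms)),
    as_tibble(evid)
  )
  if (n == 0L) {
    out <- tibble(protein_id = character(), is_cad = logical())
  }
  attr(out, "tolerance") <- tolerance
  class(out) <- c("cad_classification", class(out))
  out
}

#' Classify all proteins in a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-FASTA of amino-acid sequences and
#' classifies each record with [classify_proteins()].
#'
#' @inheritParams classify_proteins
#' @param path Path to a readable FASTA file.
#' @return See [classify_proteins()]; rows follow file order.
#' @export
classify_fasta <- function(path, patterns = cad_site_patterns(), tolerance = 2L) {
  proteins <- read_protein_fasta(path)
  classify_proteins(proteins, patterns = patterns, tolerance = tolerance)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence` (upper case).
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate ids in FASTA \"%s\": %s.", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, sequence = toupper(as.character(set)))
}

#' Write the accepted (CAD-positive) proteins to FASTA
#'
#' @param classification A `cad_classification` table.
#' @param proteins The data frame of `id`/`sequence` that was classified.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_accepted_fasta <- function(classification, proteins, path) {
  keep <- classification$protein_id[classification$is_cad]
  sel <- proteins[match(keep, as.character(proteins$id)), , drop = FALSE]
  set <- Biostrings::AAStringSet(setNames(toupper(sel$sequence), sel$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @describeIn classify_proteins `tidy()` returns one row per protein per
#'   site with the match evidence in long form.
#' @param x A `cad_classification` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cad_classification <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x),
    cols = -c("protein_id", "is_cad"),
    names_to = c("site", ".value"),
    names_pattern = "^(.*)_(start|mismatches)$"
  )
  arrange(long, match(.data$protein_id, x$protein_id))
}

#' @describeIn classify_proteins `glance()` returns a one-row summary:
#'   number of proteins, number classified CAD, and the tolerance budgets.
#' @exportS3Method generics::glance
glance.cad_classification <- function(x, ...) {
  tol <- attr(x, "tolerance")
  tibble(
    n_proteins = nrow(x),
    n_cad = sum(x$is_cad),
    tolerance = paste(names(tol), tol, sep = "=", collapse = ", ")
  )
}

#' @describeIn classify_proteins `autoplot()` draws a per-protein, per-site
#'   tile map of mismatch counts (grey tiles: site absent at the budget).
#' @param object A `cad_classification` object.
#' @exportS3Method ggplot2::autoplot
autoplot.cad_classification <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$protein_id,
                                     fill = .data$mismatches)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", direction = -1) +
    ggplot2::labs(x = "signature site", y = NULL, fill = "mismatches",
                  title = "Signature-site evidence per protein") +
    ggplot2::theme_minimal()
}

#' Write a classification table to TSV
#'
#' @param classification A `cad_classification` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  readr::write_tsv(as_tibble(classification), path)
  invisible(path)
}
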