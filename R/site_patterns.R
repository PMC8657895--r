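#' Parse a degenerate signature-site pattern
#'
#' CAD signature sites are written as short degenerate patterns: literal
#' residues interleaved with fixed-length wildcard runs, e.g. the catalytic
#' Zn-binding site `"GHE(X)2G(X)5V"`. The grammar is:
#'
#' * an upper-case residue letter (one of the 20 standard amino acids) is a
#'   literal position;
#' * `"(X)n"` is a wildcard run of exactly `n` positions; `"(X)"` with no
#'   count and a bare `"X"` are wildcard runs of length 1;
#' * hyphens are typographic separators and are stripped.
#'
#' Wildcard runs are exact-length: the pattern describes a fixed-span window,
#' and only literal positions can mismatch.
#'
#' @param raw Pattern string, e.g. `"GD(X)10C(X)2C(X)7C"`.
#' @param name Optional pattern name (e.g. `"catalytic_zn"`).
#'
#' @return An object of class `site_pattern`: a list with elements `name`,
#'   `raw` (the normalized pattern string), `span` (total window length),
#'   `literal_pos` (1-based positions of literal residues within the window),
#'   `literal_res` (the residue expected at each literal position) and
#'   `n_literal`.
#' @examples
#' p <- parse_site_pattern("GHE(X)2G(X)5V", name = "catalytic_zn")
#' p$span        # 12
#' p$literal_pos # 1 2 3 6 12
#' @export
parse_site_pattern <- function(raw, name = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    abort("`raw` must be a single non-empty pattern string.")
  }
  src <- gsub("-", "", raw, fixed = TRUE)
  if (!nzchar(src)) {
    abort("Pattern contains no residues or wildcards after stripping hyphens.")
  }

  aa <- .aa_letters()
  pos <- 1L
  literal_pos <- integer()
  literal_res <- character()
  span <- 0L
  norm <- character()

  while (pos <= nchar(src)) {
    ch <- substr(src, pos, pos)
    if (ch == "(") {
      rest <- substr(src, pos, nchar(src))
      grp <- regmatches(rest, regexpr("^\\(X\\)[0-9]*", rest))
      if (length(grp) == 0L) {
        bad <- substr(src, pos, min(nchar(src), pos + 3L))
        abort(sprintf("Malformed wildcard group at \"%s\" in pattern \"%s\".", bad, raw))
      }
      ndig <- nchar(grp) - 3L
      run <- if (ndig > 0L) as.integer(substr(grp, 4L, nchar(grp))) else 1L
      if (run < 1L) {
        abort(sprintf("Wildcard run \"%s\" must have length >= 1 in pattern \"%s\".", grp, raw))
      }
      span <- span + run
      norm <- c(norm, if (run == 1L) "X" else paste0("(X)", run))
      pos <- pos + nchar(grp)
    } else if (ch == "X") {
      span <- span + 1L
      norm <- c(norm, "X")
      pos <- pos + 1L
    } else if (ch %in% aa) {
      span <- span + 1L
      literal_pos <- c(literal_pos, span)
      literal_res <- c(literal_res, ch)
      norm <- c(norm, ch)
      pos <- pos + 1L
    } else {
      abort(sprintf("Invalid character \"%s\" at position %d of pattern \"%s\".", ch, pos, raw))
    }
  }
  if (length(literal_pos) == 0L) {
    abort(sprintf("Pattern \"%s\" has no literal positions.", raw))
  }

  structure(
    list(
      name = name %||% NA_character_,
      raw = paste(norm, collapse = ""),
      span = span,
      literal_pos = literal_pos,
      literal_res = literal_res,
      n_literal = length(literal_pos)
    ),
    class = "site_pattern"
  )
}

#' @export
format.site_pattern <- function(x, ...) {
  sprintf(
    "<site_pattern %s: \"%s\" (span %d, %d literal positions)>",
    if (is.na(x$name)) "?" else x$name, x$raw, x$span, x$n_literal
  )
}

#' @export
print.site_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Default CAD signature-site patterns
#'
#' The three signature sites whose joint presence defines CAD-family
#' membership: the catalytic Zn-binding site, the structural Zn-binding site
#' and the NADP(H)-binding site.
#'
#' @param catalytic_zn,structural_zn,nadph Pattern strings; the defaults are
#'   the published CAD consensus sites.
#' @return Named list of three [parse_site_pattern()] objects, in the order
#'   catalytic_zn, structural_zn, nadph.
#' @examples
#' vapply(cad_site_patterns(), function(p) p$span, integer(1))
#' @export
cad_site_patterns <- function(catalytic_zn = "GHE(X)2G(X)5V",
                              structural_zn = "GD(X)10C(X)2C(X)7C",
                              nadph = "G(X)3G(X)2GLGG(X)GH(X)2VK(X)2K(X)2G-(X)VTV(X)S(X)S(X)2K") {
  list(
    catalytic_zn = parse_site_pattern(catalytic_zn, name = "catalytic_zn"),
    structural_zn = parse_site_pattern(structural_zn, name = "structural_zn"),
    nadph = parse_site_pattern(nadph, name = "nadph")
  )
}

.aa_letters <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Normalize and validate a protein sequence; returns uppercase string.
.check_protein_seq <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort(sprintf("Protein sequence%s must be a single non-empty string.",
                  if (is.null(id)) "" else paste0(" for \"", id, "\"")))
  }
  s <- toupper(sequence)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", s)) {
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), c(.aa_letters(), "X"))
    abort(sprintf("Protein sequence%s contains invalid characters: %s.",
                  if (is.null(id)) "" else paste0(" \"", id, "\""),
                  paste(bad, collapse = ", ")))
  }
  s
}
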