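#' Synthetic data generators with ground-truth ledgers
#'
#' Every generator in this family is a pure function of its parameters and
#' `seed` (identical calls give byte-identical output) and returns, next to
#' the generated data, a ledger recording exactly what was planted. The
#' ledger fully determines the expected output of the downstream module, so
#' each pipeline stage can be tested without external genome or
#' transcriptome downloads.
#'
#' @name synthetic_data
NULL

.derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

.random_aa <- function(n) {
  sample(.aa_letters(), n, replace = TRUE)
}

# does any window match the pattern with at most `budget` literal mismatches?
# deliberately a plain loop with early exit, independent of the vectorized scanner
.has_window_within <- function(chars, pattern, budget) {
  n_win <- length(chars) - pattern$span + 1L
  if (n_win < 1L) return(FALSE)
  for (s in seq_len(n_win)) {
    m <- 0L
    for (k in seq_along(pattern$literal_pos)) {
      if (chars[s + pattern$literal_pos[k] - 1L] != pattern$literal_res[k]) {
        m <- m + 1L
        if (m > budget) break
      }
    }
    if (m <= budget) return(TRUE)
  }
  FALSE
}

# realize a signature site: literals in place, wildcards random, then mutate
# `n_mut` distinct literal positions to a different residue
.realize_site <- function(pattern, n_mut) {
  site <- .random_aa(pattern$span)
  site[pattern$literal_pos] <- pattern$literal_res
  if (n_mut > 0L) {
    mut_at <- sample(pattern$literal_pos, n_mut)
    for (p in mut_at) {
      site[p] <- sample(setdiff(.aa_letters(), site[p]), 1L)
    }
  }
  site
}

#' Simulate a protein family with planted CAD signature sites
#'
#' Positives carry all three signature sites (catalytic Zn-binding,
#' structural Zn-binding, NADP(H)-binding) at recorded positions, each with a
#' recorded number of literal-position mutations drawn uniformly from
#' `0:max_mismatch`. Decoys carry two intact sites but lack the third: its
#' region is random background, re-sampled until no window of the destroyed
#' pattern matches within `max_mismatch` mismatches, so decoys are negatives
#' at any tolerance up to that budget.
#'
#' @param n_pos,n_decoy Number of positive / decoy proteins.
#' @param max_mismatch Maximum planted mutations per site (and the budget
#'   beyond which decoys are guaranteed clean). Default 2.
#' @param backbone_length Protein length; must accommodate the three site
#'   spans plus at least one spacer residue between and around sites.
#' @param seed RNG seed.
#' @param patterns Signature patterns; default [cad_site_patterns()].
#'
#' @return List with `proteins` (tibble `id`, `sequence`), `ledger` (tibble
#'   `id`, `is_cad`, `site`, `planted`, `position`, `mismatches`) and `seed`.
#' @examples
#' fam <- make_protein_family(3, 3, seed = 1)
#' table(fam$ledger$is_cad[!duplicated(fam$ledger$id)])
#' @export
make_protein_family <- function(n_pos, n_decoy, max_mismatch = 2L,
                                backbone_length = 360L, seed = 1L,
                                patterns = cad_site_patterns()) {
  spans <- vapply(patterns, function(p) p$span, integer(1))
  n_sites <- length(patterns)
  min_len <- sum(spans) + n_sites + 1L
  if (backbone_length < min_len) {
    abort(sprintf("`backbone_length` (%d) too short: need >= %d for the %d sites plus spacing.",
                  backbone_length, min_len, n_sites))
  }
  max_mismatch <- as.integer(max_mismatch)

  withr::with_seed(as.integer(seed), {
    make_one <- function(id, destroyed_site) {
      # choose non-overlapping site starts with random spacing, in pattern order
      slack <- backbone_length - sum(spans)
      cuts <- sort(sample.int(slack - 1L, n_sites))
      gaps <- c(cuts[1], diff(cuts))  # gap before each site, >= 0 after -1 shift
      gaps <- gaps - 1L
      gaps[1] <- gaps[1] + 1L
      starts <- integer(n_sites)
      pos <- 1L
      for (k in seq_len(n_sites)) {
        pos <- pos + gaps[k]
        starts[k] <- pos
        pos <- pos + spans[k]
      }

      repeat {
        chars <- .random_aa(backbone_length)
        planted <- rep(TRUE, n_sites)
        position <- starts
        mismatches <- integer(n_sites)
        for (k in seq_len(n_sites)) {
          nm <- names(patterns)[k]
          if (identical(nm, destroyed_site)) {
            planted[k] <- FALSE
            position[k] <- NA_integer_
            mismatches[k] <- NA_integer_
          } else {
            n_mut <- sample(0:max_mismatch, 1L)
            site <- .realize_site(patterns[[k]], n_mut)
            chars[starts[k]:(starts[k] + spans[k] - 1L)] <- site
            mismatches[k] <- n_mut
          }
        }
        if (is.null(destroyed_site)) break
        # decoy: destroyed site must not appear anywhere within the budget
        if (!.has_window_within(chars, patterns[[destroyed_site]], max_mismatch)) break
      }
      list(
        protein = tibble(id = id, sequence = paste(chars, collapse = "")),
        ledger = tibble(id = id, is_cad = is.null(destroyed_site),
                        site = names(patterns), planted = planted,
                        position = position, mismatches = mismatches)
      )
    }

    pos <- map(seq_len(n_pos), function(i) make_one(sprintf("POS%03d", i), NULL))
    dec <- map(seq_len(n_decoy), function(i) {
      destroyed <- names(patterns)[((i - 1L) %% n_sites) + 1L]
      make_one(sprintf("DEC%03d", i), destroyed)
    })
    all <- c(pos, dec)
    list(
      proteins = list_rbind(map(all, "protein")),
      ledger = list_rbind(map(all, "ledger")),
      seed = as.integer(seed)
    )
  })
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Tibble with columns `id` and `sequence` (amino acid or DNA).
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- switch(type,
    AA = Biostrings::AAStringSet(setNames(records$sequence, records$id)),
    DNA = Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  )
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Evolve an alignment along a phylogeny
#'
#' Simulates i.i.d. alignment columns down a tree under a simple
#' Poisson-style substitution contract: along a branch of length `b`
#' (substitutions per site), each site is hit with probability
#' `1 - exp(-b)` and, when hit, redrawn uniformly from the 20 amino acids,
#' so the expected difference from the parent is `(1 - exp(-b)) * 19/20`
#' and saturates at 19/20 on long branches. The root sequence is uniform
#' over the 20 residues. No indels are introduced, so the result is a
#' gap-free alignment.
#'
#' @param tree An [ape::phylo] tree with branch lengths (rooted or unrooted;
#'   an unrooted tree is traversed from its basal node).
#' @param n_columns Number of alignment columns.
#' @param seed RNG seed.
#' @return Tibble with columns `id` (tip labels) and `sequence`, all of
#'   length `n_columns`.
#' @export
evolve_alignment <- function(tree, n_columns, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("`tree` must have branch lengths.")
  n_columns <- as.integer(n_columns)
  stopifnot(n_columns >= 1L)

  withr::with_seed(as.integer(seed), {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    aa <- .aa_letters()
    seqs <- matrix(NA_integer_, nrow = n_node, ncol = n_columns)
    root <- n_tip + 1L
    seqs[root, ] <- sample.int(20L, n_columns, replace = TRUE)

    ord <- ape::reorder.phylo(tree, "cladewise")
    eo <- order(match(
      paste(tree$edge[, 1], tree$edge[, 2]),
      paste(ord$edge[, 1], ord$edge[, 2])
    ))
    for (e in eo) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      s <- seqs[parent, ]
      sub <- runif(n_columns) < (1 - exp(-b))
      if (any(sub)) {
        s[sub] <- sample.int(20L, sum(sub), replace = TRUE)
      }
      seqs[child, ] <- s
    }
    tibble(
      id = tree$tip.label,
      sequence = vapply(seq_len(n_tip),
                        function(i) paste(aa[seqs[i, ]], collapse = ""),
                        character(1))
    )
  })
}

#' Simulate a tissue FPKM matrix with block-correlated modules
#'
#' Genes are generated from a latent-factor model: within each module, gene
#' latents are `loading * factor + noise`, with the loading chosen so the
#' pairwise within-module correlation on the latent (log) scale equals the
#' target exactly in expectation. Latents are standardized and mapped to the
#' FPKM scale as `2^(log2_mean + log2_sd * z)`, giving non-negative,
#' heavy-tailed values like real FPKM. Optional background genes are
#' independent, and optional low-expression genes (all values below 0.05
#' FPKM) are planted for filter tests.
#'
#' @param modules Tibble or data frame with columns `size` and `rho`
#'   (within-module latent correlation, in (0, 1)); one row per module.
#' @param n_samples Number of samples (default 26, a typical multi-tissue
#'   panel).
#' @param noise_sd Gene-level noise standard deviation on the latent scale.
#' @param n_background Number of uncorrelated background genes.
#' @param n_low_expr Number of planted genes failing the 0.05-FPKM filter.
#' @param log2_mean,log2_sd Location/scale of expressed genes on the log2
#'   FPKM scale. Exponentiation attenuates a latent correlation `rho` to
#'   `(exp(rho * a^2) - 1) / (exp(a^2) - 1)` with `a = log2_sd * ln 2`, so
#'   the default `log2_sd = 1` keeps the FPKM-scale correlation close to the
#'   latent target (0.9 maps to about 0.88) while still giving a skewed,
#'   non-negative FPKM-like distribution.
#' @param seed RNG seed.
#' @return List with `fpkm` (tibble: `gene_id` + one column per sample),
#'   `ledger` (tibble `gene_id`, `module` — background NA, `"low"` for
#'   planted low-expression genes — and `rho`), and `seed`.
#' @export
make_expression_matrix <- function(modules, n_samples = 26L, noise_sd = 1,
                                   n_background = 0L, n_low_expr = 0L,
                                   log2_mean = 3, log2_sd = 1, seed = 1L) {
  modules <- as_tibble(modules)
  stopifnot(all(c("size", "rho") %in% names(modules)))
  if (any(modules$rho <= 0 | modules$rho >= 1)) {
    abort("Module correlations `rho` must lie in (0, 1).")
  }

  withr::with_seed(as.integer(seed), {
    samples <- sprintf("S%02d", seq_len(n_samples))
    blocks <- list()
    ledger <- list()
    gi <- 0L
    for (m in seq_len(nrow(modules))) {
      size <- modules$size[m]
      rho <- modules$rho[m]
      f <- rnorm(n_samples)
      if (noise_sd == 0) {
        # noiseless limit: every gene is the factor itself, within-module PCC 1
        z <- vapply(seq_len(size), function(g) f, numeric(n_samples))
      } else {
        loading <- sqrt(rho / (1 - rho)) * noise_sd
        lat <- vapply(seq_len(size),
                      function(g) loading * f + rnorm(n_samples, sd = noise_sd),
                      numeric(n_samples))
        z <- lat / sqrt(loading^2 + noise_sd^2)
      }
      ids <- sprintf("G%04d", gi + seq_len(size))
      gi <- gi + size
      blocks[[length(blocks) + 1L]] <- t(2^(log2_mean + log2_sd * z))
      ledger[[length(ledger) + 1L]] <-
        tibble(gene_id = ids, module = sprintf("M%02d", m), rho = rho)
    }
    if (n_background > 0L) {
      z <- matrix(rnorm(n_background * n_samples), nrow = n_background)
      ids <- sprintf("G%04d", gi + seq_len(n_background))
      gi <- gi + n_background
      blocks[[length(blocks) + 1L]] <- 2^(log2_mean + log2_sd * z)
      ledger[[length(ledger) + 1L]] <-
        tibble(gene_id = ids, module = NA_character_, rho = NA_real_)
    }
    if (n_low_expr > 0L) {
      vals <- matrix(runif(n_low_expr * n_samples, 0, 0.049), nrow = n_low_expr)
      ids <- sprintf("G%04d", gi + seq_len(n_low_expr))
      blocks[[length(blocks) + 1L]] <- vals
      ledger[[length(ledger) + 1L]] <-
        tibble(gene_id = ids, module = "low", rho = NA_real_)
    }
    ledger <- list_rbind(ledger)
    mat <- do.call(rbind, blocks)
    colnames(mat) <- samples
    fpkm <- bind_cols(tibble(gene_id = ledger$gene_id), as_tibble(mat))
    list(fpkm = fpkm, ledger = ledger, seed = as.integer(seed))
  })
}

#' Simulate a control/treatment stress experiment with planted fold changes
#'
#' Generates replicate FPKM values for a control and a set of stress
#' treatments at given timepoints. Each gene has a lognormal baseline;
#' treated samples of genes listed in `plantings` are scaled by the planted
#' fold. Optional low-expression genes (all values below `low_expr` FPKM)
#' are planted to exercise the too-low-for-analysis flag.
#'
#' @param n_genes Number of regular genes.
#' @param conditions Treatment condition names (controls are generated per
#'   timepoint under condition `"control"`).
#' @param timepoints Timepoint labels.
#' @param n_reps Biological replicates per condition x timepoint.
#' @param plantings Tibble with columns `gene` (index into regular genes),
#'   `condition`, `timepoint`, `fold` (> 0); all other gene x condition cells
#'   stay at baseline (fold 1).
#' @param n_low_expr Number of planted low-expression genes.
#' @param rep_cv Multiplicative replicate noise (sd of log2 values).
#' @param low_expr Ceiling for planted low-expression genes (default just
#'   under 1 FPKM).
#' @param seed RNG seed.
#' @return List with `fpkm` (tibble `gene_id` + sample columns), `design`
#'   (tibble `sample`, `condition`, `timepoint`, `replicate`), `ledger`
#'   (the plantings with gene ids, plus low-expression genes), and `seed`.
#' @export
make_stress_experiment <- function(n_genes = 20L,
                                   conditions = c("NaCl", "PEG", "SA", "ABA"),
                                   timepoints = c("3h", "24h"),
                                   n_reps = 3L,
                                   plantings = NULL,
                                   n_low_expr = 0L,
                                   rep_cv = 0.15,
                                   low_expr = 0.9,
                                   seed = 1L) {
  if (!is.null(plantings)) {
    plantings <- as_tibble(plantings)
    stopifnot(all(c("gene", "condition", "timepoint", "fold") %in% names(plantings)))
    if (any(plantings$fold <= 0)) abort("Planted folds must be positive.")
    bad <- setdiff(plantings$condition, conditions)
    if (length(bad)) abort(sprintf("Unknown planted condition(s): %s.", paste(bad, collapse = ", ")))
  }

  withr::with_seed(as.integer(seed), {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    base <- 2^rnorm(n_genes, mean = 4, sd = 1)  # comfortably above the low-expression cutoff

    design <- tidyr::expand_grid(
      condition = c("control", conditions),
      timepoint = timepoints,
      replicate = seq_len(n_reps)
    )
    design$sample <- sprintf("%s_%s_r%d", design$condition, design$timepoint, design$replicate)
    design <- select(design, "sample", "condition", "timepoint", "replicate")

    fold_of <- function(g, cond, tp) {
      if (is.null(plantings)) return(1)
      hit <- plantings$gene == g & plantings$condition == cond & plantings$timepoint == tp
      if (any(hit)) plantings$fold[which(hit)[1]] else 1
    }
    mat <- vapply(seq_len(nrow(design)), function(j) {
      cond <- design$condition[j]
      tp <- design$timepoint[j]
      vapply(seq_len(n_genes), function(g) {
        f <- if (cond == "control") 1 else fold_of(g, cond, tp)
        base[g] * f * 2^rnorm(1, sd = rep_cv)
      }, numeric(1))
    }, numeric(n_genes))
    colnames(mat) <- design$sample

    ledger <- if (is.null(plantings)) {
      tibble(gene_id = character(), condition = character(),
             timepoint = character(), fold = numeric())
    } else {
      mutate(plantings, gene_id = gene_ids[.data$gene], .before = 1L) |>
        select("gene_id", "condition", "timepoint", "fold")
    }

    if (n_low_expr > 0L) {
      low_ids <- sprintf("LOW%03d", seq_len(n_low_expr))
      low <- matrix(runif(n_low_expr * nrow(design), 0, low_expr),
                    nrow = n_low_expr, dimnames = list(NULL, design$sample))
      mat <- rbind(mat, low)
      gene_ids <- c(gene_ids, low_ids)
    }

    fpkm <- bind_cols(tibble(gene_id = gene_ids), as_tibble(mat))
    list(fpkm = fpkm, design = design, ledger = ledger, seed = as.integer(seed))
  })
}

#' Simulate promoter sequences with planted cis-elements
#'
#' Generates uniform-A/C/G/T background promoters and plants concrete
#' realizations of IUPAC element consensi at recorded positions and strands.
#' A minus-strand planting inserts the reverse complement of the realized
#' consensus, so scanning both strands recovers it at the recorded forward
#' coordinate.
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in bp (default 2000, i.e. a 2 kb upstream
#'   region).
#' @param plantings Tibble with columns `gene` (index), `element` (name found
#'   in `elements`), `position` (1-based start on the forward strand) and
#'   `strand` (`"+"` or `"-"`). Plantings within a gene must not overlap.
#' @param elements Element table as in [cad_cis_elements()]; supplies the
#'   consensus for each planted element.
#' @param seed RNG seed.
#' @return List with `promoters` (tibble `id`, `sequence`), `ledger` (the
#'   plantings with gene ids and the realized planted sequence), and `seed`.
#' @export
make_promoters <- function(n_genes, length = 2000L, plantings = NULL,
                           elements = cad_cis_elements(), seed = 1L) {
  length <- as.integer(length)
  if (!is.null(plantings)) {
    plantings <- as_tibble(plantings)
    stopifnot(all(c("gene", "element", "position", "strand") %in% names(plantings)))
    bad <- setdiff(plantings$element, elements$name)
    if (base::length(bad)) abort(sprintf("Unknown element(s): %s.", paste(bad, collapse = ", ")))
    if (!all(plantings$strand %in% c("+", "-"))) abort("`strand` must be \"+\" or \"-\".")
    cons_len <- nchar(elements$consensus[match(plantings$element, elements$name)])
    if (any(plantings$position < 1L | plantings$position + cons_len - 1L > length)) {
      abort("Planted element(s) do not fit inside the promoter.")
    }
    for (g in unique(plantings$gene)) {
      p <- plantings[plantings$gene == g, ]
      l <- cons_len[plantings$gene == g]
      o <- order(p$position)
      if (any(p$position[o][-1] <= (p$position[o] + l[o] - 1L)[-nrow(p)])) {
        abort(sprintf("Overlapping plantings in gene %s.", g))
      }
    }
  }

  withr::with_seed(as.integer(seed), {
    ids <- sprintf("PROM%03d", seq_len(n_genes))
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))

    ledger <- tibble(gene_id = character(), element = character(),
                     position = integer(), strand = character(),
                     planted_sequence = character())
    if (!is.null(plantings) && nrow(plantings) > 0L) {
      rows <- vector("list", nrow(plantings))
      for (r in seq_len(nrow(plantings))) {
        g <- plantings$gene[r]
        cons <- elements$consensus[match(plantings$element[r], elements$name)]
        concrete <- .realize_iupac(cons)
        insert <- if (plantings$strand[r] == "-") .revcomp(concrete) else concrete
        s <- seqs[g]
        pos <- plantings$position[r]
        substr(s, pos, pos + nchar(insert) - 1L) <- insert
        seqs[g] <- s
        rows[[r]] <- tibble(
          gene_id = ids[g], element = plantings$element[r],
          position = as.integer(pos), strand = plantings$strand[r],
          planted_sequence = concrete
        )
      }
      ledger <- list_rbind(rows)
    }
    list(promoters = tibble(id = ids, sequence = seqs),
         ledger = ledger, seed = as.integer(seed))
  })
}

# draw one concrete DNA string compatible with an IUPAC consensus
.realize_iupac <- function(consensus) {
  codes <- .iupac_sets()
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- codes[[ch]]
    if (is.null(opts)) abort(sprintf("Non-IUPAC character \"%s\" in consensus.", ch))
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}
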