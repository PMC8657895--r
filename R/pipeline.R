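.default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    inputs = list(
      proteins = NULL, alignment = NULL, promoters = NULL,
      expression = NULL, stress_expression = NULL, stress_design = NULL,
      seed_genes = NULL
    ),
    classifier = list(
      tolerance = 2L,
      catalytic_zn = "GHE(X)2G(X)5V",
      structural_zn = "GD(X)10C(X)2C(X)7C",
      nadph = "G(X)3G(X)2GLGG(X)GH(X)2VK(X)2K(X)2G-(X)VTV(X)S(X)S(X)2K"
    ),
    phylogeny = list(
      model = "poisson",
      gap_handling = "pairwise",
      bootstrap_replicates = 1000L
    ),
    promoter = list(elements = NULL, strands = "both"),
    expression = list(min_fpkm = 0.05, min_samples = 7L),
    stress = list(fold_change = 2, pseudocount = 0.1, low_expression = 1,
                  control_label = "control"),
    network = list(pos_threshold = 0.7, neg_threshold = -0.5)
  )
}

.config_error <- function(msg) {
  abort(msg, class = "cadfam_config_error")
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, merges it over the documented defaults and
#' validates it. Unknown keys (at the top level or within a section) are
#' rejected, as are thresholds outside their documented ranges.
#'
#' @param path YAML file path, or a list to validate directly.
#' @return Validated config list with all defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) .config_error(sprintf("Config file \"%s\" not found.", path))
    yaml::read_yaml(path)
  }
  defaults <- .default_config()

  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    .config_error(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  for (sec in names(user)) {
    if (is.list(defaults[[sec]]) && is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(bad) > 0L) {
        .config_error(sprintf("Unknown key(s) in section \"%s\": %s.",
                              sec, paste(bad, collapse = ", ")))
      }
      defaults[[sec]] <- modifyList(defaults[[sec]], user[[sec]])
    } else {
      defaults[[sec]] <- user[[sec]]
    }
  }
  validate_pipeline_config(defaults)
}

#' @rdname read_pipeline_config
#' @param config Config list (as returned by [read_pipeline_config()]).
#' @export
validate_pipeline_config <- function(config) {
  chk <- function(ok, msg) if (!isTRUE(ok)) .config_error(msg)
  chk(is.numeric(config$seed) && config$seed == as.integer(config$seed),
      "`seed` must be an integer.")
  net <- config$network
  chk(net$pos_threshold > 0 && net$pos_threshold <= 1,
      "`network$pos_threshold` must lie in (0, 1].")
  chk(net$neg_threshold < 0 && net$neg_threshold >= -1,
      "`network$neg_threshold` must lie in [-1, 0).")
  chk(config$expression$min_fpkm >= 0, "`expression$min_fpkm` must be >= 0.")
  chk(config$expression$min_samples >= 1, "`expression$min_samples` must be >= 1.")
  chk(config$stress$fold_change > 1, "`stress$fold_change` must be > 1.")
  chk(config$stress$pseudocount >= 0, "`stress$pseudocount` must be >= 0.")
  chk(config$stress$low_expression >= 0, "`stress$low_expression` must be >= 0.")
  chk(config$phylogeny$model %in% c("poisson", "p"),
      "`phylogeny$model` must be \"poisson\" or \"p\".")
  chk(config$phylogeny$gap_handling %in% c("pairwise", "complete"),
      "`phylogeny$gap_handling` must be \"pairwise\" or \"complete\".")
  chk(config$phylogeny$bootstrap_replicates >= 1,
      "`phylogeny$bootstrap_replicates` must be >= 1.")
  chk(config$promoter$strands %in% c("both", "forward"),
      "`promoter$strands` must be \"both\" or \"forward\".")
  chk(is.numeric(config$classifier$tolerance) && all(config$classifier$tolerance >= 0),
      "`classifier$tolerance` must be >= 0.")
  config
}

#' Run the CAD-family analysis pipeline end to end
#'
#' Executes every stage whose inputs are configured — classification,
#' phylogeny with bootstrap, promoter element scan, expression filtering and
#' heatmap preparation, stress fold-change calling, co-expression network —
#' and writes the stage outputs plus a run manifest into `output_dir`.
#' Stages without configured inputs are skipped. All randomness (the
#' bootstrap) derives from the single top-level `seed`, so reruns with the
#' same config produce identical stage outputs (the manifest additionally
#' records a timestamp). A stage failure aborts the run naming the stage;
#' outputs of completed stages are retained next to a `FAILED` marker file.
#'
#' @param config Path to a YAML config, or a config list; see
#'   [read_pipeline_config()].
#' @param output_dir Output directory (created if needed); overrides
#'   `config$output_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (stages run, outputs, parameters).
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  config <- read_pipeline_config(config)
  out <- output_dir %||% config$output_dir
  if (is.null(out)) .config_error("An output directory is required (`output_dir`).")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  say <- function(stage, msg) if (!quiet) inform(sprintf("[%s] %s", stage, msg))

  stage_seeds <- .derive_seeds(as.integer(config$seed), 6L)
  manifest <- list(
    package = "cadfam",
    version = as.character(packageVersion("cadfam")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = as.integer(config$seed),
    parameters = config[setdiff(names(config), c("output_dir"))],
    stages = list()
  )
  outputs <- character()

  run_stage <- function(stage, f) {
    res <- tryCatch(f(), error = function(e) {
      writeLines(c(stage, conditionMessage(e)), file.path(out, "FAILED"))
      abort(sprintf("Pipeline stage \"%s\" failed: %s", stage, conditionMessage(e)),
            class = "cadfam_stage_error")
    })
    manifest$stages[[stage]] <<- res
    outputs <<- c(outputs, unlist(res))
    say(stage, "done")
  }

  inp <- config$inputs

  if (!is.null(inp$proteins)) {
    run_stage("identify", function() {
      patterns <- cad_site_patterns(
        catalytic_zn = config$classifier$catalytic_zn,
        structural_zn = config$classifier$structural_zn,
        nadph = config$classifier$nadph
      )
      proteins <- read_protein_fasta(inp$proteins)
      cls <- classify_proteins(proteins, patterns,
                               tolerance = unlist(config$classifier$tolerance))
      write_classification(cls, file.path(out, "classification.tsv"))
      write_accepted_fasta(cls, proteins, file.path(out, "accepted_proteins.fasta"))
      list(classification = "classification.tsv", accepted = "accepted_proteins.fasta")
    })
  }

  if (!is.null(inp$alignment)) {
    run_stage("tree", function() {
      aln <- read_alignment(inp$alignment)
      dm <- pairwise_distance(aln, model = config$phylogeny$model,
                              gap_handling = config$phylogeny$gap_handling)
      write_distance_matrix(dm, file.path(out, "distances.tsv"))
      bs <- bootstrap_support(aln, replicates = config$phylogeny$bootstrap_replicates,
                              model = config$phylogeny$model,
                              seed = stage_seeds[2],
                              gap_handling = config$phylogeny$gap_handling)
      write_newick(bs, file.path(out, "tree.nwk"))
      list(distances = "distances.tsv", tree = "tree.nwk")
    })
  }

  if (!is.null(inp$promoters)) {
    run_stage("promoters", function() {
      elements <- if (is.null(config$promoter$elements)) cad_cis_elements()
                  else read_cis_elements(config$promoter$elements)
      promoters <- read_promoter_fasta(inp$promoters)
      hits <- scan_promoter_set(promoters, elements = elements,
                                strands = config$promoter$strands)
      readr::write_tsv(hits, file.path(out, "promoter_hits.tsv"))
      counts <- element_count_matrix(hits, genes = promoters$id, elements = elements)
      readr::write_tsv(counts, file.path(out, "promoter_element_counts.tsv"))
      list(hits = "promoter_hits.tsv", counts = "promoter_element_counts.tsv")
    })
  }

  filtered <- NULL
  if (!is.null(inp$expression)) {
    run_stage("expression", function() {
      em <- read_fpkm(inp$expression)
      filtered <<- expression_filter(em, min_fpkm = config$expression$min_fpkm,
                                     min_samples = config$expression$min_samples)
      write_fpkm(filtered, file.path(out, "expression_filtered.tsv"))
      write_fpkm(heatmap_matrix(filtered), file.path(out, "heatmap_matrix.tsv"))
      list(filtered = "expression_filtered.tsv", heatmap = "heatmap_matrix.tsv")
    })
  }

  if (!is.null(inp$stress_expression) && !is.null(inp$stress_design)) {
    run_stage("stress", function() {
      em <- read_fpkm(inp$stress_expression)
      design <- readr::read_tsv(inp$stress_design, col_types = readr::cols())
      tab <- stress_response_table(
        em, design,
        pseudocount = config$stress$pseudocount,
        up_threshold = config$stress$fold_change,
        low_expr = config$stress$low_expression,
        control_label = config$stress$control_label
      )
      readr::write_tsv(as_tibble(tab), file.path(out, "stress_fold_changes.tsv"))
      list(fold_changes = "stress_fold_changes.tsv")
    })
  }

  if (!is.null(filtered)) {
    run_stage("coexpress", function() {
      seed_genes <- if (!is.null(inp$seed_genes)) readLines(inp$seed_genes) else NULL
      edges <- withCallingHandlers(
        build_network(filtered,
                      pos_threshold = config$network$pos_threshold,
                      neg_threshold = config$network$neg_threshold,
                      seed_genes = seed_genes),
        message = function(m) if (quiet) invokeRestart("muffleMessage")
      )
      export_network(edges, file.path(out, "network_edges.tsv"), format = "tsv")
      export_network(edges, file.path(out, "network.sif"), format = "sif")
      list(edges = "network_edges.tsv", sif = "network.sif")
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  if (!quiet) inform(sprintf("Pipeline complete: %d stage(s), outputs in %s",
                             length(manifest$stages), out))
  invisible(manifest)
}
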