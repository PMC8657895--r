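# build a complete small synthetic fixture set on disk
make_fixture_dir <- function(dir, seed = 101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- make_protein_family(4, 4, seed = seed)
  write_fasta(fam$proteins, file.path(dir, "proteins.fasta"))
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.5,(C:0.2,D:0.2):0.5,(E:0.2,F:0.2):0.5);")
  write_fasta(evolve_alignment(tr, 200, seed = seed + 1), file.path(dir, "alignment.fasta"))
  pr <- make_promoters(3, 600,
                       plantings = tibble::tibble(gene = 1:3, element = "ABRE",
                                                  position = c(50L, 150L, 250L),
                                                  strand = c("+", "-", "+")),
                       seed = seed + 2)
  write_fasta(pr$promoters, file.path(dir, "promoters.fasta"), type = "DNA")
  ex <- make_expression_matrix(tibble::tibble(size = c(5, 5), rho = c(0.9, 0.85)),
                               n_low_expr = 2, seed = seed + 3)
  write_fpkm(ex$fpkm, file.path(dir, "expression.tsv"))
  st <- make_stress_experiment(n_genes = 6,
                               plantings = tibble::tibble(gene = 1:2, condition = "NaCl",
                                                          timepoint = "24h",
                                                          fold = c(4, 0.2)),
                               seed = seed + 4)
  write_fpkm(st$fpkm, file.path(dir, "stress.tsv"))
  readr::write_tsv(st$design, file.path(dir, "design.tsv"))
  list(
    seed = 5,
    inputs = list(
      proteins = file.path(dir, "proteins.fasta"),
      alignment = file.path(dir, "alignment.fasta"),
      promoters = file.path(dir, "promoters.fasta"),
      expression = file.path(dir, "expression.tsv"),
      stress_expression = file.path(dir, "stress.tsv"),
      stress_design = file.path(dir, "design.tsv")
    ),
    phylogeny = list(bootstrap_replicates = 30)
  )
}
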