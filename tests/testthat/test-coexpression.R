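test_that("pearson matches hand values and the two-pass formula oracle", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84), tolerance = 1e-15)

  withr::with_seed(101, {
    for (rep in 1:200) {
      x <- rnorm(26); y <- rnorm(26)
      expect_equal(pearson(x, y), oracle_pcc(x, y), tolerance = 1e-12)
      expect_lte(abs(pearson(x, y)), 1 + 1e-12)
    }
  })

  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), ">= 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero-variance")
})

test_that("PCCs are invariant to sample permutation", {
  withr::with_seed(6, {
    x <- runif(26); y <- runif(26)
    perm <- sample(26)
    expect_equal(pearson(x, y), pearson(x[perm], y[perm]), tolerance = 1e-12)
  })
})

two_module_em <- function(seed, size = 6, rho = 0.9) {
  make_expression_matrix(tibble::tibble(size = c(size, size), rho = c(rho, rho)),
                         n_samples = 26, seed = seed)
}

test_that("build_network classifies pairs by the inclusive 0.7 / -0.5 thresholds", {
  ex <- two_module_em(42)
  net <- suppressMessages(build_network(ex$fpkm))
  g <- glance(net)
  expect_equal(g$n_pairs_evaluated, choose(12, 2))
  expect_true(all(net$pcc[net$sign_class == "positive"] >= 0.7))
  expect_true(all(net$pcc[net$sign_class == "negative"] <= -0.5))
  expect_true(all(net$gene_a < net$gene_b))
  expect_false(any(net$gene_a == net$gene_b))

  # duplicated profiles give one perfect positive edge
  em <- ex$fpkm[1:2, ]
  em[2, -1] <- em[1, -1]
  em$gene_id <- c("dupA", "dupB")
  net2 <- suppressMessages(build_network(em))
  expect_equal(nrow(net2), 1L)
  expect_equal(net2$pcc, 1)
  expect_equal(net2$sign_class, "positive")

  # extreme thresholds empty the network on noisy data
  net3 <- suppressMessages(build_network(ex$fpkm, 0.999999, -0.999999))
  expect_equal(nrow(net3), 0L)

  expect_error(suppressMessages(build_network(ex$fpkm, pos_threshold = 1.5)), "Thresholds")
  expect_error(suppressMessages(build_network(ex$fpkm[1, ])), "at least 2 genes")
})

test_that("raising the positive threshold never adds edges", {
  ex <- two_module_em(7)
  nets <- lapply(c(0.5, 0.7, 0.9), function(th) {
    suppressMessages(build_network(ex$fpkm, pos_threshold = th))
  })
  keys <- lapply(nets, function(n) paste(n$gene_a, n$gene_b)[n$sign_class == "positive"])
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_true(all(keys[[3]] %in% keys[[2]]))
})

test_that("zero-variance genes are skipped with a warning, not an error", {
  ex <- two_module_em(3)
  em <- dplyr::bind_rows(ex$fpkm, tibble::tibble(gene_id = "flat",
                                                 !!!setNames(as.list(rep(1, 26)),
                                                             names(ex$fpkm)[-1])))
  expect_warning(net <- suppressMessages(build_network(em)), "flat")
  expect_false("flat" %in% c(net$gene_a, net$gene_b))
})

test_that("seed-gene mode restricts evaluation to seed x universe pairs", {
  ex <- two_module_em(11)
  seeds <- ex$fpkm$gene_id[1:2]
  net <- suppressMessages(build_network(ex$fpkm, seed_genes = seeds))
  expect_true(all(net$gene_a %in% seeds | net$gene_b %in% seeds))
  n_genes <- nrow(ex$fpkm)
  expect_equal(glance(net)$n_pairs_evaluated, 2L * (n_genes - 2L) + 1L)
})

test_that("planted modules come back as the network's connected components", {
  skip_if_not_installed("igraph")
  ok <- 0L
  for (seed in 1:30) {
    ex <- two_module_em(seed)
    net <- suppressMessages(build_network(ex$fpkm))
    pos <- net[net$sign_class == "positive", ]
    g <- igraph::graph_from_data_frame(pos[, c("gene_a", "gene_b")], directed = FALSE,
                                       vertices = ex$fpkm$gene_id)
    comp <- igraph::components(g)$membership
    planted <- split(ex$ledger$gene_id, ex$ledger$module)
    found <- split(names(comp), comp)
    same <- length(found) == length(planted) &&
      setequal(lapply(found, sort), lapply(planted, sort))
    ok <- ok + same
  }
  expect_gte(ok, 28L)
})

test_that("network export is deterministic and round-trips", {
  ex <- two_module_em(5)
  net <- suppressMessages(build_network(ex$fpkm))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv)
  expect_equal(as.data.frame(back), as.data.frame(net[, 1:4]), tolerance = 1e-12,
               ignore_attr = TRUE)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net))
  rel <- ifelse(net$sign_class == "positive", "pos", "neg")
  expect_equal(lines, sprintf("%s %s %s", net$gene_a, rel, net$gene_b))

  # byte-stable across repeated export
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv2, "tsv")
  expect_identical(readLines(tsv), readLines(tsv2))

  # empty network still writes a header in TSV mode
  empty <- suppressMessages(build_network(ex$fpkm, 0.999999, -0.999999))
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, tsv3, "tsv")
  expect_equal(readLines(tsv3), "gene_a\tgene_b\tpcc\tsign_class")
  expect_s3_class(autoplot(net), "ggplot")
})
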