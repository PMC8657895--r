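test_that("pairwise distances implement p and Poisson models with pairwise deletion", {
  aln <- tibble::tibble(id = c("a", "b"), sequence = c("AAAA", "AAAT"))
  expect_equal(pairwise_distance(aln, model = "p")["a", "b"], 0.25)

  aln2 <- tibble::tibble(id = c("a", "b"), sequence = c("AAAA", "TTAA"))
  expect_equal(pairwise_distance(aln2, model = "poisson")["a", "b"], -log(0.5))

  ident <- tibble::tibble(id = c("a", "b", "c"), sequence = rep("ACDEF", 3))
  expect_true(all(pairwise_distance(ident) == 0))

  # pairwise deletion: gapped columns dropped per pair
  gap <- tibble::tibble(id = c("a", "b"), sequence = c("A-CD", "AACC"))
  expect_equal(pairwise_distance(gap, model = "p")["a", "b"], 1 / 3)
  # complete deletion drops the gapped column for everyone
  expect_equal(pairwise_distance(gap, model = "p", gap_handling = "complete")["a", "b"], 1 / 3)

  # saturation and no-shared-column errors name the pair
  sat <- tibble::tibble(id = c("a", "b"), sequence = c("AAAA", "TTTT"))
  expect_error(pairwise_distance(sat, model = "poisson"), "Saturated.*\"a\".*\"b\"")
  disj <- tibble::tibble(id = c("a", "b"), sequence = c("AA--", "--AA"))
  expect_error(pairwise_distance(disj), "No shared")
})

test_that("neighbor joining is exact on a hand-checked additive matrix", {
  labs <- LETTERS[1:4]
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_equal(path_metric(tr, labs), d, tolerance = 1e-12)
  expect_equal(split_set(tr), "C|D")  # the AB|CD split, anchored at A's side complement
  # leaf and internal edge lengths: 1, 2, 3, 4 and 1
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))
})

test_that("the three-taxon tree uses the closed-form star solution", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[labs], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("degenerate equidistant input joins the lowest-index pair and yields a zero internal edge", {
  labs <- LETTERS[1:4]
  d <- matrix(2, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr <- neighbor_joining(d)
  expect_equal(split_set(tr), "C|D")  # A,B joined first
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 0)
  expect_equal(path_metric(tr, labs)[upper.tri(d)], d[upper.tri(d)])
})

test_that("malformed distance matrices are rejected", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3, dimnames = list(labs, labs))
  expect_error(neighbor_joining(d), "symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))),
               "at least 3")
})

test_that("NJ reproduces random additive metrics and their topologies", {
  withr::with_seed(2024, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      ad <- rand_additive(n)
      tr <- neighbor_joining(ad$dm)
      expect_equal(path_metric(tr, rownames(ad$dm)), ad$dm, tolerance = 1e-9)
      expect_identical(split_set(tr), split_set(ad$tree))
    }
  })
})

test_that("NJ matches the exhaustive least-squares topology oracle on additive inputs", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      n <- sample(5:6, 1)
      ad <- rand_additive(n)
      expect_identical(split_set(neighbor_joining(ad$dm)), ls_best_splits(ad$dm))
    }
  })
})

test_that("NJ agrees with an independent reference implementation", {
  withr::with_seed(3191, {
    for (rep in 1:10) {
      ad <- rand_additive(6)
      ours <- neighbor_joining(ad$dm)
      ref <- ape::nj(as.dist(ad$dm))
      expect_identical(split_set(ours), split_set(ref))
      expect_equal(sort(ours$edge.length), sort(ref$edge.length), tolerance = 1e-9)
    }
  })
})

test_that("Newick output round-trips topology, lengths and supports", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      ad <- rand_additive(6)
      tr <- neighbor_joining(ad$dm)
      f <- withr::local_tempfile(fileext = ".nwk")
      write_newick(tr, f)
      back <- ape::read.tree(f)
      expect_identical(split_set(back), split_set(tr))
      expect_equal(path_metric(back, rownames(ad$dm)), path_metric(tr, rownames(ad$dm)),
                   tolerance = 1e-9)
    }
  })
  # labels with Newick metacharacters survive NJ and are quoted on output
  labs <- c("a b", "c:d", "e(f)", "plain")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr_meta <- neighbor_joining(d)
  expect_setequal(tr_meta$tip.label, labs)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr_meta, f)
  txt <- readLines(f)
  expect_true(grepl("'a b'", txt, fixed = TRUE))
  expect_true(grepl("'e(f)'", txt, fixed = TRUE))
  expect_false(grepl("'plain'", txt, fixed = TRUE))

  expect_error(write_newick(NULL, tempfile()), "non-empty")
})

strong_tree <- ape::read.tree(
  text = "((A:0.2,B:0.2):0.6,(C:0.2,D:0.2):0.6,(E:0.2,F:0.2):0.6);"
)

test_that("a perfectly separating alignment gets 100% support", {
  aln <- tibble::tibble(
    id = c("A", "B", "C", "D"),
    sequence = c(paste0(strrep("A", 30), "C"), paste0(strrep("A", 30), "D"),
                 paste0(strrep("W", 30), "C"), paste0(strrep("W", 30), "Y"))
  )
  bs <- bootstrap_support(aln, replicates = 100, model = "p", seed = 1)
  expect_equal(nrow(bs$support), 1L)
  expect_equal(bs$support$support, 100)
  expect_equal(bs$n_skipped, 0L)

  # a single replicate can only give 0 or 100
  bs1 <- bootstrap_support(aln, replicates = 1, model = "p", seed = 3)
  expect_true(all(bs1$support$support %in% c(0, 100)))
})

test_that("bootstrap is deterministic under a fixed seed and invariant to taxon order", {
  aln <- evolve_alignment(strong_tree, 300, seed = 8)
  b1 <- bootstrap_support(aln, replicates = 40, seed = 10)
  b2 <- bootstrap_support(aln, replicates = 40, seed = 10)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  perm <- aln[c(4, 2, 6, 1, 3, 5), ]
  b3 <- bootstrap_support(perm, replicates = 40, seed = 10)
  expect_equal(dplyr::arrange(b1$support, bipartition),
               dplyr::arrange(b3$support, bipartition))
})

test_that("simulation along a known tree recovers its bipartitions", {
  aln <- evolve_alignment(strong_tree, 500, seed = 21)
  bs <- bootstrap_support(aln, replicates = 100, seed = 22)
  expect_setequal(bs$support$bipartition, split_set(strong_tree))
  # supports land on the tree as internal node labels
  expect_true(all(nzchar(bs$tree$node.label[-1])))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bs, f)
  back <- ape::read.tree(f)
  expect_setequal(as.numeric(back$node.label[nzchar(back$node.label)]),
                  bs$support$support)
  # tidy/glance accessors
  expect_identical(tidy(bs), bs$support)
  expect_equal(glance(bs)$replicates, 100L)
})
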