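pat_cat <- parse_site_pattern("GHE(X)2G(X)5V", "catalytic_zn")

test_that("scan_sites finds exact and single-substitution planted sites", {
  hits <- scan_sites("GHEKLGSTACDV", pat_cat, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$matched_subsequence, "GHEKLGSTACDV")

  # H -> Q substitution: found at budget 1, absent at budget 0
  expect_equal(scan_sites("GQEKLGSTACDV", pat_cat, max_mismatch = 1)$mismatches, 1L)
  expect_equal(nrow(scan_sites("GQEKLGSTACDV", pat_cat, max_mismatch = 0)), 0L)

  # all five literals wrong
  expect_equal(nrow(scan_sites(strrep("A", 12), pat_cat, max_mismatch = 1)), 0L)

  # shorter than the span: empty, not an error
  expect_equal(nrow(scan_sites("GHEKL", pat_cat, max_mismatch = 0)), 0L)
})

test_that("scan_sites treats wildcards and unknown residues as specified", {
  # wildcard positions accept anything, including X
  expect_equal(scan_sites("GHEXXGXXXXXV", pat_cat, max_mismatch = 0)$mismatches, 0L)
  # X at a literal position always counts as a mismatch
  expect_equal(scan_sites("XHEKLGSTACDV", pat_cat, max_mismatch = 1)$mismatches, 1L)
  # case-insensitive
  expect_identical(scan_sites("gheklgstacdv", pat_cat, 0),
                   scan_sites("GHEKLGSTACDV", pat_cat, 0))
  # budget must stay below the number of literal positions
  expect_error(scan_sites("GHEKLGSTACDV", pat_cat, max_mismatch = 5), "smaller than")
})

test_that("scan_sites agrees with the exhaustive window oracle on short proteins", {
  pats <- cad_site_patterns()
  withr::with_seed(421, {
    for (rep in 1:40) {
      len <- sample(12:60, 1)
      seqs <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M",
                             "N","P","Q","R","S","T","V","W","Y","X"),
                           len, replace = TRUE), collapse = "")
      for (pat in pats[c("catalytic_zn", "structural_zn")]) {
        for (mm in 0:3) {
          got <- scan_sites(seqs, pat, mm)
          want <- oracle_scan(seqs, pat, mm)
          expect_equal(got$start, want$start)
          expect_equal(got$mismatches, want$mismatches)
        }
      }
    }
  })
})

test_that("classification requires all three sites and reports best matches", {
  fam <- make_protein_family(1, 0, max_mismatch = 0, seed = 99)
  prot <- fam$proteins
  cls <- classify_proteins(prot, tolerance = 2)
  expect_true(cls$is_cad)
  expect_equal(cls$catalytic_zn_mismatches, 0L)
  expect_equal(cls$structural_zn_mismatches, 0L)
  expect_equal(cls$nadph_mismatches, 0L)
  led <- fam$ledger
  expect_equal(cls$catalytic_zn_start, led$position[led$site == "catalytic_zn"])
  expect_equal(cls$nadph_start, led$position[led$site == "nadph"])

  # deleting the NADP(H) site flips the verdict and the evidence goes NA
  nad <- led$position[led$site == "nadph"]
  seq2 <- prot$sequence
  substr(seq2, nad, nad + 34L) <- strrep("A", 35)
  cls2 <- classify_proteins(tibble::tibble(id = "del", sequence = seq2), tolerance = 2)
  expect_false(cls2$is_cad)
  expect_true(is.na(cls2$nadph_start))
  expect_equal(cls2$catalytic_zn_mismatches, 0L)
})

test_that("synthetic families are recovered perfectly at the planted tolerance", {
  fam <- make_protein_family(20, 20, max_mismatch = 2, seed = 7)
  cls <- classify_proteins(fam$proteins, tolerance = 2)
  truth <- fam$ledger[!duplicated(fam$ledger$id), c("id", "is_cad")]
  expect_equal(cls$is_cad, truth$is_cad)
  expect_equal(sum(cls$is_cad), 20L)

  # planted sites mutated at <= k literals are found at tolerance k
  planted <- fam$ledger[fam$ledger$planted, ]
  evid <- tidy(cls)
  hit <- merge(planted, evid, by.x = c("id", "site"), by.y = c("protein_id", "site"))
  expect_true(all(!is.na(hit$start)))
  expect_true(all(hit$mismatches.y <= hit$mismatches.x))
})

test_that("raising the mismatch budget never un-classifies a protein", {
  fam <- make_protein_family(8, 8, max_mismatch = 2, seed = 31)
  verdicts <- lapply(0:3, function(tol) classify_proteins(fam$proteins, tolerance = tol)$is_cad)
  for (k in 1:3) {
    expect_true(all(verdicts[[k + 1]] >= verdicts[[k]]))
  }
  # and classification is a pure function of its inputs
  expect_identical(classify_proteins(fam$proteins, tolerance = 2),
                   classify_proteins(fam$proteins, tolerance = 2))
})

test_that("per-site tolerance budgets are honoured independently", {
  fam <- make_protein_family(1, 0, max_mismatch = 0, seed = 5)
  prot <- fam$proteins
  led <- fam$ledger
  # put exactly 2 literal mutations into the planted NADP(H) site
  pats <- cad_site_patterns()
  nad_start <- led$position[led$site == "nadph"]
  s <- strsplit(prot$sequence, "")[[1]]
  for (off in pats$nadph$literal_pos[1:2]) {
    pos <- nad_start + off - 1L
    s[pos] <- setdiff(c("A", "R"), s[pos])[1]
  }
  prot$sequence <- paste(s, collapse = "")
  tol_strict <- c(catalytic_zn = 2L, structural_zn = 2L, nadph = 1L)
  tol_lenient <- c(catalytic_zn = 2L, structural_zn = 2L, nadph = 2L)
  expect_false(classify_proteins(prot, tolerance = tol_strict)$is_cad)
  expect_true(classify_proteins(prot, tolerance = tol_lenient)$is_cad)
})

test_that("FASTA round trip preserves verdicts, order and normalization", {
  fam <- make_protein_family(2, 4, seed = 13)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$proteins, fa)
  cls_file <- classify_fasta(fa, tolerance = 2)
  cls_mem <- classify_proteins(fam$proteins, tolerance = 2)
  expect_equal(as.data.frame(cls_file), as.data.frame(cls_mem))

  # lowercase input gives the same verdicts
  lower <- fam$proteins
  lower$sequence <- tolower(lower$sequence)
  expect_equal(classify_proteins(lower, tolerance = 2)$is_cad, cls_mem$is_cad)

  # empty FASTA -> empty table
  empty_fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty_fa)
  expect_equal(nrow(classify_fasta(empty_fa)), 0L)

  # duplicate ids are rejected with the duplicates listed
  dup_fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "GHEKL", ">p1", "GHEKL"), dup_fa)
  expect_error(classify_fasta(dup_fa), "p1")
})

test_that("tidy and glance summarise a classification", {
  fam <- make_protein_family(3, 2, seed = 17)
  cls <- classify_proteins(fam$proteins, tolerance = 2)
  long <- tidy(cls)
  expect_equal(nrow(long), 5L * 3L)
  expect_setequal(unique(long$site), c("catalytic_zn", "structural_zn", "nadph"))
  g <- glance(cls)
  expect_equal(g$n_proteins, 5L)
  expect_equal(g$n_cad, 3L)
  expect_s3_class(autoplot(cls), "ggplot")
})
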