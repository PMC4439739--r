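psm_tbl <- function(peptide, protein, count, bait = "B", replicate = "r1") {
  tibble::tibble(peptide = peptide, protein = protein, spectral_count = count,
                 bait = bait, replicate = replicate)
}

test_that("unique peptides sum plainly into per-protein counts", {
  run <- assemble_apsm(psm_tbl(c("p1", "p2"), c("A", "A"), c(3, 4)))
  expect_equal(run$counts, c(A = 7))
})

test_that("proportional policy splits shared peptides by unique evidence", {
  run <- assemble_apsm(psm_tbl(c("pa", "pb", "ps"), c("A", "B", "A;B"), c(6, 6, 4)))
  expect_equal(run$counts, c(A = 8, B = 8))
  # uneven unique evidence: 2:1 split
  run2 <- assemble_apsm(psm_tbl(c("pa", "pb", "ps"), c("A", "B", "A;B"), c(8, 4, 6)))
  expect_equal(run2$counts, c(A = 12, B = 6))
  # no unique evidence anywhere: equal split
  run3 <- assemble_apsm(psm_tbl("ps", "A;B", 4))
  expect_equal(run3$counts, c(A = 2, B = 2))
})

test_that("parsimony policy collapses shared-only proteins onto the unique winner", {
  run <- assemble_apsm(psm_tbl(c("pd", "ps"), c("D", "C;D"), c(5, 3)),
                       policy = "parsimony")
  expect_equal(run$counts, c(D = 8))
  expect_false("C" %in% names(run$counts))
})

test_that("proportional allocation conserves total spectral counts", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    prots <- replicate(n, paste(sample(LETTERS[1:5], sample(1:3, 1)),
                                collapse = ";"))
    counts <- sample(0:12, n, replace = TRUE)
    run <- assemble_apsm(psm_tbl(sprintf("p%d", 1:n), prots, counts))
    expect_equal(sum(run$counts), sum(counts))
  }
})

test_that("assemble_apsm validates its input", {
  expect_error(assemble_apsm(psm_tbl("p", "A", 3), policy = "nonsense"), "arg")
  expect_error(assemble_apsm(psm_tbl("p", "A", -1)), "non-negative")
  expect_error(
    assemble_apsm(dplyr::bind_rows(psm_tbl("p", "A", 1, bait = "B1"),
                                   psm_tbl("q", "A", 1, bait = "B2"))),
    "one bait")
  expect_error(assemble_apsm(tibble::tibble(peptide = "p")), "missing column")
  empty <- assemble_apsm(psm_tbl(character(), character(), numeric()))
  expect_length(empty$counts, 0)
})

test_that("merge_replicates averages over replicates acquired", {
  r1 <- assemble_apsm(psm_tbl("p", "P", 8, replicate = "r1"))
  r2 <- assemble_apsm(psm_tbl("p", "P", 10, replicate = "r2"))
  s <- merge_replicates(list(r1, r2))
  expect_equal(s$apsm, c(P = 9))
  expect_equal(s$detections, c(P = 2L), ignore_attr = TRUE)

  single <- merge_replicates(list(assemble_apsm(psm_tbl("p", "P", 5))))
  expect_equal(single$apsm, c(P = 5))
  expect_equal(unname(single$detections), 1L)

  # absence in a replicate drags the average down
  r2b <- assemble_apsm(psm_tbl("p", "Q", 4, replicate = "r2"))
  r1b <- assemble_apsm(psm_tbl(c("p", "q"), c("P", "Q"), c(6, 4), replicate = "r1"))
  s2 <- merge_replicates(list(r1b, r2b))
  expect_equal(s2$apsm[["P"]], 3)
  expect_equal(s2$detections[[which(names(s2$apsm) == "P")]], 1L)
})

test_that("merge_replicates is invariant to replicate order and rejects bad input", {
  r1 <- assemble_apsm(psm_tbl(c("p", "q"), c("P", "Q"), c(6, 2), replicate = "r1"))
  r2 <- assemble_apsm(psm_tbl("p", "P", 10, replicate = "r2"))
  expect_equal(merge_replicates(list(r1, r2))$apsm,
               merge_replicates(list(r2, r1))$apsm)
  expect_error(merge_replicates(list()), "at least one")
  expect_error(merge_replicates(list(r1, r1)), "unique")
})

test_that("stats_table enforces the detection invariant", {
  X <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "p"))
  P <- matrix(c(0L, 0L), 2, 1)
  expect_error(stats_table(X, P), "positive exactly where")
  P2 <- matrix(c(1L, 0L), 2, 1)
  expect_s3_class(stats_table(X, P2), "stats_table")
  expect_error(stats_table(-X, P2), "non-negative")
})

test_that("stats tables round-trip through TSV exactly", {
  set.seed(42)
  tab <- random_stats_table(4, 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_table(tab, path)
  back <- read_stats_table(path)
  expect_identical(back$apsm, tab$apsm)
  expect_identical(back$detections, tab$detections)
  expect_identical(back$cell_line, tab$cell_line)
})

test_that("stats table reader validates files and handles header-only input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("bait\tprey\tapsm\treplicates", path)
  empty <- read_stats_table(path)
  expect_equal(nrow(empty$apsm), 0)
  expect_error(score_interactions(empty), "k >= 2")

  writeLines(c("bait\tprey\tapsm", "A\tP\t3"), path)
  expect_error(read_stats_table(path), "replicates")

  writeLines(c("bait\tprey\tapsm\treplicates", "A\tP\t-3\t1"), path)
  expect_error(read_stats_table(path), "negative")
})

test_that("the hand-authored 3x5 fixture parses to the expected matrix", {
  tab <- read_stats_table(system.file("extdata", "example_stats_table.tsv",
                                      package = "micoskit"))
  expected <- matrix(
    c(4, 12, 3, 5, 2,
      6, 20, 7, 9, 1,
      2, 8, 2.5, 14, 3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("MIC19", "MIC60", "MTX2"),
                    c("MIC25", "MIC60", "QIL1", "SAMM50", "TMEM11")))
  expect_equal(tab$apsm, expected)
  expect_equal(sum(tab$detections == 1L), 4)
})

test_that("membership lists read uniquely, skipping comments", {
  path <- withr::local_tempfile()
  writeLines(c("# mito list", "MIC60", "MIC19", "", "MIC60"), path)
  expect_equal(read_membership(path), c("MIC60", "MIC19"))
})
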