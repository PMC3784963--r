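test_that("abundance threshold keeps the top N and degrades gracefully", {
  set.seed(41)
  acc <- sprintf("P%02d", 1:40)
  ab <- makeAbundance(acc, "D", runif(40), "rep1")
  thr <- abundanceThreshold(ab, topNd = 30)
  expect_length(thr$selected$rep1, 30L)
  expect_equal(unname(thr$threshold["rep1"]),
               sort(ab$empai, decreasing = TRUE)[30])
  # fewer D proteins than topNd: all kept, warning, threshold = minimum
  small <- makeAbundance(sprintf("Q%02d", 1:10), "D", runif(10), "rep1")
  expect_warning(thrS <- abundanceThreshold(small, topNd = 30), "only 10")
  expect_length(thrS$selected$rep1, 10L)
  expect_equal(unname(thrS$threshold["rep1"]), min(small$empai))
})

test_that("threshold emPAI is non-increasing as topNd grows", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    ab <- makeAbundance(sprintf("P%03d", 1:n), "D", runif(n), "rep1")
    th <- vapply(1:n, function(k)
      unname(abundanceThreshold(ab, k)$threshold["rep1"]), numeric(1))
    expect_true(all(diff(th) <= 1e-12))
    # brute-force: k-th largest value
    expect_equal(th, sort(ab$empai, decreasing = TRUE))
  }
})

test_that("the U screen uses strict inequalities on both axes", {
  ab <- rbind(makeAbundance(c("U1", "U2", "U3"), "U", c(0.8, 0.5, 0.4),
                            "rep1"))
  scores <- c(U1 = 0.2, U2 = 0.1, U3 = 5)
  sel <- screenUncharacterised(ab, c(rep1 = 0.5), scores)
  # U2 sits exactly at the abundance threshold -> excluded; U3 below
  expect_equal(sel$rep1, "U1")
  # score exactly at the binder threshold -> excluded
  sel0 <- screenUncharacterised(ab, c(rep1 = 0.1), c(U1 = 0, U2 = 1, U3 = 1))
  expect_equal(sort(sel0$rep1), c("U2", "U3"))
  # missing score for an above-threshold protein names the accession
  expect_error(screenUncharacterised(ab, c(rep1 = 0.1), c(U1 = 1)), "U2")
  expect_equal(screenUncharacterised(ab[0, ], c(rep1 = 0.1),
                                     scores)$rep1, character(0))
})

test_that("replicate intersection discards single-replicate proteins", {
  expect_equal(intersectReplicates(list(c("A", "B", "C"), c("B", "C", "D"))),
               c("B", "C"))
  expect_equal(intersectReplicates(list(c("A", "B"), c("A", "B"))),
               c("A", "B"))
  expect_error(intersectReplicates(list(c("A"))), ">= 2")
  expect_equal(intersectReplicates(list(c("A"), c("B")),
                                   requireBothReplicates = FALSE),
               c("A", "B"))
})

test_that("the candidate table merges, ranks and flags correctly", {
  ab <- rbind(
    makeAbundance(c("D1", "D2", "U1"), c("D", "D", "U"), c(3, 1, 2), "rep1"),
    makeAbundance(c("D1", "D2", "U1"), c("D", "D", "U"), c(1, 3, 2), "rep2"))
  naps <- data.frame(name = "known", locus_tag = "LTD1")
  tab <- buildCandidateTable(c("D1", "D2"), "U1", ab,
                             bindingScores = c(U1 = 0.7), knownNaps = naps)
  expect_equal(nrow(tab), 3L)
  # amalgamated rank over the merged pool, sorted by replicate-1 rank
  expect_equal(tab$accession, c("D1", "U1", "D2"))
  expect_equal(tab$rank_rep1, 1:3)
  expect_equal(tab$rank_rep2[tab$accession == "D2"], 1L)
  expect_equal(tab$binding_score[tab$accession == "U1"], 0.7)
  expect_true(all(is.na(tab$binding_score[tab$category == "D"])))
  expect_equal(tab$known_nap, c(TRUE, FALSE, FALSE))
  # category exclusivity
  expect_error(buildCandidateTable(c("D1"), c("D1"), ab, knownNaps = naps),
               "exclusive")
  # empty selections
  expect_equal(nrow(buildCandidateTable(character(), character(), ab,
                                        knownNaps = naps)), 0L)
})

test_that("candidate set is monotone in topNd", {
  set.seed(43)
  n <- 50
  ab <- rbind(
    makeAbundance(sprintf("D%02d", 1:n), "D", runif(n), "rep1"),
    makeAbundance(sprintf("D%02d", 1:n), "D", runif(n), "rep2"))
  prev <- character()
  for (k in c(5, 10, 20, 40)) {
    sel <- selectCandidates(ab, bindingScores = numeric(),
                            config = selectionConfig(topNd = k))
    now <- sel$candidates$accession[sel$candidates$category == "D"]
    expect_true(all(prev %in% now))
    prev <- now
  }
})

test_that("selection on the study fixture enforces its invariants", {
  fx <- readStudyFixture()
  sel <- suppressWarnings(
    selectCandidates(fx$abundance, bindingScores = fx$bindingScores,
                     physchem = fx$physchem))
  cand <- sel$candidates
  # every candidate present in both replicates
  expect_false(any(is.na(cand$empai_rep1)) || any(is.na(cand$empai_rep2)))
  # no candidate from categories R, C, E
  expect_true(all(cand$category %in% c("D", "U")))
  # every U candidate scores strictly above the binder threshold
  expect_true(all(cand$binding_score[cand$category == "U"] > 0))
  # physchem pass-through from the fixture
  expect_equal(cand$mw_kda[cand$locus_tag == "SCO2950"], 9.9)
  expect_equal(cand$pi[cand$locus_tag == "SCO2950"], 9.5)
})

test_that("reports are deterministic and mirror the candidate table", {
  fx <- readStudyFixture()
  sel <- suppressWarnings(
    selectCandidates(fx$abundance, bindingScores = fx$bindingScores,
                     physchem = fx$physchem))
  d1 <- tempfile(); d2 <- tempfile()
  writeReport(sel, d1, records = fx$abundance)
  writeReport(sel, d2, records = fx$abundance)
  expect_identical(readLines(file.path(d1, "candidates.tsv")),
                   readLines(file.path(d2, "candidates.tsv")))
  expect_identical(readLines(file.path(d1, "summary.txt")),
                   readLines(file.path(d2, "summary.txt")))
  tsv <- read.delim(file.path(d1, "candidates.tsv"), na.strings = "n/a")
  expect_equal(nrow(tsv), nrow(sel$candidates))
  # empty candidate list: header-only TSV
  d3 <- tempfile()
  writeReport(sel$candidates[0, ], d3)
  expect_length(readLines(file.path(d3, "candidates.tsv")), 1L)
})
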