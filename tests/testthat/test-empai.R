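test_that("evidence reading validates schema and values", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(accession = c("A1", "A1", "A2"),
                         peptide = c("GASLLK", "GASLLK", "MMPPTR"),
                         expect = c(0.01, 0.04, 0.2),
                         replicate = c("rep1", "rep1", "rep2"),
                         slice = c("s1", "s2", "s1"),
                         extra = 1:3),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- readEvidence(f)
  expect_equal(nrow(ev), 3L)
  expect_false("extra" %in% names(ev))  # extras ignored

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(accession = "A1", peptide = "GK", expect = 0.1),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readEvidence(f2), "replicate")

  f3 <- tempfile(fileext = ".tsv")
  write.table(data.frame(accession = "A1", peptide = "GK", expect = -1,
                         replicate = "rep1"),
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readEvidence(f3), ">= 0")
})

test_that("expect filtering keeps the boundary and merges slices", {
  ev <- data.frame(accession = "A1",
                   peptide = c("GASLLK", "GASLLK", "MMPPTR"),
                   expect = c(0.01, 0.05, 0.06),
                   replicate = "rep1", slice = c("s1", "s2", "s1"))
  kept <- filterEvidence(ev, 0.05)
  # 0.05 retained (boundary included), 0.06 dropped; the peptide seen in
  # two slices of one replicate collapses to a single occurrence
  expect_equal(nrow(kept), 1L)
  expect_false("slice" %in% names(kept))
  expect_equal(nrow(filterEvidence(ev[0, ], 0.05)), 0L)
  expect_error(filterEvidence(ev, 0), "> 0")
})

test_that("emPAI records follow 10^(Nobs/Nobsbl) - 1", {
  s <- strrep("AGLLPKMSTYVR", 8)
  ps <- proteinSet(c(s, "MAKGGR"), c("A1", "A2"),
                   category = c("D", "U"), locusTag = c("L1", "L2"))
  w <- observabilityWindow(mzMin = 100, mzMax = 3000, charges = 1:3,
                           minLength = 6L, maxMissedCleavages = 1L)
  nObs <- countObservable(s, w)
  ev <- data.frame(accession = "A1",
                   peptide = c("AGLLPK", "MSTYVR"),
                   replicate = "rep1")
  rec <- computeEmpai(ev, ps, w)
  expect_equal(nrow(rec), 1L)  # A2 absent, not zero-listed
  expect_equal(rec$n_observed, 2L)
  expect_equal(rec$n_observable, nObs)
  expect_equal(rec$empai, 10^(2 / nObs) - 1)
  expect_error(computeEmpai(data.frame(accession = "ZZ", peptide = "GK",
                                       replicate = "rep1"), ps, w),
               "ZZ")
})

test_that("emPAI is monotone in observed and observable counts", {
  empai <- function(nobs, nobsbl) 10^(nobs / nobsbl) - 1
  expect_equal(empai(0, 10), 0)
  expect_equal(empai(10, 10), 9)       # PAI = 1
  expect_equal(empai(5, 10), 10^0.5 - 1, tolerance = 1e-12)
  for (nobsbl in c(5, 20, 50))
    expect_true(all(diff(empai(0:nobsbl, nobsbl)) > 0))
  for (nobs in c(1, 5, 10))
    expect_true(all(diff(empai(nobs, 10:50)) < 0))
})

test_that("proteins without a category are reported as U with a warning", {
  ps <- proteinSet(strrep("AGLLPK", 10), "A1")  # category NA
  w <- observabilityWindow(mzMin = 100, mzMax = 3000, charges = 1:3)
  ev <- data.frame(accession = "A1", peptide = "AGLLPK", replicate = "rep1")
  expect_warning(rec <- computeEmpai(ev, ps, w), "default to U")
  expect_equal(rec$category, "U")
})

test_that("ranking is a dense per-replicate permutation with stable ties", {
  ab <- makeAbundance(c("B", "A", "C", "B", "A", "C"), "D",
                      c(3, 3, 1, 5, 2, 2),
                      rep(c("rep1", "rep2"), each = 3))
  r <- rankByEmpai(ab, scope = "D")
  r1 <- r[r$replicate == "rep1", ]
  expect_equal(sort(r1$rank), 1:3)
  # tie at 3: accession order A then B
  expect_equal(r1$accession[order(r1$rank)], c("A", "B", "C"))
  r2 <- r[r$replicate == "rep2", ]
  expect_equal(r2$accession[order(r2$rank)], c("B", "A", "C"))
  # single record
  one <- rankByEmpai(makeAbundance("X", "D", 1, "rep1"))
  expect_equal(one$rank, 1L)
  # predicate scope
  rp <- rankByEmpai(ab, scope = function(d) d$empai > 2)
  expect_true(all(rp$empai > 2))
})

test_that("composition percentages sum to 100 and ignore row order", {
  ab <- makeAbundance(c("A", "B", "C"), c("R", "D", "D"), c(3, 0.5, 0.5),
                      "rep1")
  cs <- compositionSummary(ab)
  expect_equal(sum(cs$percentage), 100, tolerance = 1e-9)
  expect_equal(cs$percentage[cs$category == "R"], 75)
  expect_equal(cs$percentage[cs$category == "D"], 25)
  expect_equal(cs$percentage[cs$category == "U"], 0)
  perm <- compositionSummary(ab[c(3, 1, 2), ])
  expect_equal(perm, cs)
  # single category
  expect_equal(
    compositionSummary(makeAbundance("A", "E", 2, "rep1"))$percentage[5],
    100)
})
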