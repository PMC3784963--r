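# Lighter configurations keep the generator tests fast; the full default
# conditions are exercised by the acceptance suite.
smallConfig <- function(seed = 1L, ...) {
  syntheticConfig(nProteins = 120L, nPlantedNaps = 6L,
                  detectionCapacity = 2000, seed = seed, ...)
}

test_that("generation is a deterministic function of the configuration", {
  cfg <- smallConfig(seed = 9L)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(as.character(sequences(a$proteins)),
                   as.character(sequences(b$proteins)))
  expect_identical(a$truth, b$truth)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$bindingFixture, b$bindingFixture)
  c2 <- simulateExperiment(smallConfig(seed = 10L))
  expect_false(identical(a$evidence, c2$evidence))
})

test_that("planted NAPs are basic-residue-enriched with category D or U", {
  pro <- generateProteome(smallConfig(seed = 2L))
  comp <- aaComposition(sequences(pro$proteins))
  kr <- comp[, "K"] + comp[, "R"]
  planted <- pro$truth$is_planted_nap
  expect_gt(mean(kr[planted]), mean(kr[!planted]))
  expect_true(all(pro$truth$category[planted] %in% c("D", "U")))
  expect_true(all(pro$truth$binder_label[planted]))
  # basic composition shifts pI upward
  pis <- isoelectricPoint(sequences(pro$proteins))
  expect_gt(mean(pis[planted]), mean(pis[!planted]))
  # no planted NAPs -> no flags
  zero <- generateProteome(syntheticConfig(nProteins = 50L,
                                           nPlantedNaps = 0L, seed = 2L))
  expect_false(any(zero$truth$is_planted_nap))
})

test_that("abundances follow the configured power law", {
  cfg <- smallConfig(seed = 3L)
  tr <- generateAbundances(generateProteome(cfg)$truth, cfg)
  # exponent 1: rank-1 abundance is twice rank-2
  a <- tr$abundance_rep1
  r <- tr$true_rank
  expect_equal(a[r == 1] / a[r == 2], 2, tolerance = 1e-12)
  expect_equal(a, r^(-1))
  # perfect correlation -> identical replicates
  cfg1 <- syntheticConfig(nProteins = 80L, nPlantedNaps = 4L,
                          replicateCorrelation = 1, seed = 3L)
  tr1 <- generateAbundances(generateProteome(cfg1)$truth, cfg1)
  expect_identical(tr1$abundance_rep1, tr1$abundance_rep2)
})

test_that("replicate correlation calibration hits its target", {
  target <- 0.8
  got <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(nProteins = 500L, nPlantedNaps = 10L,
                           replicateCorrelation = target, seed = s)
    tr <- generateAbundances(generateProteome(cfg)$truth, cfg)
    cor(tr$abundance_rep1, tr$abundance_rep2, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(got) - target), 0.1)
})

test_that("evidence follows the saturating detection model", {
  cfg <- smallConfig(seed = 4L)
  pro <- generateProteome(cfg)
  tr <- generateAbundances(pro$truth, cfg)
  w <- observabilityWindow()
  # zero abundance -> no evidence rows
  tr0 <- tr
  tr0$abundance_rep1[1] <- 0
  tr0$abundance_rep2[1] <- 0
  ev0 <- generateEvidence(pro$proteins, tr0, w, cfg)
  expect_false(tr0$accession[1] %in% ev0$accession)
  # capacity at the total observable count -> essentially full coverage
  sat <- syntheticConfig(nProteins = 20L, nPlantedNaps = 2L,
                         detectionCapacity = 1e9, seed = 4L)
  proS <- generateProteome(sat)
  trS <- generateAbundances(proS$truth, sat)
  evS <- generateEvidence(proS$proteins, trS, w, sat)
  nObs <- vapply(as.character(sequences(proS$proteins)), countObservable,
                 integer(1), window = w, USE.NAMES = FALSE)
  seen <- table(factor(evS$accession[evS$replicate == "rep1"],
                       levels = accessions(proS$proteins)))
  expect_gte(sum(seen) / sum(nObs), 0.99)
  # doubling capacity increases the mean observation count
  tot <- function(capacity, seeds) {
    mean(vapply(seeds, function(s) {
      cc <- syntheticConfig(nProteins = 60L, nPlantedNaps = 3L,
                            detectionCapacity = capacity, seed = s)
      p <- generateProteome(cc)
      t <- generateAbundances(p$truth, cc)
      nrow(generateEvidence(p$proteins, t, w, cc))
    }, numeric(1)))
  }
  expect_gt(tot(2000, 1:3), tot(1000, 1:3))
})

test_that("generated evidence round-trips through the evidence readers", {
  cfg <- smallConfig(seed = 6L)
  d <- tempfile()
  sim <- simulateExperiment(cfg, dir = d)
  expect_setequal(list.files(d),
                  c("proteome.fasta", "annotations.tsv", "evidence_rep1.tsv",
                    "evidence_rep2.tsv", "truth.tsv", "binding_fixture.tsv"))
  ev <- rbind(readEvidence(file.path(d, "evidence_rep1.tsv")),
              readEvidence(file.path(d, "evidence_rep2.tsv")))
  expect_equal(nrow(ev), nrow(sim$evidence))
  kept <- filterEvidence(ev)
  expect_gt(nrow(kept), 0L)
  pro <- readProteomeFasta(file.path(d, "proteome.fasta"))
  expect_equal(sort(accessions(pro)), sort(accessions(sim$proteins)))
  # pipeline closure: quantify and select without manual edits
  pro <- assignCategories(pro, overrides =
                            readAnnotations(file.path(d, "annotations.tsv")))
  rec <- computeEmpai(kept, pro)
  model <- trainBindingModel(sim$bindingFixture$sequence,
                             sim$bindingFixture$label, seed = cfg$seed)
  sel <- suppressWarnings(
    selectCandidates(rec, proteins = pro,
                     config = selectionConfig(topNd = 10),
                     bindingModel = model))
  expect_gt(nrow(sel$candidates), 0L)
})

test_that("the binding fixture margin knob controls separability", {
  fix <- generateBindingFixture(smallConfig(seed = 7L))
  m <- trainBindingModel(fix$sequence, fix$label, seed = 7L)
  expect_gte(mean(isBinder(scoreBinding(fix$sequence, m)) ==
                    (fix$label == 1)), 0.9)
  # margin 0: classes are both background draws, no perfect separation
  flat <- generateBindingFixture(smallConfig(seed = 7L, bindingMargin = 0),
                                 nPerClass = 60L)
  m0 <- trainBindingModel(flat$sequence, flat$label, seed = 7L)
  expect_lt(mean(isBinder(scoreBinding(flat$sequence, m0)) ==
                   (flat$label == 1)), 1)
})
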