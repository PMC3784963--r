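# Fully synthetic nucleoid-proteomics experiment with ground truth:
# power-law protein abundances, two correlated biological replicates, a
# saturating peptide-detection model, and planted NAPs (small, abundant,
# basic-residue-enriched) among realistic contaminants.

# Background residue frequencies (approximate proteome-average values).
.BG_FREQ <- c(
  A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014,
  E = 0.068, Q = 0.039, G = 0.071, H = 0.023, I = 0.060,
  L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
  S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.069
)

.CATEGORY_NAMES <- c(
  R = "50S ribosomal protein",
  C = "molecular chaperone",
  D = "putative transcriptional regulator",
  U = "uncharacterised protein",
  E = "metabolic enzyme"
)

#' Synthetic experiment configuration
#'
#' Defines the conditions of the simulated nucleoid survey: proteome size,
#' number of planted NAPs, category proportions, the power-law exponent of
#' the abundance distribution, the target between-replicate Spearman
#' correlation, and the expected total number of peptide observations per
#' replicate (which sets the saturation level of the detection model).
#'
#' @param nProteins Number of proteins; default 500.
#' @param nPlantedNaps Number of planted NAPs; default 10.
#' @param categoryProportions Named proportions over R/C/D/U/E summing
#'   to 1.
#' @param powerLawExponent Exponent of the rank-abundance power law
#'   (> 0); default 1.
#' @param replicateCorrelation Target Spearman correlation between
#'   replicate abundances, in \[0, 1\]; default 0.8.
#' @param detectionCapacity Expected total peptide observations per
#'   replicate; default 6000.
#' @param expectAboveFraction Fraction of generated expect values above the
#'   0.05 identification threshold; default 0.1.
#' @param bindingMargin Separation knob for the binding training fixture in
#'   \[0, 1\] (0 = classes overlap); default 1.
#' @param seed Integer seed; all generator outputs are deterministic
#'   functions of the configuration including this seed.
#' @return List with class `"synthetic_config"`.
#' @export
syntheticConfig <- function(nProteins = 500L, nPlantedNaps = 10L,
                            categoryProportions = c(R = 0.10, C = 0.05,
                                                    D = 0.15, U = 0.20,
                                                    E = 0.50),
                            powerLawExponent = 1,
                            replicateCorrelation = 0.8,
                            detectionCapacity = 6000,
                            expectAboveFraction = 0.1,
                            bindingMargin = 1,
                            seed = 1L) {
  if (nPlantedNaps > nProteins)
    stop("nPlantedNaps must be <= nProteins")
  if (!setequal(names(categoryProportions), .CATEGORIES) ||
      abs(sum(categoryProportions) - 1) > 1e-9)
    stop("categoryProportions must be named R/C/D/U/E and sum to 1")
  if (powerLawExponent <= 0) stop("powerLawExponent must be > 0")
  if (replicateCorrelation < 0 || replicateCorrelation > 1)
    stop("replicateCorrelation must be in [0, 1]")
  structure(list(nProteins = as.integer(nProteins),
                 nPlantedNaps = as.integer(nPlantedNaps),
                 categoryProportions = categoryProportions[.CATEGORIES],
                 powerLawExponent = powerLawExponent,
                 replicateCorrelation = replicateCorrelation,
                 detectionCapacity = detectionCapacity,
                 expectAboveFraction = expectAboveFraction,
                 bindingMargin = bindingMargin,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.napFreq <- function(margin = 1) {
  f <- .BG_FREQ
  f[c("K", "R")] <- f[c("K", "R")] * (1 + 2 * margin)
  f["E"] <- f["E"] * (1 + margin)
  f / sum(f)
}

.nonBinderFreq <- function(margin = 1) {
  f <- .BG_FREQ
  f["D"] <- f["D"] * (1 + 2 * margin)
  f[c("L", "A", "V")] <- f[c("L", "A", "V")] * (1 + 0.8 * margin)
  f[c("K", "R")] <- f[c("K", "R")] / (1 + 2 * margin)
  f / sum(f)
}

.randomSeq <- function(len, freq) {
  paste(sample(names(freq), len, replace = TRUE, prob = freq),
        collapse = "")
}

#' Generate a synthetic proteome with planted NAPs
#'
#' Random sequences (length 60-400) from a background residue distribution;
#' planted NAPs are shorter (60-150, NAPs are small proteins) and drawn
#' from a lysine/arginine/glutamate-enriched distribution, which also
#' shifts their pI upward. Categories are sampled from the configured
#' proportions; planted NAPs receive category D or U.
#'
#' @param config A [syntheticConfig()].
#' @return List with `proteins` (a [ProteinSet-class]) and `truth`
#'   (data.frame: accession, locus_tag, is_planted_nap, category,
#'   binder_label).
#' @export
generateProteome <- function(config) {
  set.seed(config$seed)
  n <- config$nProteins
  np <- config$nPlantedNaps
  planted <- seq_len(n) <= np
  napf <- .napFreq(1)
  lens <- integer(n)
  lens[planted] <- sample(60:150, np, replace = TRUE)
  lens[!planted] <- sample(60:400, n - np, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n))
    seqs[i] <- .randomSeq(lens[i], if (planted[i]) napf else .BG_FREQ)
  category <- character(n)
  if (np > 0L)
    category[planted] <- sample(c("D", "U"), np, replace = TRUE,
                                prob = c(0.7, 0.3))
  category[!planted] <- sample(.CATEGORIES, n - np, replace = TRUE,
                               prob = config$categoryProportions)
  accession <- sprintf("SYN%04d", seq_len(n))
  locus <- sprintf("SCL%04d", seq_len(n))
  descr <- paste(unname(.CATEGORY_NAMES[category]), seq_len(n))
  proteins <- proteinSet(seqs, accession = accession, locusTag = locus,
                         protName = descr, category = category)
  truth <- data.frame(accession = accession, locus_tag = locus,
                      is_planted_nap = planted, category = category,
                      binder_label = planted, stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}

# Calibrate the lognormal noise sd so that Spearman(base, base * noise)
# matches the target, by bisection against Monte-Carlo estimates sharing
# one set of standard-normal draws (monotone in sd, so bisection is exact
# for those draws).
.calibrateNoiseSd <- function(logBase, target, ndraws = 30L) {
  if (target >= 1) return(0)
  n <- length(logBase)
  E <- matrix(rnorm(ndraws * n), nrow = ndraws)
  est <- function(sd) {
    mean(apply(E, 1L, function(e)
      cor(logBase, logBase + sd * e, method = "spearman")))
  }
  lo <- 0; hi <- 0.5
  while (est(hi) > target && hi < 64) hi <- hi * 2
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (est(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate per-replicate true abundances
#'
#' Base abundance for the protein of abundance rank `r` is proportional to
#' `r^-exponent`; planted NAPs are assigned ranks in the top fifth of the
#' distribution (so that most, but not all, fall in the top decile).
#' Replicate 1 equals the base; replicate 2 is the base perturbed by
#' lognormal noise whose sd is calibrated so the between-replicate Spearman
#' rank correlation matches the configured value.
#'
#' @param truth Truth data.frame from [generateProteome()].
#' @param config A [syntheticConfig()].
#' @return The truth data.frame extended with `true_rank`,
#'   `abundance_rep1`, `abundance_rep2`; the calibrated noise sd is in
#'   `attr(, "noise_sd")`.
#' @export
generateAbundances <- function(truth, config) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  np <- sum(truth$is_planted_nap)
  topPool <- seq_len(max(np, ceiling(0.2 * n)))
  ranks <- integer(n)
  plantedRanks <- sample(topPool, np)
  ranks[truth$is_planted_nap] <- plantedRanks
  ranks[!truth$is_planted_nap] <- sample(setdiff(seq_len(n), plantedRanks))
  base <- ranks^(-config$powerLawExponent)
  sd <- .calibrateNoiseSd(log(base), config$replicateCorrelation)
  noise <- if (sd == 0) rep(0, n) else rnorm(n, 0, sd)
  truth$true_rank <- ranks
  truth$abundance_rep1 <- base
  truth$abundance_rep2 <- base * exp(noise)
  attr(truth, "noise_sd") <- sd
  truth
}

#' Generate synthetic peptide-identification evidence
#'
#' For each protein and replicate, every observable tryptic peptide is
#' detected independently with probability `1 - exp(-c * abundance)`, the
#' simplest saturating observation model (abundant proteins approach full
#' coverage, reproducing the emPAI saturation seen for e.g. ribosomal
#' proteins); `c` is calibrated by root-finding so the expected total
#' number of observations per replicate equals `detectionCapacity`.
#' Detected peptides receive expect values of which a configured fraction
#' falls above the 0.05 threshold, and are assigned to three gel-slice
#' labels by peptide-mass tertile.
#'
#' @param proteins [ProteinSet-class] from [generateProteome()].
#' @param abundances Truth data.frame from [generateAbundances()].
#' @param window An [ObservabilityWindow-class].
#' @param config A [syntheticConfig()].
#' @return Evidence data.frame (accession, peptide, expect, replicate,
#'   slice) covering both replicates.
#' @export
generateEvidence <- function(proteins, abundances,
                             window = observabilityWindow(), config) {
  set.seed(config$seed + 2L)
  acc <- accessions(proteins)
  obsPeps <- lapply(as.character(sequences(proteins)), observablePeptides,
                    window = window)
  names(obsPeps) <- acc
  nObs <- lengths(obsPeps)
  out <- list()
  for (rep in c("rep1", "rep2")) {
    A <- abundances[[paste0("abundance_", rep)]][match(acc,
                                                       abundances$accession)]
    expTotal <- function(cc) sum(nObs * (1 - exp(-cc * A)))
    cap <- min(config$detectionCapacity, 0.999 * sum(nObs))
    cc <- uniroot(function(x) expTotal(exp(x)) - cap,
                  lower = log(1e-12), upper = log(1e12), tol = 1e-10)$root
    cc <- exp(cc)
    p <- 1 - exp(-cc * A)
    rows <- list()
    for (i in seq_along(acc)) {
      if (nObs[i] == 0L || p[i] == 0) next
      hit <- runif(nObs[i]) < p[i]
      if (!any(hit)) next
      pep <- obsPeps[[i]][hit]
      above <- runif(length(pep)) < config$expectAboveFraction
      expect <- ifelse(above, 0.05 + runif(length(pep)) * 0.95,
                       runif(length(pep)) * 0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc[i], peptide = pep, expect = expect,
        replicate = rep, stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
    if (is.null(ev)) next
    mass <- vapply(ev$peptide, function(s)
      sum(.MASS_MONO[strsplit(s, "")[[1L]]]) + .MASS_WATER_MONO,
      numeric(1L), USE.NAMES = FALSE)
    cut3 <- stats::quantile(mass, c(1 / 3, 2 / 3))
    ev$slice <- paste0("slice",
                       1L + (mass > cut3[1L]) + (mass > cut3[2L]))
    out[[rep]] <- ev
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Generate a labelled binding-training fixture
#'
#' Binder sequences are enriched in lysine, arginine and glutamate;
#' non-binders in acidic/hydrophobic residues. The `bindingMargin` knob
#' interpolates both classes toward the background distribution (0 = both
#' classes are background draws, so they overlap).
#'
#' @param config A [syntheticConfig()].
#' @param nPerClass Sequences per class; default 40.
#' @return data.frame with columns `accession`, `sequence`, `label`
#'   (1 = binder).
#' @export
generateBindingFixture <- function(config, nPerClass = 40L) {
  set.seed(config$seed + 3L)
  m <- config$bindingMargin
  fb <- .napFreq(m)
  fn <- .nonBinderFreq(m)
  lens <- sample(80:200, 2L * nPerClass, replace = TRUE)
  seqs <- character(2L * nPerClass)
  for (i in seq_len(nPerClass))
    seqs[i] <- .randomSeq(lens[i], fb)
  for (i in (nPerClass + 1L):(2L * nPerClass))
    seqs[i] <- .randomSeq(lens[i], fn)
  data.frame(accession = sprintf("BFIX%03d", seq_len(2L * nPerClass)),
             sequence = seqs,
             label = rep(c(1L, 0L), each = nPerClass),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic experiment
#'
#' Runs all generators under one configuration and optionally writes the
#' standard file set (`proteome.fasta`, `annotations.tsv`,
#' `evidence_rep1.tsv`, `evidence_rep2.tsv`, `truth.tsv`,
#' `binding_fixture.tsv`) to a directory.
#'
#' @param config A [syntheticConfig()].
#' @param dir Optional output directory.
#' @param window An [ObservabilityWindow-class].
#' @return List with `proteins`, `truth` (including abundances),
#'   `evidence`, `bindingFixture`, `config`.
#' @export
simulateExperiment <- function(config = syntheticConfig(), dir = NULL,
                               window = observabilityWindow()) {
  pro <- generateProteome(config)
  truth <- generateAbundances(pro$truth, config)
  evidence <- generateEvidence(pro$proteins, truth, window, config)
  fixture <- generateBindingFixture(config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    aa <- sequences(pro$proteins)
    names(aa) <- paste0(accessions(pro$proteins), "|",
                        unname(locusTags(pro$proteins)), " ",
                        unname(proteinNames(pro$proteins)))
    Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
    ann <- data.frame(accession = accessions(pro$proteins),
                      locus_tag = unname(locusTags(pro$proteins)),
                      description = unname(proteinNames(pro$proteins)),
                      category_override = unname(categories(pro$proteins)))
    write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (rep in unique(evidence$replicate))
      write.table(evidence[evidence$replicate == rep, ],
                  file.path(dir, paste0("evidence_", rep, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fixture, file.path(dir, "binding_fixture.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(proteins = pro$proteins, truth = truth, evidence = evidence,
       bindingFixture = fixture, config = config)
}

#' Run the pipeline on a synthetic experiment and score recovery
#'
#' Convenience benchmark: simulates an experiment, quantifies it with
#' emPAI, trains a binding model on the simulated fixture, runs the
#' candidate selection, and reports (a) the fraction of planted top-decile
#' NAPs recovered in the candidate list and (b) the Spearman correlation
#' between true replicate-1 abundance and emPAI over detected proteins.
#' Planted NAPs below the top abundance decile are excluded from the
#' recovery denominator: an abundance-threshold method cannot be expected
#' to find low-abundance regulators.
#'
#' @param config A [syntheticConfig()].
#' @param window An [ObservabilityWindow-class].
#' @param selection A [selectionConfig()].
#' @return List with `recovery`, `spearman`, `selection`, `records`,
#'   `truth`, `sim`.
#' @export
runSyntheticBenchmark <- function(config = syntheticConfig(),
                                  window = observabilityWindow(),
                                  selection = selectionConfig()) {
  sim <- simulateExperiment(config, window = window)
  ev <- filterEvidence(sim$evidence, selection$expectThreshold)
  records <- computeEmpai(ev, sim$proteins, window)
  model <- trainBindingModel(sim$bindingFixture$sequence,
                             sim$bindingFixture$label,
                             seed = config$seed)
  sel <- selectCandidates(records, proteins = sim$proteins,
                          config = selection, bindingModel = model)
  truth <- sim$truth
  decile <- ceiling(0.1 * nrow(truth))
  target <- truth$accession[truth$is_planted_nap & truth$true_rank <= decile]
  recovery <- if (length(target))
    mean(target %in% sel$candidates$accession) else NA_real_
  r1 <- records[records$replicate == "rep1", ]
  idx <- match(r1$accession, truth$accession)
  spear <- cor(truth$abundance_rep1[idx], r1$empai, method = "spearman")
  list(recovery = recovery, spearman = spear, selection = sel,
       records = records, truth = truth, sim = sim)
}
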