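# The "ruling in" candidate-selection procedure: abundance threshold on
# annotated DNA-binding proteins (category D), composition-based binding
# screen on sufficiently abundant uncharacterised proteins (category U),
# replicate intersection, merged ranked candidate table. No contaminant
# subtraction against other subcellular fractions is performed.

#' Selection configuration
#'
#' @param topNd Number of top category-D proteins per replicate retained as
#'   potential NAPs/GRs; default 30.
#' @param binderThreshold Binding-score threshold (strictly greater-than);
#'   default 0.
#' @param requireBothReplicates Discard proteins present in only one
#'   replicate as possible contaminants; default `TRUE`.
#' @param expectThreshold Peptide expect-value threshold used upstream;
#'   default 0.05.
#' @return A list with class `"selection_config"`.
#' @export
selectionConfig <- function(topNd = 30L, binderThreshold = 0,
                            requireBothReplicates = TRUE,
                            expectThreshold = 0.05) {
  if (topNd < 1L) stop("topNd must be >= 1")
  structure(list(topNd = as.integer(topNd),
                 binderThreshold = as.numeric(binderThreshold),
                 requireBothReplicates = isTRUE(requireBothReplicates),
                 expectThreshold = as.numeric(expectThreshold)),
            class = "selection_config")
}

#' Abundance threshold on category-D proteins
#'
#' Per replicate, ranks the category-D (annotated DNA-binding) proteins by
#' descending emPAI and keeps the top `topNd`; the threshold emPAI is the
#' score of the last protein kept. If a replicate holds fewer than `topNd`
#' category-D proteins, all are kept and the threshold is the minimum, with
#' a warning.
#'
#' @param records Abundance data.frame (see [computeEmpai()]); category-D
#'   rows are selected internally.
#' @param topNd Number of proteins to keep per replicate; default 30.
#' @return List with `selected` (per-replicate list of accessions, ordered
#'   by rank) and `threshold` (named numeric, the emPAI of the last kept
#'   protein per replicate).
#' @export
abundanceThreshold <- function(records, topNd = 30L) {
  if (topNd < 1L) stop("topNd must be >= 1")
  d <- rankByEmpai(records, scope = "D")
  reps <- sort(unique(records$replicate))
  selected <- list(); threshold <- setNames(numeric(length(reps)), reps)
  for (r in reps) {
    dr <- d[d$replicate == r, , drop = FALSE]
    if (nrow(dr) < topNd)
      warning(sprintf(
        "replicate %s has only %d category-D proteins (< topNd = %d); keeping all",
        r, nrow(dr), topNd))
    keep <- dr[dr$rank <= topNd, , drop = FALSE]
    selected[[r]] <- keep$accession
    threshold[r] <- if (nrow(keep)) min(keep$empai) else NA_real_
  }
  list(selected = selected, threshold = threshold)
}

#' Screen abundant uncharacterised proteins for binding propensity
#'
#' Per replicate, takes the category-U proteins whose emPAI is strictly
#' greater than that replicate's category-D abundance threshold and keeps
#' those whose binding score is strictly greater than `binderThreshold`.
#' Scores may come from [scoreBinding()] or from an external tool; a
#' missing score for an above-threshold protein is an error naming the
#' accession.
#'
#' @param records Abundance data.frame; category-U rows are selected
#'   internally.
#' @param threshold Named numeric of per-replicate threshold emPAI values
#'   (from [abundanceThreshold()]).
#' @param scores Named numeric vector of binding scores keyed by accession.
#' @param binderThreshold Score threshold, default 0.
#' @return Per-replicate list of selected U accessions.
#' @export
screenUncharacterised <- function(records, threshold, scores,
                                  binderThreshold = 0) {
  u <- records[records$category == "U", , drop = FALSE]
  reps <- names(threshold)
  out <- list()
  for (r in reps) {
    ur <- u[u$replicate == r & u$empai > threshold[[r]], , drop = FALSE]
    noscore <- setdiff(ur$accession, names(scores))
    if (length(noscore))
      stop("no binding score for above-threshold category-U protein(s): ",
           paste(noscore, collapse = ", "))
    out[[r]] <- ur$accession[scores[ur$accession] > binderThreshold]
  }
  out
}

#' Intersect per-replicate selections
#'
#' Proteins present in only one replicate are discarded as possible
#' contaminants: the candidate set is the intersection of the per-replicate
#' selections (by accession).
#'
#' @param sets List (length >= 2) of accession vectors, one per replicate.
#' @param requireBothReplicates If `FALSE`, the union is returned instead.
#' @return Character vector of accessions.
#' @export
intersectReplicates <- function(sets, requireBothReplicates = TRUE) {
  if (!requireBothReplicates)
    return(sort(unique(unlist(sets))))
  if (length(sets) < 2L)
    stop("replicate intersection requires >= 2 replicate sets")
  sort(Reduce(intersect, sets))
}

#' Curated list of experimentally verified NAPs/GRs
#'
#' Loads the shipped curated table of nucleoid-associated proteins and
#' global regulators verified in other studies (HupA, HupS, sIHF, Lsr2,
#' BldD, CRP), used only to flag rows of the candidate table.
#'
#' @return data.frame with columns `name`, `locus_tag`.
#' @export
knownNapList <- function() {
  read.delim(system.file("extdata", "known_naps.tsv",
                         package = "nucleoprofiler", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

.sanitizeRep <- function(r) gsub("[^A-Za-z0-9]", "_", r)

#' Build the merged candidate table
#'
#' Combines the selected category-D and category-U accessions into one
#' table with per-replicate emPAI and amalgamated rank (the rank of each
#' candidate within the merged D+U candidate pool, recomputed per
#' replicate), physico-chemical columns (computed from sequences when a
#' proteome is supplied, otherwise taken from `physchem`), binding scores
#' for category-U rows, and known-NAP flags. Rows are ordered by the first
#' replicate's amalgamated rank.
#'
#' @param dSelected,uSelected Final accession vectors (post-intersection);
#'   they must not overlap.
#' @param records Abundance data.frame covering the candidates.
#' @param proteins Optional [ProteinSet-class]; if supplied, `mw_kda` and
#'   `pi` are computed from the sequences and `locus_tag`/`name` are taken
#'   from it.
#' @param bindingScores Named numeric of binding scores (category-U rows).
#' @param knownNaps data.frame with a `locus_tag` column; default
#'   [knownNapList()].
#' @param physchem Optional data.frame with columns `accession`,
#'   `locus_tag`, `name`, `mw_kda`, `pi` used when no proteome is supplied.
#' @return data.frame, one row per candidate.
#' @export
buildCandidateTable <- function(dSelected, uSelected, records,
                                proteins = NULL, bindingScores = NULL,
                                knownNaps = knownNapList(),
                                physchem = NULL) {
  clash <- intersect(dSelected, uSelected)
  if (length(clash))
    stop("accession(s) in both D and U selections (categories are exclusive): ",
         paste(clash, collapse = ", "))
  acc <- c(dSelected, uSelected)
  if (length(acc) == 0L)
    return(data.frame(accession = character(), locus_tag = character(),
                      name = character(), category = character(),
                      known_nap = logical(), binding_score = numeric(),
                      mw_kda = numeric(), pi = numeric()))
  category <- setNames(c(rep("D", length(dSelected)),
                         rep("U", length(uSelected))), acc)

  pool <- records[records$accession %in% acc, , drop = FALSE]
  ranked <- rankByEmpai(pool)
  reps <- sort(unique(ranked$replicate))

  out <- data.frame(accession = acc, stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    sub <- proteins[acc]
    out$locus_tag <- unname(locusTags(sub))
    out$name <- unname(proteinNames(sub))
    out$mw_kda <- unname(molecularWeight(sequences(sub)))
    out$pi <- unname(isoelectricPoint(sequences(sub)))
  } else if (!is.null(physchem)) {
    idx <- match(acc, physchem$accession)
    out$locus_tag <- physchem$locus_tag[idx]
    out$name <- physchem$name[idx]
    out$mw_kda <- physchem$mw_kda[idx]
    out$pi <- physchem$pi[idx]
  } else {
    idx <- match(acc, records$accession)
    out$locus_tag <- if ("locus_tag" %in% names(records))
      records$locus_tag[idx] else NA_character_
    out$name <- NA_character_
    out$mw_kda <- NA_real_
    out$pi <- NA_real_
  }
  out$category <- unname(category[acc])
  out$known_nap <- out$locus_tag %in% knownNaps$locus_tag
  out$binding_score <- NA_real_
  if (!is.null(bindingScores)) {
    hit <- out$category == "U" & out$accession %in% names(bindingScores)
    out$binding_score[hit] <- unname(bindingScores[out$accession[hit]])
  }
  for (r in reps) {
    rr <- ranked[ranked$replicate == r, , drop = FALSE]
    idx <- match(acc, rr$accession)
    out[[paste0("empai_", .sanitizeRep(r))]] <- rr$empai[idx]
    out[[paste0("rank_", .sanitizeRep(r))]] <- rr$rank[idx]
  }
  firstRank <- out[[paste0("rank_", .sanitizeRep(reps[1L]))]]
  out <- out[order(firstRank, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full candidate-selection procedure
#'
#' Applies the abundance threshold to category D, the binding screen to
#' category U (scores computed from the proteome with `bindingModel` when
#' `bindingScores` is not supplied), intersects replicates, and builds the
#' merged candidate table.
#'
#' @param records Abundance data.frame (see [computeEmpai()] or
#'   [readStudyFixture()]).
#' @param bindingScores Optional named numeric of externally computed
#'   binding scores; takes precedence over model-based scoring.
#' @param proteins Optional [ProteinSet-class] (needed to compute scores
#'   and physchem columns from sequences).
#' @param config A [selectionConfig()].
#' @param bindingModel Model used when scores must be computed; default
#'   [defaultBindingModel()].
#' @param knownNaps,physchem Passed to [buildCandidateTable()].
#' @return List with elements `candidates` (the merged table),
#'   `threshold` (per-replicate category-D threshold emPAI),
#'   `dSelected`, `uSelected` (final accession vectors).
#' @export
selectCandidates <- function(records, bindingScores = NULL, proteins = NULL,
                             config = selectionConfig(),
                             bindingModel = NULL,
                             knownNaps = knownNapList(), physchem = NULL) {
  thr <- abundanceThreshold(records, config$topNd)
  if (is.null(bindingScores)) {
    uAcc <- unique(records$accession[records$category == "U"])
    if (length(uAcc)) {
      if (is.null(proteins))
        stop("supply bindingScores or a proteome to score category-U proteins")
      if (is.null(bindingModel)) bindingModel <- defaultBindingModel()
      bindingScores <- setNames(
        scoreBinding(sequences(proteins)[uAcc], bindingModel), uAcc)
    } else bindingScores <- numeric()
  }
  uSel <- screenUncharacterised(records, thr$threshold, bindingScores,
                                config$binderThreshold)
  dFinal <- intersectReplicates(thr$selected, config$requireBothReplicates)
  uFinal <- intersectReplicates(uSel, config$requireBothReplicates)
  tab <- buildCandidateTable(dFinal, uFinal, records, proteins = proteins,
                             bindingScores = bindingScores,
                             knownNaps = knownNaps, physchem = physchem)
  list(candidates = tab, threshold = thr$threshold,
       dSelected = dFinal, uSelected = uFinal)
}

#' Write the candidate report
#'
#' Writes `candidates.tsv` (fixed header, one row per candidate) and
#' `summary.txt` (counts per category, thresholds used and, when abundance
#' records are given, the per-replicate category composition). Output is
#' byte-identical across runs on identical input.
#'
#' @param selection Result of [selectCandidates()] (or a bare candidate
#'   data.frame).
#' @param dir Output directory (created if needed).
#' @param records Optional abundance data.frame for the composition block.
#' @return Invisible character vector of the files written.
#' @export
writeReport <- function(selection, dir, records = NULL) {
  if (is.data.frame(selection))
    selection <- list(candidates = selection, threshold = NULL)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  candPath <- file.path(dir, "candidates.tsv")
  write.table(selection$candidates, candPath, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "n/a")
  lines <- c("nucleoprofiler candidate report",
             sprintf("candidates: %d (D: %d, U: %d)",
                     nrow(selection$candidates),
                     sum(selection$candidates$category == "D"),
                     sum(selection$candidates$category == "U")),
             sprintf("known NAPs/GRs flagged: %d",
                     sum(selection$candidates$known_nap)))
  if (!is.null(selection$threshold))
    lines <- c(lines, sprintf("category-D abundance threshold (%s): %s",
                              names(selection$threshold),
                              format(selection$threshold, digits = 6)))
  if (!is.null(records)) {
    comp <- compositionSummary(records)
    lines <- c(lines, "category composition (% of summed emPAI):",
               sprintf("  %s %s: %.2f%%", comp$replicate, comp$category,
                       comp$percentage))
  }
  sumPath <- file.path(dir, "summary.txt")
  writeLines(lines, sumPath)
  invisible(c(candPath, sumPath))
}

#' Load the transcribed published candidate table
#'
#' The shipped study fixture is a transcription of the published 24-row
#' candidate table for the *Streptomyces coelicolor* nucleoid survey:
#' per-replicate emPAI scores and ranks, categories (18 D, 6 U), DNAbinder
#' scores for the U rows, molecular weight, pI and known-NAP flags. The
#' replicate-2 printed ranks are reproduced verbatim even though they are
#' internally inconsistent in the source; only replicate-1 ranks are
#' consecutive.
#'
#' @return List with `table` (the raw fixture), `abundance` (long-format
#'   records usable by the selection functions), `bindingScores` (named
#'   numeric, U rows) and `physchem` (accession, locus_tag, name, mw_kda,
#'   pi).
#' @export
readStudyFixture <- function() {
  path <- system.file("extdata", "study_candidates.tsv",
                      package = "nucleoprofiler", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$locus_tag <- paste0("SCO", tab$sco)
  long <- rbind(
    data.frame(accession = tab$accession, locus_tag = tab$locus_tag,
               category = tab$category, replicate = "rep1",
               empai = tab$empai_rep1, stringsAsFactors = FALSE),
    data.frame(accession = tab$accession, locus_tag = tab$locus_tag,
               category = tab$category, replicate = "rep2",
               empai = tab$empai_rep2, stringsAsFactors = FALSE))
  u <- tab$category == "U"
  list(table = tab,
       abundance = long,
       bindingScores = setNames(tab$dnabinder_score[u], tab$accession[u]),
       physchem = data.frame(accession = tab$accession,
                             locus_tag = tab$locus_tag, name = tab$name,
                             mw_kda = tab$mw_kda, pi = tab$pi,
                             stringsAsFactors = FALSE))
}
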