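# emPAI quantification from peptide identification evidence.

#' Read peptide identification evidence
#'
#' Tab-delimited export of identified peptides with columns `accession`,
#' `peptide`, `expect`, `replicate` and (optionally) `slice`; extra columns
#' are ignored. One row is one identified peptide occurrence; expect values
#' are the search engine's per-peptide significance statistic (lower is
#' more confident).
#'
#' @param path Path to a TSV file.
#' @return data.frame with the five canonical columns (slice `NA` when
#'   absent).
#' @export
readEvidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "peptide", "expect", "replicate")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  if (!"slice" %in% names(ev)) ev$slice <- NA_character_
  ev <- ev[, c(need, "slice")]
  ev$expect <- as.numeric(ev$expect)
  if (anyNA(ev$expect) || any(ev$expect < 0))
    stop("expect values must be numeric and >= 0")
  if (any(is.na(ev$peptide) | nchar(ev$peptide) == 0L))
    stop("peptide sequences must be non-empty")
  ev$peptide <- toupper(ev$peptide)
  ev$replicate <- as.character(ev$replicate)
  ev
}

#' Filter evidence by expect value and merge gel slices
#'
#' Retains rows with `expect <= expectThreshold` (boundary included), then
#' merges the gel slices of each replicate: the slice label is dropped and
#' duplicate (accession, peptide, replicate) occurrences collapse to one,
#' so a peptide seen in several slices of one replicate contributes once to
#' the observed-peptide count.
#'
#' @param evidence data.frame from [readEvidence()].
#' @param expectThreshold Retention threshold, default 0.05.
#' @return data.frame with columns `accession`, `peptide`, `replicate`.
#' @export
filterEvidence <- function(evidence, expectThreshold = 0.05) {
  if (!is.numeric(expectThreshold) || expectThreshold <= 0)
    stop("expectThreshold must be > 0")
  keep <- evidence[evidence$expect <= expectThreshold,
                   c("accession", "peptide", "replicate")]
  keep <- unique(keep)
  rownames(keep) <- NULL
  keep
}

#' Compute emPAI abundance records
#'
#' For each (protein, replicate) with at least one identified peptide:
#' `n_observed` is the number of distinct identified peptide sequences,
#' `n_observable` the count of in-silico observable tryptic peptides
#' ([countObservable()]), `pai = n_observed / n_observable` and
#' `empai = 10^pai - 1`. Proteins with no evidence in a replicate are
#' absent from that replicate's records rather than listed at zero.
#' Saturation for very abundant proteins (emPAI approaching `10^1 - 1 = 9`
#' when every observable peptide is seen) is a property of the index and is
#' not corrected.
#'
#' @param evidence Filtered evidence (see [filterEvidence()]).
#' @param proteins A [ProteinSet-class] covering every evidence accession.
#' @param window An [ObservabilityWindow-class].
#' @return data.frame with columns `accession`, `locus_tag`, `category`,
#'   `replicate`, `n_observed`, `n_observable`, `pai`, `empai`. Proteins
#'   lacking a category are reported as U with a warning.
#' @examples
#' ps <- proteinSet(strrep("AGLK", 30), "P1", category = "D")
#' ev <- data.frame(accession = "P1", peptide = "AGLKAGLK",
#'                  replicate = "rep1")
#' computeEmpai(ev, ps)
#' @export
computeEmpai <- function(evidence, proteins,
                         window = observabilityWindow()) {
  validObject(window)
  missing <- setdiff(unique(evidence$accession), accessions(proteins))
  if (length(missing))
    stop("evidence accession(s) absent from proteome: ",
         paste(missing, collapse = ", "))
  if (nrow(evidence) == 0L)
    return(data.frame(accession = character(), locus_tag = character(),
                      category = character(), replicate = character(),
                      n_observed = integer(), n_observable = integer(),
                      pai = numeric(), empai = numeric()))
  ev <- unique(evidence[, c("accession", "peptide", "replicate")])
  agg <- aggregate(peptide ~ accession + replicate, data = ev, FUN = length)
  names(agg)[names(agg) == "peptide"] <- "n_observed"

  accs <- unique(agg$accession)
  seqs <- as.character(sequences(proteins)[accs])
  nobs <- vapply(seqs, countObservable, integer(1L), window = window,
                 USE.NAMES = FALSE)
  names(nobs) <- accs
  if (any(nobs == 0L))
    stop("protein(s) with identified peptides but zero observable peptides: ",
         paste(accs[nobs == 0L], collapse = ", "),
         " (observability window too narrow for these sequences)")
  agg$n_observable <- unname(nobs[agg$accession])
  agg$pai <- agg$n_observed / agg$n_observable
  agg$empai <- 10^agg$pai - 1

  idx <- match(agg$accession, accessions(proteins))
  agg$locus_tag <- proteins@locusTag[idx]
  cat <- proteins@category[idx]
  if (anyNA(cat)) {
    warning("protein(s) without category assigned default to U: ",
            paste(unique(agg$accession[is.na(cat)]), collapse = ", "))
    cat[is.na(cat)] <- "U"
  }
  agg$category <- cat
  agg <- agg[order(agg$replicate, agg$accession),
             c("accession", "locus_tag", "category", "replicate",
               "n_observed", "n_observable", "pai", "empai")]
  rownames(agg) <- NULL
  agg
}

.applyScope <- function(records, scope) {
  if (is.null(scope)) return(records)
  if (is.function(scope)) return(records[scope(records), , drop = FALSE])
  if (is.character(scope))
    return(records[records$category %in% scope, , drop = FALSE])
  stop("scope must be NULL, a category vector or a predicate function")
}

#' Rank abundance records by emPAI
#'
#' Assigns 1-based ranks by descending emPAI within each replicate, over
#' the records selected by `scope` (e.g. `"D"` to rank the annotated
#' DNA-binding proteins only, or `NULL` for all). Ties are broken by
#' ascending accession so ranking is deterministic; within each
#' (scope, replicate) the ranks are a permutation of `1..n`.
#'
#' @param records Abundance data.frame from [computeEmpai()].
#' @param scope `NULL`, a character vector of categories, or a predicate
#'   `function(records) -> logical`.
#' @return The selected records with a `rank` column, ordered by replicate
#'   then rank.
#' @export
rankByEmpai <- function(records, scope = NULL) {
  rec <- .applyScope(records, scope)
  if (nrow(rec) == 0L) {
    rec$rank <- integer()
    return(rec)
  }
  parts <- lapply(split(rec, rec$replicate), function(d) {
    d <- d[order(-d$empai, d$accession), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Category composition by summed emPAI
#'
#' Per replicate, the summed emPAI of each functional category as a
#' percentage of the total summed emPAI — the approximate protein-mass
#' composition of the fraction.
#'
#' @param records Abundance data.frame with `category`, `replicate`,
#'   `empai` columns.
#' @return data.frame with columns `replicate`, `category`,
#'   `summed_empai`, `percentage`; percentages sum to 100 within each
#'   replicate. All five categories are reported (zero rows included).
#' @export
compositionSummary <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(replicate = character(), category = character(),
                      summed_empai = numeric(), percentage = numeric()))
  parts <- lapply(split(records, records$replicate), function(d) {
    s <- vapply(.CATEGORIES,
                function(k) sum(d$empai[d$category == k]), numeric(1L))
    data.frame(replicate = d$replicate[1L], category = .CATEGORIES,
               summed_empai = unname(s),
               percentage = unname(100 * s / sum(s)))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
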