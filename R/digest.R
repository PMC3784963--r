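# In-silico tryptic digestion and the observability count feeding the
# emPAI denominator.

#' Tryptic (trypsin/P) digestion of a protein sequence
#'
#' Cleaves after every K or R with no proline exception (the trypsin/P
#' rule) and enumerates all peptides carrying up to `maxMissedCleavages`
#' internal uncut sites. Peptides are returned ordered by start then end
#' position (1-based, inclusive); the zero-missed-cleavage peptides
#' partition the parent sequence.
#'
#' @param sequence A single amino-acid sequence.
#' @param maxMissedCleavages Maximum internal cleavage sites per peptide;
#'   default 2.
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`. Empty sequence gives zero rows.
#' @examples
#' digestTryptic("MKRAG", 1)
#' @export
digestTryptic <- function(sequence, maxMissedCleavages = 2L) {
  if (maxMissedCleavages < 0L) stop("maxMissedCleavages must be >= 0")
  if (methods::is(sequence, "AAString") || methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)[1L]
  if (is.na(sequence) || nchar(sequence) == 0L)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # fragment boundaries: after every K/R, plus the sequence end
  cuts <- unique(c(which(res %in% c("K", "R")), n))
  starts <- c(1L, utils::head(cuts, -1L) + 1L)
  ends <- cuts
  nf <- length(starts)
  out <- vector("list", maxMissedCleavages + 1L)
  for (mc in 0:maxMissedCleavages) {
    if (mc >= nf) break
    i <- seq_len(nf - mc)
    out[[mc + 1L]] <- data.frame(
      start = starts[i], end = ends[i + mc],
      missed_cleavages = mc)
  }
  pep <- do.call(rbind, out)
  pep$peptide <- substring(sequence, pep$start, pep$end)
  pep <- pep[order(pep$start, pep$end),
             c("peptide", "start", "end", "missed_cleavages")]
  rownames(pep) <- NULL
  pep
}

#' Peptide precursor m/z
#'
#' `(M + z * m_proton) / z` where `M` is the monoisotopic neutral peptide
#' mass (sum of monoisotopic residue masses plus one water; see
#' [residueMasses()]).
#'
#' @param peptide Character vector of peptide sequences.
#' @param charge Positive integer charge state (scalar).
#' @return Numeric vector of m/z values.
#' @examples
#' peptideMz("GASK", 2)
#' @export
peptideMz <- function(peptide, charge) {
  if (length(charge) != 1L || charge < 1L)
    stop("charge must be a single integer >= 1")
  vapply(peptide, function(p) {
    chk <- .checkSequence(p, "error")
    M <- sum(.MASS_MONO[chk$residues]) + .MASS_WATER_MONO
    (M + charge * .MASS_PROTON) / charge
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Observable tryptic peptides of a protein
#'
#' The distinct peptide sequences from [digestTryptic()] that the
#' instrument could have selected: at least `minLength` residues and an m/z
#' within the scan window at one or more of the considered charge states.
#' Duplicate peptide sequences within a protein count once, matching the
#' distinct-peptide convention of the emPAI numerator.
#'
#' @param sequence A single amino-acid sequence.
#' @param window An [ObservabilityWindow-class].
#' @return Character vector of distinct observable peptide sequences.
#' @export
observablePeptides <- function(sequence, window = observabilityWindow()) {
  validObject(window)
  pep <- unique(digestTryptic(sequence, window@maxMissedCleavages)$peptide)
  pep <- pep[nchar(pep) >= window@minLength]
  if (length(pep) == 0L) return(character())
  ok <- rep(FALSE, length(pep))
  for (z in window@charges) {
    mz <- peptideMz(pep, z)
    ok <- ok | (mz >= window@mzMin & mz <= window@mzMax)
  }
  pep[ok]
}

#' Count observable peptides (emPAI denominator)
#'
#' @inheritParams observablePeptides
#' @return Integer count of distinct observable peptides.
#' @examples
#' countObservable(strrep("AGLK", 20))
#' @export
countObservable <- function(sequence, window = observabilityWindow()) {
  length(observablePeptides(sequence, window))
}
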