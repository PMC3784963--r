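#' ProteinSet: a proteome with annotation
#'
#' Container for a set of protein records: amino-acid sequences (as a
#' [Biostrings::AAStringSet] named by accession) together with locus tags,
#' free-text descriptions and the five-way functional category used by the
#' nucleoid survey: R (ribosomal), C (chaperone/redox), D (DNA-binding),
#' U (unknown function), E (enzyme/cytosolic/membrane). Categories may be
#' `NA` until [assignCategories()] is applied.
#'
#' @slot sequences [Biostrings::AAStringSet], names are accessions (unique).
#' @slot locusTag character, locus tags (e.g. "SCO1480"), parallel to
#'   sequences.
#' @slot protName character, free-text descriptions.
#' @slot category character, one of "R","C","D","U","E" or `NA`.
#'
#' @aliases ProteinSet-class
#' @export
setClass("ProteinSet",
  representation(
    sequences = "AAStringSet",
    locusTag  = "character",
    protName  = "character",
    category  = "character"
  )
)

.CATEGORIES <- c("R", "C", "D", "U", "E")

setValidity("ProteinSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (is.null(names(object@sequences)) && n > 0L)
    msgs <- c(msgs, "sequences must be named by accession")
  acc <- names(object@sequences)
  if (anyDuplicated(acc))
    msgs <- c(msgs, paste0("duplicate accession(s): ",
                           paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  if (length(object@locusTag) != n || length(object@protName) != n ||
      length(object@category) != n)
    msgs <- c(msgs, "locusTag, protName and category must parallel sequences")
  if (n > 0L) {
    if (any(Biostrings::width(object@sequences) == 0L))
      msgs <- c(msgs, "empty sequence(s) are not allowed")
    freq <- Biostrings::alphabetFrequency(object@sequences)
    nonstd <- setdiff(colnames(freq), .AA_STANDARD)
    bad <- rowSums(freq[, nonstd, drop = FALSE]) > 0
    if (any(bad))
      msgs <- c(msgs, paste0("nonstandard residue letters in: ",
                             paste(utils::head(acc[bad], 5L), collapse = ", ")))
    okcat <- is.na(object@category) | object@category %in% .CATEGORIES
    if (!all(okcat))
      msgs <- c(msgs, "category must be one of R, C, D, U, E or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences Character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences (upper-cased on input).
#' @param accession Character vector of unique accessions.
#' @param locusTag,protName,category Optional parallel character vectors;
#'   default `NA`.
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- proteinSet(c("MAK", "GASR"), accession = c("P1", "P2"))
#' accessions(ps)
#' @export
proteinSet <- function(sequences, accession,
                       locusTag = NA_character_,
                       protName = NA_character_,
                       category = NA_character_) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(toupper(sequences))
  n <- length(sequences)
  if (length(accession) != n)
    stop("accession must parallel sequences")
  names(sequences) <- as.character(accession)
  new("ProteinSet",
      sequences = sequences,
      locusTag  = rep_len(as.character(locusTag), n),
      protName  = rep_len(as.character(protName), n),
      category  = rep_len(as.character(category), n))
}

#' ObservabilityWindow: which peptides the instrument can see
#'
#' Parameters deciding whether an in-silico tryptic peptide counts as
#' "observable" for the emPAI denominator: a precursor m/z scan window, the
#' precursor charge states selected for fragmentation, a minimum peptide
#' length, and the maximum number of missed cleavages allowed by the search.
#'
#' Defaults mirror a typical Orbitrap survey: m/z 350-1800, 2+/3+
#' precursors, 2 missed cleavages; the 6-residue length floor is the
#' conventional minimum identifiable tryptic peptide.
#'
#' @slot mzMin,mzMax numeric scan window bounds (m/z).
#' @slot charges integer vector of precursor charges considered.
#' @slot minLength integer minimum peptide length (residues).
#' @slot maxMissedCleavages integer maximum missed cleavages.
#'
#' @aliases ObservabilityWindow-class
#' @export
setClass("ObservabilityWindow",
  representation(
    mzMin = "numeric", mzMax = "numeric", charges = "integer",
    minLength = "integer", maxMissedCleavages = "integer"
  )
)

setValidity("ObservabilityWindow", function(object) {
  msgs <- character()
  if (length(object@mzMin) != 1L || length(object@mzMax) != 1L ||
      !is.finite(object@mzMin) || !is.finite(object@mzMax))
    msgs <- c(msgs, "mzMin and mzMax must be finite scalars")
  else if (object@mzMin >= object@mzMax)
    msgs <- c(msgs, "mzMin must be < mzMax")
  if (length(object@charges) == 0L || any(object@charges < 1L))
    msgs <- c(msgs, "charges must be a non-empty set of integers >= 1")
  if (object@minLength < 1L)
    msgs <- c(msgs, "minLength must be >= 1")
  if (object@maxMissedCleavages < 0L)
    msgs <- c(msgs, "maxMissedCleavages must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @param mzMin,mzMax Scan window bounds (m/z); defaults 350 and 1800.
#' @param charges Precursor charges; default `c(2L, 3L)`.
#' @param minLength Minimum peptide length; default 6.
#' @param maxMissedCleavages Maximum missed cleavages; default 2.
#' @return An [ObservabilityWindow-class] object.
#' @examples
#' observabilityWindow()
#' @rdname ObservabilityWindow-class
#' @export
observabilityWindow <- function(mzMin = 350, mzMax = 1800,
                                charges = c(2L, 3L),
                                minLength = 6L, maxMissedCleavages = 2L) {
  new("ObservabilityWindow",
      mzMin = as.numeric(mzMin), mzMax = as.numeric(mzMax),
      charges = as.integer(charges),
      minLength = as.integer(minLength),
      maxMissedCleavages = as.integer(maxMissedCleavages))
}

#' BindingModel: affine DNA-binding propensity scorer
#'
#' A linear model over amino-acid composition fractions: the score of a
#' sequence is `sum(weights * composition) + bias`, and scores strictly
#' above zero flag a predicted nucleic-acid binder. Train one with
#' [trainBindingModel()] or load the shipped synthetic default with
#' [defaultBindingModel()].
#'
#' @slot weights Named numeric of length 20 (one weight per standard
#'   residue letter).
#' @slot bias Numeric scalar.
#' @slot provenance Free-text description of the training data.
#'
#' @aliases BindingModel-class
#' @export
setClass("BindingModel",
  representation(weights = "numeric", bias = "numeric",
                 provenance = "character")
)

setValidity("BindingModel", function(object) {
  msgs <- character()
  if (length(object@weights) != 20L ||
      !setequal(names(object@weights), .AA_STANDARD))
    msgs <- c(msgs, "weights must be named by the 20 standard residues")
  if (!all(is.finite(object@weights)))
    msgs <- c(msgs, "weights must be finite")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    msgs <- c(msgs, "bias must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BindingModel
#'
#' @param weights Named numeric of length 20 (names: standard residue
#'   letters, any order).
#' @param bias Numeric scalar.
#' @param provenance Description of where the weights came from.
#' @return A [BindingModel-class] object.
#' @export
bindingModel <- function(weights, bias = 0,
                         provenance = "unspecified") {
  new("BindingModel",
      weights = weights[.AA_STANDARD],
      bias = as.numeric(bias),
      provenance = as.character(provenance))
}
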