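# Proteome I/O, categorisation and physico-chemical sequence features.

.DEFAULT_HEADER <- "^(?<accession>[^|[:space:]]+)\\|(?<locus_tag>[^[:space:]]+)[[:space:]]*(?<name>.*)$"

.matchHeader <- function(headers, pattern) {
  m <- regexpr(pattern, headers, perl = TRUE)
  if (any(m == -1L))
    stop("FASTA header(s) not matching the header grammar: ",
         paste(utils::head(headers[m == -1L], 3L), collapse = "; "))
  st <- attr(m, "capture.start")
  ln <- attr(m, "capture.length")
  grab <- function(grp) {
    if (!grp %in% colnames(st))
      stop("header grammar must define named groups 'accession' and 'locus_tag'")
    substr(headers, st[, grp], st[, grp] + ln[, grp] - 1L)
  }
  nm <- if ("name" %in% colnames(st)) grab("name") else rep("", length(headers))
  data.frame(accession = grab("accession"), locus_tag = grab("locus_tag"),
             name = trimws(nm), stringsAsFactors = FALSE)
}

#' Read a protein FASTA into a ProteinSet
#'
#' Parses a protein FASTA whose identifier lines carry an accession and a
#' locus tag. The header grammar is a Perl regular expression with named
#' capture groups `accession`, `locus_tag` and (optionally) `name`; the
#' default handles headers of the form `>ACC|LOCUS free-text description`.
#' Sequences are upper-cased; nonstandard residue letters and duplicate
#' accessions are rejected.
#'
#' @param path Path to a FASTA file.
#' @param headerPattern Perl regex with named groups; see Details.
#' @return A [ProteinSet-class] with categories unset (`NA`).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">Q9KXR9|SCO1480 sIHF", "MAK"), f)
#' readProteomeFasta(f)
#' @export
readProteomeFasta <- function(path, headerPattern = .DEFAULT_HEADER) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(proteinSet(character(), character()))
  hdr <- .matchHeader(names(aa), headerPattern)
  if (anyDuplicated(hdr$accession))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(hdr$accession[duplicated(hdr$accession)]),
               collapse = ", "))
  proteinSet(toupper(as.character(aa)), accession = hdr$accession,
             locusTag = hdr$locus_tag, protName = hdr$name)
}

#' Read an annotation table
#'
#' Tab-delimited table with columns `accession`, `locus_tag`, `description`
#' and (optionally) `category_override`; extra columns are ignored.
#' Per-accession overrides take precedence over keyword rules in
#' [assignCategories()].
#'
#' @param path Path to a TSV file.
#' @return data.frame with the four canonical columns.
#' @export
readAnnotations <- function(path) {
  an <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "locus_tag", "description")
  miss <- setdiff(need, names(an))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"category_override" %in% names(an))
    an$category_override <- NA_character_
  an$category_override[an$category_override %in% c("", "NA")] <- NA_character_
  bad <- !is.na(an$category_override) &
    !an$category_override %in% .CATEGORIES
  if (any(bad))
    stop("invalid category_override value(s): ",
         paste(unique(an$category_override[bad]), collapse = ", "))
  an[, c(need, "category_override")]
}

#' Read a category-rule table
#'
#' Keyword rules mapping protein descriptions to the five functional
#' categories. Columns: `pattern` (regular expression matched
#' case-insensitively against the description), `category` (R/C/D/U/E) and
#' `priority` (integer; lower wins). The lowest-priority rule should be a
#' catch-all assigning U so that assignment is total.
#'
#' @param path Path to a TSV file.
#' @return data.frame ordered by priority.
#' @export
readCategoryRules <- function(path) {
  ru <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "category", "priority")
  miss <- setdiff(need, names(ru))
  if (length(miss))
    stop("rule table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(ru$category %in% .CATEGORIES))
    stop("rule categories must be one of R, C, D, U, E")
  ru[order(ru$priority), need]
}

#' Default category rules shipped with the package
#'
#' @return data.frame of keyword rules ending in a catch-all U rule.
#' @export
defaultCategoryRules <- function() {
  readCategoryRules(system.file("extdata", "category_rules.tsv",
                                package = "nucleoprofiler", mustWork = TRUE))
}

#' Assign functional categories to a proteome
#'
#' Applies keyword rules (lowest priority number wins; first match decides)
#' to each protein's description, then applies per-accession overrides from
#' the annotation table, which always take precedence. The rule set must
#' contain a catch-all so every protein receives exactly one of the five
#' categories; assignment is deterministic and idempotent.
#'
#' @param proteins A [ProteinSet-class].
#' @param rules data.frame from [readCategoryRules()] /
#'   [defaultCategoryRules()].
#' @param overrides Optional annotation data.frame (from
#'   [readAnnotations()]) or a named character vector
#'   (accession -> category).
#' @return The `ProteinSet` with categories set.
#' @export
assignCategories <- function(proteins, rules = defaultCategoryRules(),
                             overrides = NULL) {
  if (nrow(rules) == 0L) stop("rules must be non-empty")
  rules <- rules[order(rules$priority), ]
  if (!any(vapply(rules$pattern, function(p)
        grepl(p, "arbitrary-unmatched-description", ignore.case = TRUE),
        logical(1L))))
    stop("rules must include a catch-all default (e.g. pattern '.*' -> U)")
  desc <- proteins@protName
  desc[is.na(desc)] <- ""
  cat <- rep(NA_character_, length(proteins))
  for (k in seq_len(nrow(rules))) {
    hit <- is.na(cat) & grepl(rules$pattern[k], desc, ignore.case = TRUE)
    cat[hit] <- rules$category[k]
  }
  cat[is.na(cat)] <- "U"
  if (!is.null(overrides)) {
    if (is.data.frame(overrides)) {
      ov <- overrides$category_override
      names(ov) <- overrides$accession
      ov <- ov[!is.na(ov)]
    } else ov <- overrides
    idx <- match(names(ov), accessions(proteins))
    cat[idx[!is.na(idx)]] <- unname(ov[!is.na(idx)])
  }
  proteins@category <- cat
  validObject(proteins)
  proteins
}

.checkSequence <- function(sequence, nonstandard = c("error", "average")) {
  nonstandard <- match.arg(nonstandard)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(res %in% .AA_STANDARD)
  if (any(bad) && nonstandard == "error")
    stop("nonstandard residue letter(s): ",
         paste(unique(res[bad]), collapse = ", "))
  list(residues = res, nonstandard = bad)
}

#' Protein molecular weight (kDa)
#'
#' Sum of average residue masses plus one water, in kilodaltons; the mass
#' table is available via [residueMasses()]. By default any letter outside
#' the 20 standard residues is an error; `nonstandard = "average"`
#' substitutes the mean residue mass for unknown letters (useful for
#' database sequences containing X).
#'
#' @param sequence Character vector of amino-acid sequences (or an
#'   [Biostrings::AAStringSet]).
#' @param nonstandard `"error"` (default) or `"average"`.
#' @return Numeric vector of masses in kDa.
#' @examples
#' molecularWeight("G")  # 0.0750672 kDa
#' @export
molecularWeight <- function(sequence, nonstandard = c("error", "average")) {
  nonstandard <- match.arg(nonstandard)
  if (methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  vapply(sequence, function(s) {
    chk <- .checkSequence(s, nonstandard)
    m <- .MASS_AVERAGE[chk$residues]
    m[chk$nonstandard] <- mean(.MASS_AVERAGE)
    (sum(m) + .MASS_WATER_AVERAGE) / 1000
  }, numeric(1L), USE.NAMES = !is.null(names(sequence)))
}

.netCharge <- function(pH, counts, pka) {
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- -1 / (1 + 10^(pka$cterm - pH))
  for (r in c("K", "R", "H"))
    pos <- pos + counts[[r]] / (1 + 10^(pH - pka[[r]]))
  for (r in c("D", "E", "C", "Y"))
    neg <- neg - counts[[r]] / (1 + 10^(pka[[r]] - pH))
  pos + neg
}

#' Protein isoelectric point
#'
#' pH at which the modelled net charge is zero under a
#' Henderson-Hasselbalch charge model with the Bjellqvist-style pKa set
#' (see [pkaSet()]): one positive term per N-terminus/K/R/H, one negative
#' term per C-terminus/D/E/C/Y. The net charge is strictly decreasing in
#' pH, so the root on \[0, 14\] is unique; it is located by bisection to a
#' tolerance of 1e-4.
#'
#' @param sequence Character vector of sequences (or
#'   [Biostrings::AAStringSet]).
#' @param pka pKa configuration, default [pkaSet()]`("bjellqvist")`.
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values in pH units.
#' @examples
#' isoelectricPoint("ACDEFGHIKLMNPQRSTVWY")
#' @export
isoelectricPoint <- function(sequence, pka = pkaSet(), tol = 1e-4) {
  if (methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  vapply(sequence, function(s) {
    chk <- .checkSequence(s, "error")
    counts <- as.list(table(factor(chk$residues, levels = .AA_STANDARD)))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.netCharge(mid, counts, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1L), USE.NAMES = !is.null(names(sequence)))
}
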