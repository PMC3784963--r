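# Amino-acid-composition DNA/RNA-binding propensity scoring. Nucleic-acid
# binders tend to be enriched in lysine, arginine and glutamic acid; a
# linear model over composition fractions captures this, with scores
# strictly above zero flagging predicted binders.

#' Amino-acid composition of sequences
#'
#' Per-residue counts divided by sequence length, for the 20 standard
#' residues. Composition is invariant under any permutation of the
#' sequence; fractions sum to 1.
#'
#' @param sequence Character vector of non-empty sequences (or an
#'   [Biostrings::AAStringSet]).
#' @return Numeric matrix, one row per sequence, 20 named columns.
#' @examples
#' aaComposition("KR")
#' @export
aaComposition <- function(sequence) {
  if (is.character(sequence)) {
    if (any(is.na(sequence) | nchar(sequence) == 0L))
      stop("sequences must be non-empty")
    sequence <- Biostrings::AAStringSet(toupper(sequence))
  }
  if (any(Biostrings::width(sequence) == 0L))
    stop("sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(sequence)
  nonstd <- setdiff(colnames(freq), .AA_STANDARD)
  if (any(freq[, nonstd] > 0))
    stop("nonstandard residue letters in input sequences")
  freq <- freq[, .AA_STANDARD, drop = FALSE]
  freq / rowSums(freq)
}

.asComposition <- function(x) {
  if (is.character(x) || methods::is(x, "AAStringSet"))
    return(aaComposition(x))
  if (is.matrix(x)) {
    if (!all(.AA_STANDARD %in% colnames(x)))
      stop("composition matrix must have the 20 standard residue columns")
    return(x[, .AA_STANDARD, drop = FALSE])
  }
  if (is.numeric(x) && length(x) == 20L) {
    if (!setequal(names(x), .AA_STANDARD))
      stop("composition vector must be named by the 20 standard residues")
    return(matrix(x[.AA_STANDARD], nrow = 1L,
                  dimnames = list(NULL, .AA_STANDARD)))
  }
  stop("x must be sequences, a composition vector or a composition matrix")
}

#' Score binding propensity
#'
#' Affine score `sum(weights * composition) + bias` under a
#' [BindingModel-class]. Accepts raw sequences, a single named composition
#' vector, or a composition matrix.
#'
#' @param x Sequences or composition (see [aaComposition()]).
#' @param model A [BindingModel-class]; default [defaultBindingModel()].
#' @return Numeric vector of scores.
#' @export
scoreBinding <- function(x, model = defaultBindingModel()) {
  validObject(model)
  comp <- .asComposition(x)
  drop(comp %*% model@weights[.AA_STANDARD]) + model@bias
}

#' Binder call from a score
#'
#' Scores strictly above the threshold (default 0) flag a predicted
#' nucleic-acid binder; a score of exactly zero is not a call.
#'
#' @param score Numeric vector of scores.
#' @param threshold Decision threshold, default 0.
#' @return Logical vector.
#' @examples
#' isBinder(c(0.59, 0.03, 0, -0.1))
#' @export
isBinder <- function(score, threshold = 0) {
  score > threshold
}

#' Train a linear binding model on labelled compositions
#'
#' Fits a maximum-margin linear separator (linear-kernel support vector
#' machine on unscaled composition fractions) to labelled sequences and
#' returns the equivalent affine [BindingModel-class]. The sign is oriented
#' so binders score positive. Training is deterministic given the seed.
#'
#' @param sequence Character vector of training sequences.
#' @param label Binary labels (1/TRUE = binder, 0/FALSE = non-binder); at
#'   least two examples of each class are required.
#' @param cost Soft-margin cost parameter, default 10.
#' @param seed Integer seed, default 1.
#' @param provenance Optional free-text description of the training data.
#' @return A [BindingModel-class].
#' @export
trainBindingModel <- function(sequence, label, cost = 10, seed = 1L,
                              provenance = NULL) {
  label <- as.integer(as.logical(label))
  if (length(label) != length(sequence))
    stop("label must parallel sequence")
  if (sum(label == 1L) < 2L || sum(label == 0L) < 2L)
    stop("need at least 2 examples of each class (binder / non-binder)")
  comp <- aaComposition(sequence)
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = comp, y = factor(label, levels = c(0L, 1L)),
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient so that binders (label 1) score higher
  sc <- drop(comp %*% w) + b
  if (mean(sc[label == 1L]) < mean(sc[label == 0L])) {
    w <- -w; b <- -b
  }
  if (is.null(provenance))
    provenance <- sprintf(
      "linear SVM on composition fractions: %d binders, %d non-binders, cost=%g, seed=%d",
      sum(label == 1L), sum(label == 0L), cost, as.integer(seed))
  bindingModel(setNames(as.numeric(w[.AA_STANDARD]), .AA_STANDARD),
               bias = b, provenance = provenance)
}

#' Write / read a BindingModel as JSON
#'
#' The JSON carries the 20 residue weights (keyed by residue letter), the
#' bias and a provenance string; reading round-trips exactly.
#'
#' @param model A [BindingModel-class].
#' @param path Output / input file path.
#' @return `writeBindingModel` returns `path` invisibly;
#'   `readBindingModel` returns the model.
#' @export
writeBindingModel <- function(model, path) {
  validObject(model)
  jsonlite::write_json(
    list(weights = as.list(model@weights), bias = model@bias,
         provenance = model@provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeBindingModel
#' @export
readBindingModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$weights) || is.null(obj$bias))
    stop("model JSON must contain 'weights' and 'bias'")
  bindingModel(unlist(obj$weights), bias = obj$bias,
               provenance = if (is.null(obj$provenance)) "unspecified"
                            else obj$provenance)
}

#' The shipped default binding model
#'
#' A synthetic model: a linear SVM trained once on the package's own
#' generated binding fixture (basic-residue-enriched binders vs
#' acidic/hydrophobic non-binders; see [generateBindingFixture()]). It
#' reproduces the role of composition-based binding screens — not the
#' weights of any published tool — so externally computed scores can always
#' be supplied instead wherever a score column is accepted.
#'
#' @return A [BindingModel-class].
#' @export
defaultBindingModel <- function() {
  readBindingModel(system.file("extdata", "binding_model_default.json",
                               package = "nucleoprofiler", mustWork = TRUE))
}
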