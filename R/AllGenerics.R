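#' @rdname ProteinSet-class
#' @param x,object A `ProteinSet`.
#' @param value Replacement value.
#' @param i Index for subsetting.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname ProteinSet-class
#' @export
setGeneric("locusTags", function(x) standardGeneric("locusTags"))

#' @rdname ProteinSet-class
#' @export
setGeneric("proteinNames", function(x) standardGeneric("proteinNames"))

#' @rdname ProteinSet-class
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname ProteinSet-class
#' @export
setGeneric("categories<-", function(x, value) standardGeneric("categories<-"))

#' @rdname ProteinSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname BindingModel-class
#' @param x,object A `BindingModel`.
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname BindingModel-class
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

#' @rdname BindingModel-class
#' @export
setGeneric("modelProvenance", function(x) standardGeneric("modelProvenance"))

#' @rdname ProteinSet-class
#' @export
setMethod("accessions", "ProteinSet", function(x) names(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("locusTags", "ProteinSet", function(x) {
  setNames(x@locusTag, names(x@sequences))
})

#' @rdname ProteinSet-class
#' @export
setMethod("proteinNames", "ProteinSet", function(x) {
  setNames(x@protName, names(x@sequences))
})

#' @rdname ProteinSet-class
#' @export
setMethod("categories", "ProteinSet", function(x) {
  setNames(x@category, names(x@sequences))
})

#' @rdname ProteinSet-class
#' @export
setReplaceMethod("categories", "ProteinSet", function(x, value) {
  if (!is.null(names(value))) {
    idx <- match(names(x@sequences), names(value))
    if (anyNA(idx))
      stop("categories<-: missing categories for some accessions")
    value <- value[idx]
  }
  x@category <- unname(as.character(value))
  validObject(x)
  x
})

#' @rdname ProteinSet-class
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("names", "ProteinSet", function(x) names(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("[", "ProteinSet", function(x, i) {
  if (is.character(i)) {
    i <- match(i, names(x@sequences))
    if (anyNA(i)) stop("unknown accession(s) in subset")
  }
  new("ProteinSet",
      sequences = x@sequences[i],
      locusTag  = x@locusTag[i],
      protName  = x@protName[i],
      category  = x@category[i])
})

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  cat("ProteinSet with", n, "proteins\n")
  if (n > 0L) {
    tab <- table(factor(object@category, levels = .CATEGORIES),
                 useNA = "ifany")
    cat("  categories:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
    cat("  sequence length range:",
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        "\n")
  }
  invisible(NULL)
})

#' @rdname BindingModel-class
#' @export
setMethod("modelWeights", "BindingModel", function(x) x@weights)

#' @rdname BindingModel-class
#' @export
setMethod("modelBias", "BindingModel", function(x) x@bias)

#' @rdname BindingModel-class
#' @export
setMethod("modelProvenance", "BindingModel", function(x) x@provenance)

setMethod("show", "BindingModel", function(object) {
  top <- sort(object@weights, decreasing = TRUE)[1:3]
  cat("BindingModel (affine over residue composition)\n")
  cat("  bias:", format(object@bias, digits = 4), "\n")
  cat("  largest weights:",
      paste(names(top), format(top, digits = 3), sep = "=", collapse = " "),
      "\n")
  cat("  provenance:", object@provenance, "\n")
  invisible(NULL)
})

setMethod("show", "ObservabilityWindow", function(object) {
  cat("ObservabilityWindow: m/z [", object@mzMin, ", ", object@mzMax,
      "], charges {", paste(object@charges, collapse = ","),
      "}, minLength ", object@minLength,
      ", maxMissedCleavages ", object@maxMissedCleavages, "\n", sep = "")
  invisible(NULL)
})
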