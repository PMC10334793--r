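#' @rdname SeEventSet-class
#' @param x,object an object.
#' @param ... unused.
#' @export
setGeneric("ijc", function(x, ...) standardGeneric("ijc"))

#' @rdname SeEventSet-class
#' @export
setGeneric("sjc", function(x, ...) standardGeneric("sjc"))

#' @rdname SeEventSet-class
#' @export
setGeneric("incFormLen", function(x, ...) standardGeneric("incFormLen"))

#' @rdname SeEventSet-class
#' @export
setGeneric("skipFormLen", function(x, ...) standardGeneric("skipFormLen"))

#' @rdname PsiExperiment-class
#' @param x an object.
#' @param ... unused.
#' @export
setGeneric("psiValues", function(x, ...) standardGeneric("psiValues"))

#' @rdname PsiExperiment-class
#' @export
setGeneric("totalReads", function(x, ...) standardGeneric("totalReads"))

#' @rdname ActivityScores-class
#' @param x an object.
#' @param ... unused.
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname ActivityScores-class
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname ActivityScores-class
#' @export
setGeneric("genesetName", function(x, ...) standardGeneric("genesetName"))

#' @rdname NormalizedExpression-class
#' @param x an object.
#' @param ... unused.
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

# ---- methods ----

#' @rdname SeEventSet-class
#' @export
setMethod("ijc", "SeEventSet", function(x, ...) assay(x, "ijc"))

#' @rdname SeEventSet-class
#' @export
setMethod("sjc", "SeEventSet", function(x, ...) assay(x, "sjc"))

#' @rdname SeEventSet-class
#' @export
setMethod("incFormLen", "SeEventSet", function(x, ...)
  stats::setNames(rowData(x)$incFormLen, rownames(x)))

#' @rdname SeEventSet-class
#' @export
setMethod("skipFormLen", "SeEventSet", function(x, ...)
  stats::setNames(rowData(x)$skipFormLen, rownames(x)))

#' @rdname PsiExperiment-class
#' @export
setMethod("psiValues", "PsiExperiment", function(x, ...) assay(x, "psi"))

#' @rdname PsiExperiment-class
#' @export
setMethod("totalReads", "PsiExperiment", function(x, ...) assay(x, "total"))

#' @rdname ActivityScores-class
#' @export
setMethod("scores", "ActivityScores", function(x, ...)
  stats::setNames(x@scores, x@sampleIds))

#' @rdname ActivityScores-class
#' @export
setMethod("sampleIds", "ActivityScores", function(x, ...) x@sampleIds)

#' @rdname ActivityScores-class
#' @export
setMethod("genesetName", "ActivityScores", function(x, ...) x@genesetName)

#' @rdname NormalizedExpression-class
#' @export
setMethod("exprValues", "NormalizedExpression", function(x, ...) x@values)

sizeFactors <- BiocGenerics::sizeFactors

#' @rdname NormalizedExpression-class
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "NormalizedExpression",
          function(object)
  stats::setNames(object@sizeFactors, colnames(object@values)))

#' @rdname SeEventSet-class
#' @export
setMethod("show", "SeEventSet", function(object) {
  cat(sprintf("SeEventSet: %d skipped-exon events x %d samples\n",
              nrow(object), ncol(object)))
  g <- metadata(object)$genome
  if (length(g) && !is.na(g)) cat("genome:", g, "\n")
  callNextMethod()
})

#' @rdname ActivityScores-class
#' @export
setMethod("show", "ActivityScores", function(object) {
  cat(sprintf("ActivityScores '%s' (%s): %d samples, %d gene-set genes used\n",
              object@genesetName, object@method,
              length(object@scores), object@nGenesUsed))
  print(utils::head(scores(object)))
  if (length(object@scores) > 6L) cat("...\n")
})

#' @rdname NormalizedExpression-class
#' @export
setMethod("show", "NormalizedExpression", function(object) {
  cat(sprintf("NormalizedExpression: %d genes x %d samples (log2 scale)\n",
              nrow(object@values), ncol(object@values)))
})

#' @rdname OverlapResult-class
#' @export
setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: |A|=%d |B|=%d overlap=%d universe=%d\n",
              object@sizeA, object@sizeB, object@overlap, object@universe))
  cat(sprintf("  P(X >= k) = %.4g (log = %.4g), Jaccard = %.4g\n",
              object@pHyper, object@logPHyper, object@jaccard))
})
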