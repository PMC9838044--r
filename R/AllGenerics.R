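#' Accessors for HDZipKit classes
#'
#' `designType()` returns the declared sample design of a
#' [TpmExperiment-class]; `tpm()` its assay matrix. `ka()`, `ks()` and
#' `omega()` extract the corrected distances and their ratio from a
#' [KaKsResult-class]. `edges()`, `networkNodes()`, `clusterAssignments()`,
#' `connectivity()` and `thresholdP()` read a [CoexpressionNetwork-class].
#'
#' @param x an HDZipKit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designType", function(x) standardGeneric("designType"))
#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))
#' @rdname accessors
#' @export
setGeneric("ka", function(x) standardGeneric("ka"))
#' @rdname accessors
#' @export
setGeneric("ks", function(x) standardGeneric("ks"))
#' @rdname accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))
#' @rdname accessors
#' @export
setGeneric("thresholdP", function(x) standardGeneric("thresholdP"))

#' @rdname accessors
#' @export
setMethod("designType", "TpmExperiment",
          function(x) S4Vectors::metadata(x)$design)
#' @rdname accessors
#' @export
setMethod("tpm", "TpmExperiment",
          function(x) SummarizedExperiment::assay(x, "tpm"))

#' @rdname accessors
#' @export
setMethod("ka", "KaKsResult", function(x) x@Ka)
#' @rdname accessors
#' @export
setMethod("ks", "KaKsResult", function(x) x@Ks)
#' @rdname accessors
#' @export
setMethod("omega", "KaKsResult", function(x) x@omega)

#' @rdname accessors
#' @export
setMethod("edges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "CoexpressionNetwork",
          function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("connectivity", "CoexpressionNetwork", function(x) x@degree)
#' @rdname accessors
#' @export
setMethod("thresholdP", "CoexpressionNetwork", function(x) x@thresholdP)

setMethod("show", "TpmExperiment", function(object) {
  cat(sprintf("TpmExperiment: %d genes x %d samples, design '%s'\n",
              nrow(object), ncol(object), designType(object)))
  methods::callNextMethod()
})

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf("KaKsResult: %s vs %s (%d codons)\n",
              object@pair[1], object@pair[2], object@nCodons))
  cat(sprintf("  Ka = %.4f (N sites %.2f, Nd %.2f)\n",
              object@Ka, object@NSites, object@Nd))
  cat(sprintf("  Ks = %.4f (S sites %.2f, Sd %.2f)\n",
              object@Ks, object@SSites, object@Sd))
  cat(sprintf("  Ka/Ks = %s\n",
              ifelse(is.na(object@omega), "undefined",
                     sprintf("%.3f", object@omega))))
  if (!is.na(object@tMYA))
    cat(sprintf("  divergence time = %.3f MYA\n", object@tMYA))
  if (any(object@saturated))
    cat("  warning: saturated (p >= 3/4), correction undefined\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf(
    "CoexpressionNetwork at p <= %g: %d nodes, %d edges, %d clusters\n",
    object@thresholdP, length(object@nodes), nrow(object@edges),
    length(unique(object@clusters))))
})
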