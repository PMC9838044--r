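#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.DESIGNS <- c("ages4", "tissues14", "cultivars42")
.DESIGN_SIZES <- c(ages4 = 4L, tissues14 = 14L, cultivars42 = 42L)

#' TpmExperiment: a TPM expression matrix with a declared sample design
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single non-negative `tpm` assay (genes x samples) plus the sample design
#' the study distinguishes: four root ages (`ages4`), fourteen tissues of a
#' four-year-old plant (`tissues14`), or four-year-old roots of 42 cultivars
#' (`cultivars42`). For `ages4` the column data must carry a strictly
#' increasing numeric `age`.
#'
#' @slot .  inherits all SummarizedExperiment slots; the design is stored in
#'   `metadata(x)$design`.
#' @export
setClass("TpmExperiment", contains = "SummarizedExperiment")

setValidity("TpmExperiment", function(object) {
  msg <- character()
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'tpm' is required")
  else {
    v <- SummarizedExperiment::assay(object, "tpm")
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "TPM values must be finite and non-negative")
  }
  d <- S4Vectors::metadata(object)$design
  if (is.null(d) || !d %in% .DESIGNS)
    msg <- c(msg, sprintf("metadata design must be one of %s",
                          paste(.DESIGNS, collapse = ", ")))
  else {
    if (ncol(object) != .DESIGN_SIZES[[d]])
      msg <- c(msg, sprintf("design '%s' requires %d samples, got %d",
                            d, .DESIGN_SIZES[[d]], ncol(object)))
    if (d == "ages4") {
      age <- SummarizedExperiment::colData(object)$age
      if (is.null(age) || !is.numeric(age) || any(diff(age) <= 0))
        msg <- c(msg, "design 'ages4' requires strictly increasing colData$age")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TpmExperiment
#'
#' @param tpm numeric matrix of TPM values, genes in rows, samples in columns;
#'   row and column names are used as gene and sample ids.
#' @param design one of `"ages4"`, `"tissues14"`, `"cultivars42"`.
#' @param sampleInfo optional data.frame of per-sample metadata; for
#'   `design = "ages4"` it must contain a strictly increasing numeric `age`
#'   column (defaults to the study's 5, 12, 18, 25 years).
#' @return a [TpmExperiment-class] object.
#' @examples
#' m <- matrix(rexp(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("age", 1:4)))
#' te <- TpmExperiment(m, "ages4")
#' designType(te)
#' @export
TpmExperiment <- function(tpm, design = c("ages4", "tissues14", "cultivars42"),
                          sampleInfo = NULL) {
  design <- match.arg(design)
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)))
    rownames(tpm) <- sprintf("gene_%04d", seq_len(nrow(tpm)))
  if (is.null(colnames(tpm)))
    colnames(tpm) <- sprintf("sample_%02d", seq_len(ncol(tpm)))
  if (is.null(sampleInfo)) {
    sampleInfo <- S4Vectors::DataFrame(row.names = colnames(tpm))
    if (design == "ages4" && ncol(tpm) == 4L)
      sampleInfo$age <- c(5, 12, 18, 25)
  } else {
    sampleInfo <- S4Vectors::DataFrame(sampleInfo, row.names = colnames(tpm))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm), colData = sampleInfo,
    metadata = list(design = design))
  methods::new("TpmExperiment", se)
}

#' Nei-Gojobori Ka/Ks estimate for one codon-aligned sequence pair
#'
#' Holds the site counts, observed difference counts, proportions corrected
#' by the Jukes-Cantor formula, the omega ratio and (optionally) the
#' molecular-clock divergence date for a pair of coding sequences.
#'
#' @slot pair character(2), sequence names.
#' @slot Ka,Ks numeric(1), corrected nonsynonymous / synonymous distances.
#' @slot omega numeric(1), Ka/Ks (NA when Ks = 0 or undefined).
#' @slot NSites,SSites numeric(1), mean nonsynonymous / synonymous site counts.
#' @slot Nd,Sd numeric(1), pathway-averaged observed difference counts.
#' @slot nCodons integer(1), codons compared after pairwise gap/ambiguity drop.
#' @slot tMYA numeric(1), divergence time in million years (NA if not dated).
#' @slot saturated logical(2), TRUE where pN (resp. pS) >= 3/4 so the
#'   Jukes-Cantor correction is undefined.
#' @export
setClass("KaKsResult",
  representation(pair = "character", Ka = "numeric", Ks = "numeric",
                 omega = "numeric", NSites = "numeric", SSites = "numeric",
                 Nd = "numeric", Sd = "numeric", nCodons = "integer",
                 tMYA = "numeric", saturated = "logical"))

setValidity("KaKsResult", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must name two sequences")
  tot <- object@NSites + object@SSites
  if (is.finite(tot) && abs(tot - 3 * object@nCodons) > 1e-6)
    msg <- c(msg, "NSites + SSites must equal 3 x codon count")
  if (isTRUE(object@Ka < 0) || isTRUE(object@Ks < 0))
    msg <- c(msg, "Ka and Ks must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Spearman co-expression network at one significance threshold
#'
#' Edges are gene pairs whose Spearman correlation is significant at
#' `thresholdP` (either sign of rho); nodes are genes incident to at least
#' one retained edge; clusters are the connected components, labelled
#' deterministically by their lexicographically smallest member.
#'
#' @slot thresholdP numeric(1), the p-value cutoff used.
#' @slot edges data.frame with columns geneA, geneB, rho, p (geneA < geneB).
#' @slot nodes character, genes incident to >= 1 edge.
#' @slot clusters named integer, component index per node.
#' @slot degree named integer, connectivity per node.
#' @export
setClass("CoexpressionNetwork",
  representation(thresholdP = "numeric", edges = "data.frame",
                 nodes = "character", clusters = "integer",
                 degree = "integer"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("geneA", "geneB", "rho", "p")
  if (!all(need %in% names(e)))
    msg <- c(msg, "edges must have columns geneA, geneB, rho, p")
  else if (nrow(e)) {
    if (any(e$geneA >= e$geneB))
      msg <- c(msg, "edges must satisfy geneA < geneB (no self-edges)")
    if (sum(object@degree) != 2L * nrow(e))
      msg <- c(msg, "degree sum must equal 2 x edge count")
  }
  if (!identical(sort(names(object@clusters)), sort(object@nodes)) &&
      length(object@nodes))
    msg <- c(msg, "clusters must cover exactly the nodes")
  if (length(msg)) msg else TRUE
})
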