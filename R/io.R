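#' @importFrom utils read.delim write.table head
#' @importFrom jsonlite write_json
NULL

#' Read a domain-hit table
#'
#' TSV with header columns `transcript_id`, `domain`, `start`, `end`,
#' `evalue` (amino-acid coordinates, 1-based inclusive).
#'
#' @param path file path.
#' @return data.frame ready for [identifyFamily()].
#' @export
readDomainHits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "domain", "start", "end", "evalue")
  if (!all(need %in% names(d)))
    stop("domain hits need columns: ", paste(need, collapse = ", "))
  d
}

#' Read a BLAST outfmt-6-like alignment table with a genotype column
#'
#' Expects the 12 standard tabular columns (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) plus a
#' final `genotype` column; no header. The chromosome is taken from sseqid
#' and genome coordinates from sstart/send (normalized so start <= end).
#'
#' @param path file path.
#' @return data.frame ready for [assignLoci()].
#' @export
readGenomeAlignments <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "genotype")
  d <- utils::read.delim(path, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  data.frame(transcript_id = d$qseqid, genotype = d$genotype,
             chromosome = d$sseqid,
             start = pmin(d$sstart, d$send),
             end = pmax(d$sstart, d$send),
             aligned_length = d$length, identity = d$pident,
             evalue = d$evalue, stringsAsFactors = FALSE)
}

#' Read a GO annotation table
#'
#' TSV with header columns `transcript_id`, `category` (BP/MF/CC) and
#' optionally `level2_term`.
#'
#' @param path file path.
#' @return data.frame ready for [summarizeGo()].
#' @export
readGoAnnotations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "category") %in% names(d)))
    stop("GO annotations need columns transcript_id, category")
  d
}

#' Read / write a TPM matrix
#'
#' TSV with gene ids in the first column and a header row of sample ids.
#'
#' @param path file path.
#' @param design sample design declared for the matrix.
#' @return [TpmExperiment-class].
#' @export
readTpmMatrix <- function(path, design) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  TpmExperiment(as.matrix(d), design = design)
}

#' @rdname readTpmMatrix
#' @param x a [TpmExperiment-class] or TPM matrix to write.
#' @export
writeTpmMatrix <- function(x, path) {
  v <- .asTpmMatrix(x)
  d <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with header columns `group`, `replicate`, `gene_id`, `ct_target`,
#' `ct_reference`.
#'
#' @param path file path.
#' @return data.frame ready for [relativeExpression()].
#' @export
readCtTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "replicate", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% names(d)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Write a generic TSV
#'
#' @param d data.frame.
#' @param path file path.
#' @export
writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary of a family characterization
#'
#' @param summary a named list (e.g. subfamily counts, locus counts,
#'   comparison results); written with `auto_unbox`.
#' @param path file path.
#' @export
writeJsonSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
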