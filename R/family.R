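#' @importFrom stats setNames
NULL

.DOMAINS <- c("HD", "HALZ", "START", "MEKHLA", "CPSCE", "HDZIP_NTERM")
.GENOTYPES <- c("Damaya", "ChP", "IR826")
.METHODS <- c("domain_tblastn", "known_gene_blast", "hmm_search")

#' Classify an HD-Zip subfamily from a transcript's domain content
#'
#' HD-Zip membership requires the homeodomain (HD) together with either the
#' HALZ leucine zipper or the START domain. The four subfamilies are told
#' apart by their extra diagnostic motifs: CPSCE marks subfamily II among
#' the HD+HALZ transcripts, MEKHLA marks subfamily III among the HD+START
#' transcripts; the plain combinations fall to subfamilies I and IV. The
#' motif rules take precedence over the plain combinations because the
#' definitions are otherwise nested.
#'
#' @param domains character vector of domain labels (subset of
#'   `r paste(.DOMAINS, collapse = ", ")`). Duplicates are ignored.
#' @return a character scalar `"I"`, `"II"`, `"III"`, `"IV"`, or `NA` with a
#'   `reason` attribute when the transcript is rejected.
#' @examples
#' classifySubfamily(c("HD", "HALZ"))           # "I"
#' classifySubfamily(c("HD", "START", "MEKHLA")) # "III"
#' classifySubfamily("HALZ")                    # rejected
#' @export
classifySubfamily <- function(domains) {
  domains <- unique(as.character(domains))
  bad <- setdiff(domains, .DOMAINS)
  if (length(bad))
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  reject <- function(reason) structure(NA_character_, reason = reason)
  if (!"HD" %in% domains) return(reject("no HD"))
  hasHALZ <- "HALZ" %in% domains
  hasSTART <- "START" %in% domains
  if (hasHALZ) {
    if ("CPSCE" %in% domains) return("II")
    return("I")
  }
  if (hasSTART) {
    if ("MEKHLA" %in% domains) return("III")
    return("IV")
  }
  reject("HD without HALZ or START")
}

#' Identify family members from a domain-hit table
#'
#' Collapses per-transcript domain evidence, applies the family rule
#' (HD together with HALZ or START) and classifies subfamilies. Rejected
#' candidates are kept with the failing rule, mirroring the "deleted"
#' candidates of a manual screen.
#'
#' @param hits data.frame with columns `transcript_id`, `domain`, `start`,
#'   `end`, `evalue` (as read by [readDomainHits()]). Coordinates are
#'   1-based inclusive amino-acid positions.
#' @return a list with `members` (data.frame: transcript_id, subfamily,
#'   domains) and `rejected` (data.frame: transcript_id, domains, reason).
#' @export
identifyFamily <- function(hits) {
  stopifnot(all(c("transcript_id", "domain") %in% names(hits)))
  if (!is.null(hits$start) && any(hits$start > hits$end))
    stop("domain hit with start > end")
  if (!is.null(hits$evalue) && any(hits$evalue < 0))
    stop("negative E-value in domain hits")
  dom <- split(as.character(hits$domain), hits$transcript_id)
  cls <- lapply(dom, classifySubfamily)
  ok <- !vapply(cls, is.na, logical(1))
  members <- data.frame(
    transcript_id = names(dom)[ok],
    subfamily = unlist(cls[ok], use.names = FALSE),
    domains = vapply(dom[ok], function(d)
      paste(sort(unique(d)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rejected <- data.frame(
    transcript_id = names(dom)[!ok],
    domains = vapply(dom[!ok], function(d)
      paste(sort(unique(d)), collapse = ";"), character(1)),
    reason = vapply(cls[!ok], function(x)
      attr(x, "reason"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  members <- members[order(members$transcript_id), , drop = FALSE]
  rownames(members) <- NULL
  list(members = members, rejected = rejected)
}

#' Merge multi-method candidate sets with provenance
#'
#' The family screen combines candidates found by several search methods
#' (domain tblastn, known-gene blast, HMM search); the family is the union
#' after duplicate removal, and the provenance matrix records which methods
#' found each transcript so method-exclusive identifications can be counted.
#'
#' @param sets named list of character vectors, one per search method.
#' @return list with `ids` (sorted union), `provenance` (logical matrix,
#'   ids x methods), and `exclusives` (named list of ids found by exactly
#'   one method, per method).
#' @examples
#' u <- mergeCandidateSets(list(m1 = c("A", "B"), m2 = c("B", "C")))
#' u$ids
#' u$exclusives
#' @export
mergeCandidateSets <- function(sets) {
  if (!length(sets)) stop("at least one candidate set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("method", seq_along(sets))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  ids <- sort(unique(unlist(sets, use.names = FALSE)))
  prov <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  prov <- matrix(prov, nrow = length(ids),
                 dimnames = list(ids, names(sets)))
  one <- rowSums(prov) == 1L
  exclusives <- lapply(names(sets), function(m)
    ids[one & prov[, m]])
  names(exclusives) <- names(sets)
  list(ids = ids, provenance = prov, exclusives = exclusives)
}

.bestAlignment <- function(a) {
  # best = lowest E-value, ties -> highest identity, then leftmost start
  o <- order(a$evalue, -a$identity, a$start)
  a[o[1], , drop = FALSE]
}

#' Assign transcripts to genome loci from alignment tables
#'
#' Filters transcript-to-genome alignments by aligned length, percent
#' identity and E-value (the study's criteria: cover >= 180 bp, identity
#' >= 99 percent, E-value <= 1e-6), keeps each transcript's best surviving
#' alignment (lowest E-value, then highest identity, then leftmost start)
#' and merges best alignments that overlap by at least 1 bp on the same
#' chromosome, transitively, into loci.
#'
#' @param alignments data.frame with columns `transcript_id`, `genotype`,
#'   `chromosome`, `start`, `end`, `aligned_length`, `identity`, `evalue`
#'   (1-based inclusive bp coordinates; see [readGenomeAlignments()]).
#' @param minLen minimum aligned length in bp (default 180).
#' @param minIdentity minimum percent identity (default 99).
#' @param maxEvalue maximum E-value (default 1e-6).
#' @param chromosomes valid chromosome labels (default `"chr1"`..`"chr24"`,
#'   bare `1`..`24` also accepted).
#' @return a data.frame of loci with columns `locus_id`, `chromosome`,
#'   `start`, `end`, `n_transcripts`, plus a `members` list-column mapping
#'   genotype to member transcript ids, and an `unplaced` attribute listing
#'   transcripts whose alignments all failed the filters.
#' @export
assignLoci <- function(alignments, minLen = 180, minIdentity = 99,
                       maxEvalue = 1e-6,
                       chromosomes = paste0("chr", 1:24)) {
  need <- c("transcript_id", "genotype", "chromosome", "start", "end",
            "aligned_length", "identity", "evalue")
  stopifnot(all(need %in% names(alignments)))
  a <- alignments
  a$chromosome <- ifelse(grepl("^[0-9]+$", a$chromosome),
                         paste0("chr", a$chromosome), a$chromosome)
  bad <- setdiff(unique(a$chromosome), chromosomes)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  if (any(a$start > a$end)) stop("alignment with start > end")
  if (any(a$identity < 0 | a$identity > 100))
    stop("identity must be a percentage in [0, 100]")
  keep <- a$aligned_length >= minLen & a$identity >= minIdentity &
    a$evalue <= maxEvalue
  a <- a[keep, , drop = FALSE]
  allIds <- unique(alignments$transcript_id)
  unplaced <- setdiff(allIds, a$transcript_id)
  if (!nrow(a)) {
    out <- data.frame(locus_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      n_transcripts = integer())
    out$members <- list()
    attr(out, "unplaced") <- unplaced
    return(out)
  }
  best <- do.call(rbind, lapply(
    split(a, paste(a$genotype, a$transcript_id, sep = "\r")),
    .bestAlignment))
  gr <- GenomicRanges::GRanges(
    seqnames = best$chromosome,
    ranges = IRanges::IRanges(best$start, best$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  best$locus <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  md <- data.frame(chromosome = as.character(GenomicRanges::seqnames(merged)),
                   start = GenomicRanges::start(merged),
                   end = GenomicRanges::end(merged))
  ord <- order(factor(md$chromosome, levels = chromosomes), md$start)
  md <- md[ord, , drop = FALSE]
  relabel <- setNames(seq_along(ord), ord)
  best$locus <- relabel[as.character(best$locus)]
  md$locus_id <- sprintf("%s_L%03d", md$chromosome,
                         stats::ave(seq_len(nrow(md)), md$chromosome,
                                    FUN = seq_along))
  md$members <- lapply(seq_len(nrow(md)), function(i) {
    b <- best[best$locus == i, , drop = FALSE]
    lapply(split(b$transcript_id, b$genotype), sort)
  })
  md$n_transcripts <- vapply(md$members, function(m)
    length(unlist(m)), integer(1))
  out <- md[, c("locus_id", "chromosome", "start", "end",
                "n_transcripts", "members")]
  rownames(out) <- NULL
  attr(out, "unplaced") <- unplaced
  out
}

#' Detect genotype-specific loci
#'
#' A locus is specific to the focal genotype when it has members from that
#' genotype and from no other, e.g. the cultivar-specific genes a joint
#' multi-genotype locus map reveals.
#'
#' @param loci locus table from [assignLoci()].
#' @param focal genotype label to test (must occur somewhere in the data).
#' @return the subset of `loci` specific to `focal`.
#' @export
findGenotypeSpecific <- function(loci, focal) {
  present <- unique(unlist(lapply(loci$members, names)))
  if (!focal %in% present)
    stop("focal genotype '", focal, "' absent from the locus data")
  keep <- vapply(loci$members, function(m)
    identical(names(m), focal), logical(1))
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.VENN_CELLS <- c("BP", "MF", "CC", "BP&MF", "BP&CC", "MF&CC", "BP&MF&CC")

.vennCell <- function(categories) {
  paste(intersect(c("BP", "MF", "CC"), categories), collapse = "&")
}

#' Summarize GO categorization per subfamily as a Venn partition
#'
#' Partitions annotated family members into the seven disjoint cells of the
#' Biological Process / Molecular Function / Cellular Component Venn
#' diagram, overall and per subfamily. Cells are disjoint and sum to the
#' number of annotated members.
#'
#' @param annotations data.frame with columns `transcript_id`, `category`
#'   (values among BP, MF, CC; one row per transcript-category pair).
#' @param members member table from [identifyFamily()] (`$members`).
#' @return list with `venn` (named integer over the 7 cells), `bySubfamily`
#'   (cells x subfamily matrix), `nAnnotated`, and `skipped` (annotated ids
#'   that are not family members, dropped with a warning).
#' @export
summarizeGo <- function(annotations, members) {
  stopifnot(all(c("transcript_id", "category") %in% names(annotations)))
  bad <- setdiff(unique(annotations$category), c("BP", "MF", "CC"))
  if (length(bad))
    stop("unknown GO category: ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(annotations$transcript_id),
                     members$transcript_id)
  if (length(unknown)) {
    warning(length(unknown),
            " annotated transcript(s) are not family members; skipped")
    annotations <- annotations[
      !annotations$transcript_id %in% unknown, , drop = FALSE]
  }
  cats <- lapply(split(annotations$category, annotations$transcript_id),
                 unique)
  cells <- vapply(cats, .vennCell, character(1))
  venn <- table(factor(cells, levels = .VENN_CELLS))
  sf <- setNames(members$subfamily, members$transcript_id)
  bySub <- table(factor(cells, levels = .VENN_CELLS),
                 factor(sf[names(cells)], levels = c("I", "II", "III", "IV")))
  list(venn = setNames(as.integer(venn), .VENN_CELLS),
       bySubfamily = unclass(bySub),
       nAnnotated = length(cells),
       skipped = unknown)
}
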