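#' @importFrom Biostrings GENETIC_CODE DNAString DNAStringSet pairwiseAlignment
NULL

.BASES <- c("A", "C", "G", "T")

# codon -> amino acid under the standard genetic code ("*" = stop)
.codonAA <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.allCodons <- function() {
  g <- expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Per-codon synonymous site count: for each of the 3 positions, the fraction
# of the 3 single-nucleotide changes that preserve the amino acid. Changes
# producing a stop codon count as nonsynonymous (they change the protein).
.codonSynSites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- .allCodons()
    aa <- .codonAA(codons)
    s <- setNames(numeric(length(codons)), codons)
    for (i in seq_along(codons)) {
      if (aa[i] == "*") { s[i] <- NA_real_; next }
      cs <- strsplit(codons[i], "")[[1]]
      syn <- 0
      for (pos in 1:3) for (b in setdiff(.BASES, cs[pos])) {
        mut <- cs; mut[pos] <- b
        if (.codonAA(paste(mut, collapse = "")) == aa[i]) syn <- syn + 1
      }
      s[i] <- syn / 3
    }
    cache <<- s
    cache
  }
})

# Pathway-averaged (Sd, Nd) contribution of one codon pair. Codons differing
# at k positions are connected by k! single-step pathways; each step is
# synonymous iff it preserves the amino acid. Pathways passing through a stop
# codon are excluded from the average; if every pathway hits a stop, all are
# kept with stop-crossing steps counted as nonsynonymous.
.codonPairDiffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  perms <- .permutations(length(pos))
  paths <- matrix(0, nrow = nrow(perms), ncol = 2)
  viable <- logical(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    cur <- s1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in pos[perms[i, ]]) {
      aaFrom <- .codonAA(paste(cur, collapse = ""))
      cur[p] <- s2[p]
      aaTo <- .codonAA(paste(cur, collapse = ""))
      if (aaTo == "*" && paste(cur, collapse = "") != c2) ok <- FALSE
      if (aaTo == aaFrom && aaTo != "*") sd <- sd + 1 else nd <- nd + 1
    }
    paths[i, ] <- c(sd, nd)
    viable[i] <- ok
  }
  if (any(viable)) paths <- paths[viable, , drop = FALSE]
  c(Sd = mean(paths[, 1]), Nd = mean(paths[, 2]))
}

# all permutations of 1..n (n <= 3 here), deterministic order
.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

.splitCodons <- function(seq) {
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)))
  if (nchar(seq) %% 3 != 0)
    stop("sequence length is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (saturated) for `p >= 3/4`.
#'
#' @param p proportion of observed differences per site, in `[0, 1]`.
#' @return corrected distance; `NA` where saturated.
#' @export
jukesCantor <- function(p) {
  out <- ifelse(is.nan(p) | p >= 0.75, NA_real_,
                -0.75 * log(1 - 4 * pmin(p, 0.74) / 3) + 0)
  as.numeric(out)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair
#'
#' Counts synonymous and nonsynonymous sites per codon from single-nucleotide
#' mutation fates under the standard genetic code (averaged between the two
#' sequences), partitions observed differences by equal-weight pathway
#' averaging for codons differing at more than one position (pathways
#' through stop codons excluded), and corrects the proportions
#' `pN = Nd/N`, `pS = Sd/S` with the Jukes-Cantor formula. The result is
#' symmetric in its arguments.
#'
#' Codons containing gaps (`-`) or ambiguity characters in either sequence
#' are dropped pairwise; the number dropped is reported in a message.
#'
#' @param seqA,seqB coding sequences of equal length (character or
#'   [Biostrings::DNAString]); length a multiple of 3, no internal stops.
#' @param pair optional character(2) of sequence names.
#' @param lambda if non-NULL, a synonymous clock rate passed to
#'   [divergenceTime()] to date the pair.
#' @return a [KaKsResult-class].
#' @examples
#' r <- computeKaKs("TTTGATGCC", "TTCGATGCC")
#' ks(r)  # 1.2071 = -(3/4) log(0.2)
#' @export
computeKaKs <- function(seqA, seqB, pair = c("seqA", "seqB"), lambda = NULL) {
  ca <- .splitCodons(seqA)
  cb <- .splitCodons(seqB)
  if (length(ca) != length(cb))
    stop("sequences must be codon-aligned to equal length")
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  nDropped <- sum(!clean)
  if (nDropped)
    message(nDropped, " codon(s) with gaps/ambiguity dropped pairwise")
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no clean codons to compare")
  syn <- .codonSynSites()
  if (any(is.na(syn[ca])) || any(is.na(syn[cb])))
    stop("internal stop codon in input")
  # sites averaged between the two sequences
  S <- (sum(syn[ca]) + sum(syn[cb])) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) .codonPairDiffs(x, y), ca, cb)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  pS <- Sd / S; pN <- Nd / N
  KsV <- jukesCantor(pS); KaV <- jukesCantor(pN)
  omegaV <- if (!is.na(KaV) && !is.na(KsV) && KsV > 0) KaV / KsV
            else NA_real_
  tMYA <- if (!is.null(lambda) && !is.na(KsV))
    divergenceTime(KsV, lambda) else NA_real_
  methods::new("KaKsResult", pair = as.character(pair),
               Ka = KaV, Ks = KsV, omega = omegaV,
               NSites = N, SSites = S, Nd = Nd, Sd = Sd,
               nCodons = length(ca), tMYA = tMYA,
               saturated = c(pN >= 0.75, pS >= 0.75))
}

#' Ka/Ks ratio
#'
#' @param Ka,Ks corrected nonsynonymous and synonymous distances.
#' @return `Ka/Ks`; `NA` when `Ks = 0` (undefined). A ratio below 1
#'   indicates purifying selection.
#' @examples
#' round(kaksRatio(0.205, 0.364), 3)  # 0.563
#' @export
kaksRatio <- function(Ka, Ks) {
  stopifnot(Ka >= 0, Ks >= 0)
  ifelse(Ks > 0, Ka / Ks, NA_real_)
}

#' Molecular-clock divergence date from Ks
#'
#' `T = Ks / (2 * lambda)` converted to million years, under a constant
#' synonymous substitution rate `lambda` per site per year (default
#' 6.5e-9, the dicot rate used for the family's dating).
#'
#' @param Ks synonymous distance (substitutions per synonymous site).
#' @param lambda clock rate, substitutions per synonymous site per year.
#' @return divergence time in million years (MYA).
#' @examples
#' divergenceTime(0.364)  # 28.0 MYA
#' @export
divergenceTime <- function(Ks, lambda = 6.5e-9) {
  if (any(Ks < 0)) stop("Ks must be non-negative")
  if (any(lambda <= 0)) stop("lambda must be positive")
  Ks / (2 * lambda) * 1e-6
}

#' Codon-aware global alignment of two coding sequences
#'
#' Aligns the translated proteins globally (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment]) and projects the gaps back to codons,
#' then removes gap codon columns, yielding the gap-free codon alignment
#' Ka/Ks counting expects.
#'
#' @param seqA,seqB unaligned CDS (character or DNAString); lengths must be
#'   multiples of 3 with no internal stop codons.
#' @return list of two equal-length gap-free sequences `seqA`, `seqB`.
#' @export
alignCodons <- function(seqA, seqB) {
  ca <- .splitCodons(seqA); cb <- .splitCodons(seqB)
  aaA <- paste(.codonAA(ca), collapse = "")
  aaB <- paste(.codonAA(cb), collapse = "")
  if (grepl("\\*", substr(aaA, 1, nchar(aaA) - 1)) ||
      grepl("\\*", substr(aaB, 1, nchar(aaB) - 1)))
    stop("internal stop codon in input")
  aaA <- sub("\\*$", "", aaA); aaB <- sub("\\*$", "", aaB)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aaA), Biostrings::AAString(aaB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- pa != "-" & ps != "-"
  ia <- cumsum(pa != "-")
  ib <- cumsum(ps != "-")
  list(seqA = paste(ca[ia[keep]], collapse = ""),
       seqB = paste(cb[ib[keep]], collapse = ""))
}

#' Rank candidate duplicate pairs by coding-sequence identity
#'
#' All-vs-all global pairwise alignment of the CDS set; pairs are ranked by
#' percent identity (matching columns over aligned columns), the screen the
#' study used to pick its most recently duplicated gene pairs. Ties are
#' broken by pair name for a deterministic order; self-pairs are excluded,
#' and sequences shorter than one codon are skipped with a warning.
#'
#' @param cds a named [Biostrings::DNAStringSet] (or named character vector)
#'   of coding sequences; at least two.
#' @param top return only the best `top` pairs (default all).
#' @return data.frame with columns `seqA`, `seqB`, `identity` (percent),
#'   sorted by decreasing identity.
#' @export
selectDuplicatePairs <- function(cds, top = Inf) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (is.null(names(cds)))
    names(cds) <- sprintf("seq%03d", seq_along(cds))
  short <- Biostrings::width(cds) < 3
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than one codon skipped")
    cds <- cds[!short]
  }
  if (length(cds) < 2) stop("need at least two usable sequences")
  nm <- names(cds)
  combs <- utils::combn(seq_along(cds), 2)
  idty <- apply(combs, 2, function(ij) {
    al <- Biostrings::pairwiseAlignment(cds[[ij[1]]], cds[[ij[2]]],
                                        type = "global")
    Biostrings::pid(al, type = "PID1")
  })
  out <- data.frame(seqA = nm[combs[1, ]], seqB = nm[combs[2, ]],
                    identity = idty, stringsAsFactors = FALSE)
  swap <- out$seqA > out$seqB
  tmp <- out$seqA[swap]; out$seqA[swap] <- out$seqB[swap]
  out$seqB[swap] <- tmp
  out <- out[order(-out$identity, out$seqA, out$seqB), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = top)
}

#' Full Ka/Ks + dating table for named pairs
#'
#' Convenience wrapper running [alignCodons()] (when needed),
#' [computeKaKs()] and [divergenceTime()] over a set of pairs, producing a
#' table with columns pair, Ka, Ks, Ka/Ks and date in MYA.
#'
#' @param cds named DNAStringSet (or character vector) of CDS.
#' @param pairs two-column matrix/data.frame of sequence names.
#' @param lambda synonymous clock rate (default 6.5e-9).
#' @param aligned set TRUE if sequences are already codon-aligned
#'   pairwise-equal-length (gaps removed); otherwise pairs are aligned.
#' @return data.frame: seqA, seqB, Ka, Ks, omega, T_mya.
#' @export
kaksTable <- function(cds, pairs, lambda = 6.5e-9, aligned = FALSE) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(cds[[pairs[i, 1]]])
    b <- as.character(cds[[pairs[i, 2]]])
    if (!aligned) {
      al <- alignCodons(a, b); a <- al$seqA; b <- al$seqB
    }
    r <- computeKaKs(a, b, pair = pairs[i, ], lambda = lambda)
    data.frame(seqA = pairs[i, 1], seqB = pairs[i, 2],
               Ka = r@Ka, Ks = r@Ks, omega = r@omega, T_mya = r@tMYA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
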