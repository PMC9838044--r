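# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive everything from first principles (the standard
# genetic code table and naive enumeration) rather than calling package
# internals.

GC_TABLE <- Biostrings::GENETIC_CODE

orcTranslate <- function(codon) unname(GC_TABLE[codon])

orcSenseCodons <- function() {
  g <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                   b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  all <- paste0(g$b1, g$b2, g$b3)
  all[orcTranslate(all) != "*"]
}

# synonymous site count of one codon: for each position, the number of the
# three alternative bases preserving the amino acid, divided by 3 (changes
# to stop codons treated as nonsynonymous)
orcSynSites <- function(codon) {
  aa <- orcTranslate(codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (orcTranslate(mut) == aa) s <- s + 1
    }
  }
  s / 3
}

# depth-first enumeration of every substitution ordering between two codons;
# returns a matrix with one row (sd, nd, hitStop) per complete pathway
orcPathways <- function(from, to) {
  out <- NULL
  walk <- function(cur, sd, nd, hitStop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) {
      out <<- rbind(out, c(sd = sd, nd = nd, hitStop = hitStop))
      return(invisible())
    }
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      syn <- orcTranslate(nxt) == orcTranslate(cur) &&
        orcTranslate(nxt) != "*"
      stopHit <- hitStop || (orcTranslate(nxt) == "*" && nxt != to)
      walk(nxt, sd + syn, nd + !syn, stopHit)
    }
  }
  walk(from, 0, 0, FALSE)
  out
}

# pathway-averaged difference counts, stop-crossing pathways excluded
# (all kept if every pathway crosses a stop)
orcCodonDiffs <- function(from, to) {
  if (from == to) return(c(Sd = 0, Nd = 0))
  paths <- orcPathways(from, to)
  ok <- !paths[, "hitStop"]
  if (any(ok)) paths <- paths[ok, , drop = FALSE]
  c(Sd = mean(paths[, "sd"]), Nd = mean(paths[, "nd"]))
}

# full NG86 oracle on two codon vectors
orcNG86 <- function(codonsA, codonsB) {
  S <- mean(c(sum(vapply(codonsA, orcSynSites, numeric(1))),
              sum(vapply(codonsB, orcSynSites, numeric(1)))))
  N <- 3 * length(codonsA) - S
  d <- mapply(orcCodonDiffs, codonsA, codonsB)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  jc <- function(p) if (is.nan(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ka = jc(Nd / N), Ks = jc(Sd / S))
}

# all permutations of 1..n as a matrix (row per permutation)
orcPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  prev <- orcPerms(n - 1)
  out <- matrix(0L, n * nrow(prev), n)
  r <- 0
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(nrow(prev)), ] <- cbind(k, matrix(rest[prev],
                                                      nrow(prev)))
    r <- r + nrow(prev)
  }
  out
}

# exact two-sided permutation p-value for Spearman rho (distinct values)
orcSpearmanPermP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rhoObs <- stats::cor(rx, ry)
  P <- orcPerms(n)
  # rho = 1 - 6 sum d^2 / (n(n^2-1)) for distinct ranks
  d2 <- rowSums((matrix(ry[P], nrow(P)) -
                   matrix(rx, nrow(P), n, byrow = TRUE))^2)
  rhoAll <- 1 - 6 * d2 / (n * (n^2 - 1))
  mean(abs(rhoAll) >= abs(rhoObs) - 1e-12)
}

# connected components by naive flood fill over an edge list
orcComponents <- function(edgesA, edgesB) {
  nodes <- sort(unique(c(edgesA, edgesB)))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1
    frontier <- start
    while (length(frontier)) {
      comp[frontier] <- cid
      nb <- c(edgesB[edgesA %in% frontier], edgesA[edgesB %in% frontier])
      frontier <- nb[is.na(comp[nb])]
      frontier <- unique(frontier)
    }
  }
  comp
}

# transitive interval merging by repeated pairwise joins (O(n^2))
orcMergeIntervals <- function(start, end) {
  iv <- cbind(start, end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}
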