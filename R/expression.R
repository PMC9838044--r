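#' @importFrom stats cor pt hclust cutree as.dist sd t.test
NULL

.asTpmMatrix <- function(m) {
  if (methods::is(m, "TpmExperiment")) tpm(m) else as.matrix(m)
}

#' Call genes expressed per sample from TPM
#'
#' A gene is called expressed in a sample when its TPM strictly exceeds the
#' threshold (default 0, i.e. any non-zero abundance counts as expressed).
#'
#' @param m a [TpmExperiment-class] or numeric TPM matrix (genes x samples).
#' @param threshold non-negative TPM cutoff; strict `>` is applied.
#' @return logical matrix with the dimensions and dimnames of the input.
#' @export
callExpressed <- function(m, threshold = 0) {
  stopifnot(threshold >= 0)
  v <- .asTpmMatrix(m)
  v > threshold
}

#' Expression-breadth distribution
#'
#' For each gene, the breadth k is the number of samples in which it is
#' called expressed; the distribution reports gene counts and percentages
#' (1 decimal place) over k = 0..n_samples, plus the cumulative
#' "expressed in at least one sample" summary the study reports.
#'
#' @param b logical matrix from [callExpressed()].
#' @return list with `k` (per-gene breadth, named), `counts` (integer over
#'   k = 0..n), `percent` (rounded to 1 d.p.), `pctAtLeastOne`, and
#'   `pctAll` (breadth = n).
#' @export
breadthDistribution <- function(b) {
  stopifnot(is.logical(b), is.matrix(b))
  k <- rowSums(b)
  n <- ncol(b)
  counts <- table(factor(k, levels = 0:n))
  counts <- setNames(as.integer(counts), 0:n)
  percent <- round(100 * counts / nrow(b), 1)
  list(k = k, counts = counts, percent = percent,
       pctAtLeastOne = round(100 * sum(k >= 1) / nrow(b), 1),
       pctAll = round(100 * sum(k == n) / nrow(b), 1))
}

# Calibrated significance of one observed statistic against n_boot random
# replicate statistics: prediction-interval t with df = n_boot - 1. Under
# the null the observation is one more draw from the replicate
# distribution, so (obs - mean) / (sd * sqrt(1 + 1/n)) ~ t_{n-1}.
.predictionP <- function(obs, reps) {
  n <- length(reps)
  s <- stats::sd(reps)
  if (s == 0) return(if (obs == mean(reps)) 1 else 0)
  tstat <- (obs - mean(reps)) / (s * sqrt(1 + 1 / n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Compare a gene set's expression breadth with a random background
#'
#' Draws `nBoot` random gene sets of the target's size from the background
#' pool (without replacement; pool genes overlapping the target are
#' excluded first), records the per-breadth histogram of each draw, and
#' tests whether the target's "expressed in at least one sample" count
#' stands out from the random draws. Significance uses a two-sided
#' prediction-interval t-test of the observed target count against the
#' bootstrap replicate counts (df = nBoot - 1), reported significant at
#' p <= 0.01.
#'
#' @param target character vector of target gene ids.
#' @param pool character vector of background gene ids (must be at least as
#'   large as the target after excluding overlap).
#' @param m [TpmExperiment-class] or TPM matrix covering all genes used.
#' @param nBoot number of bootstrap draws (default 20).
#' @param seed integer seed (required; logged in the output).
#' @param threshold TPM cutoff passed to [callExpressed()].
#' @return list with `targetCounts`, `randomMean`, `randomSd` (per-k),
#'   `randomAtLeastOne` (replicate counts), `targetAtLeastOne`, `pValue`,
#'   `significant`, `nBoot`, `seed`.
#' @export
compareWithRandomBackground <- function(target, pool, m, nBoot = 20, seed,
                                        threshold = 0) {
  if (missing(seed)) stop("a seed is required for reproducible draws")
  v <- .asTpmMatrix(m)
  pool <- setdiff(pool, target)
  if (length(pool) < length(target))
    stop("background pool smaller than the target set")
  stopifnot(all(target %in% rownames(v)), all(pool %in% rownames(v)),
            nBoot >= 1)
  b <- callExpressed(v, threshold)
  n <- ncol(b)
  targetB <- breadthDistribution(b[target, , drop = FALSE])
  set.seed(seed)
  draws <- vapply(seq_len(nBoot), function(i) {
    g <- sample(pool, length(target))
    breadthDistribution(b[g, , drop = FALSE])$counts
  }, numeric(n + 1))
  atLeast <- colSums(draws[-1, , drop = FALSE])
  obs <- sum(targetB$counts[-1])
  p <- .predictionP(obs, atLeast)
  list(targetCounts = targetB$counts,
       randomMean = rowMeans(draws),
       randomSd = apply(draws, 1, stats::sd),
       randomAtLeastOne = atLeast,
       targetAtLeastOne = obs,
       pValue = p, significant = p <= 0.01,
       nBoot = nBoot, seed = seed)
}

#' Core gene set expressed in every sample of every design
#'
#' Intersects the "expressed in all samples" sets across the three sample
#' designs (root ages, tissues, cultivars) — the ubiquitously expressed
#' core the study singles out as essential.
#'
#' @param ... two or more logical matrices from [callExpressed()] (or
#'   [TpmExperiment-class] objects, thresholded at 0), sharing one gene
#'   universe.
#' @return character vector of core gene ids.
#' @export
coreGeneSet <- function(...) {
  mats <- lapply(list(...), function(x)
    if (is.logical(x)) x else callExpressed(x))
  if (length(mats) < 2) stop("need at least two designs")
  ids <- rownames(mats[[1]])
  for (m in mats[-1])
    if (!identical(sort(rownames(m)), sort(ids)))
      stop("gene universes differ between designs")
  core <- ids
  for (m in mats)
    core <- intersect(core, rownames(m)[rowSums(m) == ncol(m)])
  sort(core)
}

#' Monotone age-trend genes
#'
#' Flags genes whose TPM varies regularly with root age: strictly
#' increasing (or strictly decreasing) across the age-ordered samples with
#' a max/min fold span of at least `minFold`.
#'
#' @param m [TpmExperiment-class] with design `ages4` (or a TPM matrix with
#'   age-ordered columns).
#' @param minFold minimum max/min TPM ratio (default 2).
#' @return data.frame with columns `gene_id`, `direction`, `fold_span`.
#' @export
ageTrendGenes <- function(m, minFold = 2) {
  if (methods::is(m, "TpmExperiment") && designType(m) != "ages4")
    stop("age trends require the ages4 design")
  v <- .asTpmMatrix(m)
  dirs <- apply(v, 1, function(x) {
    d <- diff(x)
    if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing"
    else NA_character_
  })
  span <- apply(v, 1, function(x)
    if (min(x) > 0) max(x) / min(x) else Inf)
  keep <- !is.na(dirs) & span >= minFold
  out <- data.frame(gene_id = rownames(v)[keep],
                    direction = unname(dirs[keep]),
                    fold_span = unname(span[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group samples by expression similarity
#'
#' Agglomerative clustering (average linkage) of the sample columns with
#' distance 1 - Spearman rho, cut into `kGroups` groups — the procedure
#' that separates above-ground from under-ground tissues in the study's
#' tissue panel. Constant (zero-variance) samples get rho treated as 0
#' against every other sample, with a warning.
#'
#' @param m [TpmExperiment-class] or TPM matrix.
#' @param kGroups number of groups to cut (default 2).
#' @return named integer vector of group memberships (1..kGroups), plus the
#'   `hclust` tree as attribute `"tree"`.
#' @export
clusterSamples <- function(m, kGroups = 2) {
  v <- .asTpmMatrix(m)
  if (ncol(v) < kGroups) stop("fewer samples than groups requested")
  constant <- apply(v, 2, function(x) stats::sd(x) == 0)
  if (any(constant))
    warning(sum(constant), " constant sample(s); correlation taken as 0")
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  tree <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  grp <- stats::cutree(tree, k = kGroups)
  attr(grp, "tree") <- tree
  grp
}
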