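#' @importFrom igraph graph_from_data_frame components write_graph
NULL

#' Default significance-threshold sweep
#'
#' Decade steps from 5.0E-02 down to 1.0E-08, the endpoints the study
#' sweeps between.
#' @export
defaultThresholds <- function() c(5e-2, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7,
                                  1e-8)

# Spearman rho matrix (tie-corrected, via Pearson on average ranks) and
# two-sided p from the t transform t = rho * sqrt((n-2)/(1-rho^2)), df n-2.
.spearmanMatrix <- function(v) {
  n <- ncol(v)
  r <- t(apply(v, 1, rank))          # average ranks, tie-corrected
  rho <- suppressWarnings(stats::cor(t(r)))
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  list(rho = rho, p = p)
}

#' All-pairs Spearman correlation edges
#'
#' Scores every unordered gene pair by the Spearman coefficient (average
#' ranks, tie-corrected) and a two-sided p-value from the t transform
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom. Genes that
#' are constant across samples (zero variance, e.g. never expressed) are
#' excluded with a warning before scoring.
#'
#' @param m [TpmExperiment-class] or numeric matrix, genes x samples; at
#'   least 4 samples.
#' @return data.frame of edges: `geneA`, `geneB` (geneA < geneB), `rho`,
#'   `p`, `n`.
#' @export
spearmanEdges <- function(m) {
  v <- .asTpmMatrix(m)
  if (ncol(v) < 4) stop("at least 4 samples are required")
  constant <- apply(v, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning(sum(constant), " zero-variance gene(s) excluded")
    v <- v[!constant, , drop = FALSE]
  }
  if (nrow(v) < 2)
    return(data.frame(geneA = character(), geneB = character(),
                      rho = numeric(), p = numeric(), n = integer()))
  sm <- .spearmanMatrix(v)
  idx <- which(upper.tri(sm$rho), arr.ind = TRUE)
  g <- rownames(v)
  out <- data.frame(geneA = g[idx[, 1]], geneB = g[idx[, 2]],
                    rho = sm$rho[idx], p = sm$p[idx], n = ncol(v),
                    stringsAsFactors = FALSE)
  swap <- out$geneA > out$geneB
  tmp <- out$geneA[swap]; out$geneA[swap] <- out$geneB[swap]
  out$geneB[swap] <- tmp
  out <- out[order(out$geneA, out$geneB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a co-expression network at a significance threshold
#'
#' Retains edges with `p <= thresholdP` regardless of the sign of rho,
#' takes the incident genes as nodes, and partitions them into clusters
#' (connected components) labelled by their lexicographically smallest
#' member gene.
#'
#' @param edges edge table from [spearmanEdges()].
#' @param thresholdP p-value cutoff in (0, 1].
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(edges, thresholdP = 0.05) {
  stopifnot(thresholdP > 0, thresholdP <= 1)
  e <- edges[edges$p <= thresholdP, c("geneA", "geneB", "rho", "p"),
             drop = FALSE]
  rownames(e) <- NULL
  if (!nrow(e))
    return(methods::new("CoexpressionNetwork", thresholdP = thresholdP,
                        edges = e, nodes = character(),
                        clusters = integer(), degree = integer()))
  g <- igraph::graph_from_data_frame(e[, c("geneA", "geneB")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic cluster ids: rank components by smallest member gene id
  anchor <- vapply(split(names(comp), comp), min, character(1))
  relabel <- setNames(rank(anchor), names(anchor))
  clusters <- setNames(as.integer(relabel[as.character(comp)]), names(comp))
  deg <- table(c(e$geneA, e$geneB))
  nodes <- sort(names(comp))
  methods::new("CoexpressionNetwork", thresholdP = thresholdP, edges = e,
               nodes = nodes,
               clusters = clusters[nodes],
               degree = setNames(as.integer(deg[nodes]), nodes))
}

#' Network-formation tendency against random gene sets
#'
#' For each significance threshold in the sweep, records the node and edge
#' counts of the target set's network and of `nBoot` random same-size gene
#' sets drawn from the background pool (without replacement; overlap with
#' the target excluded), and tests per threshold whether the target counts
#' stand out from the random replicates. Significance per threshold is a
#' two-sided prediction-interval t-test of the observed target count
#' against the bootstrap replicate counts (df = nBoot - 1), flagged at
#' p <= 0.01.
#'
#' @param target,pool character vectors of gene ids.
#' @param m [TpmExperiment-class] or TPM matrix covering all genes.
#' @param thresholds p-value sweep (default [defaultThresholds()]).
#' @param nBoot number of random draws (default 20).
#' @param seed integer seed (required; logged in the output).
#' @param dropUnexpressed drop genes expressed in zero samples before
#'   correlation (default TRUE, as the study networks only expressed
#'   transcripts).
#' @return list with `thresholds`, `targetNodes`, `targetEdges`,
#'   `randomNodes`, `randomEdges` (nBoot x thresholds matrices),
#'   `pNodes`, `pEdges`, `significantNodes`, `significantEdges`,
#'   `nBoot`, `seed`.
#' @export
tendencyTest <- function(target, pool, m, thresholds = defaultThresholds(),
                         nBoot = 20, seed, dropUnexpressed = TRUE) {
  if (missing(seed)) stop("a seed is required for reproducible draws")
  v <- .asTpmMatrix(m)
  pool <- setdiff(pool, target)
  if (length(pool) < length(target))
    stop("background pool smaller than the target set")
  stopifnot(all(c(target, pool) %in% rownames(v)))
  if (dropUnexpressed) {
    expressed <- rownames(v)[rowSums(v > 0) > 0]
    target <- intersect(target, expressed)
    pool <- intersect(pool, expressed)
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  countsFor <- function(genes) {
    ed <- suppressWarnings(spearmanEdges(v[genes, , drop = FALSE]))
    vapply(thresholds, function(th) {
      keep <- ed$p <= th
      c(nodes = length(unique(c(ed$geneA[keep], ed$geneB[keep]))),
        edges = sum(keep))
    }, numeric(2))
  }
  targetCounts <- countsFor(target)
  set.seed(seed)
  randomNodes <- matrix(0L, nBoot, length(thresholds))
  randomEdges <- matrix(0L, nBoot, length(thresholds))
  for (i in seq_len(nBoot)) {
    g <- sample(pool, length(target))
    cc <- countsFor(g)
    randomNodes[i, ] <- cc["nodes", ]
    randomEdges[i, ] <- cc["edges", ]
  }
  pNodes <- vapply(seq_along(thresholds), function(j)
    .predictionP(targetCounts["nodes", j], randomNodes[, j]), numeric(1))
  pEdges <- vapply(seq_along(thresholds), function(j)
    .predictionP(targetCounts["edges", j], randomEdges[, j]), numeric(1))
  list(thresholds = thresholds,
       targetNodes = targetCounts["nodes", ],
       targetEdges = targetCounts["edges", ],
       randomNodes = randomNodes, randomEdges = randomEdges,
       pNodes = pNodes, pEdges = pEdges,
       significantNodes = pNodes <= 0.01,
       significantEdges = pEdges <= 0.01,
       nBoot = nBoot, seed = seed)
}

#' Call hub genes by connectivity
#'
#' Hubs are nodes whose degree strictly exceeds `minConnectivity` (the
#' study uses > 15 for the 42-cultivar network and > 10 for the 14-tissue
#' network), sorted by decreasing degree then gene id.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param minConnectivity integer degree cutoff (strict `>`).
#' @return data.frame with columns `gene_id`, `degree`, `min_connectivity`.
#' @export
findHubs <- function(net, minConnectivity = 15) {
  deg <- connectivity(net)
  hubs <- deg[deg > minConnectivity]
  ord <- order(-hubs, names(hubs))
  data.frame(gene_id = names(hubs)[ord], degree = unname(hubs[ord]),
             min_connectivity = rep(minConnectivity, length(hubs)),
             stringsAsFactors = FALSE)
}

#' Export a co-expression network as GraphML
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  e <- edges(net)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
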