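#' @importFrom stats rnorm runif
NULL

.SUBFAMILY_DOMAINS <- list(
  I = c("HD", "HALZ"),
  II = c("HD", "HALZ", "CPSCE"),
  III = c("HD", "START", "MEKHLA"),
  IV = c("HD", "START"))

.REJECT_DOMAINS <- list("HD", "HALZ", "START", c("HALZ", "START"),
                        c("START", "MEKHLA"), c("HALZ", "CPSCE"))

#' Generate a domain-hit table with known subfamily truth
#'
#' Each generated transcript carries exactly the diagnostic domain set of
#' its assigned subfamily (plus, at random, the non-diagnostic N-terminal
#' domain); rejected transcripts violate both composite family rules. The
#' default sizes mirror the family the toolkit was built around
#' (73/13/11/20 members plus rejected candidates).
#'
#' @param nPerSubfamily named integer vector over I..IV.
#' @param nRejected number of non-family transcripts.
#' @param seed integer seed.
#' @return list with `hits` (data.frame: transcript_id, domain, start, end,
#'   evalue) and `truth` (data.frame: transcript_id, subfamily, with
#'   `"rejected"` for non-members).
#' @export
simDomainTable <- function(nPerSubfamily = c(I = 73, II = 13, III = 11,
                                             IV = 20),
                           nRejected = 10, seed) {
  stopifnot(!missing(seed), all(nPerSubfamily >= 0), nRejected >= 0)
  set.seed(seed)
  labels <- rep(names(nPerSubfamily), nPerSubfamily)
  ids <- sprintf("tr_%04d", seq_len(length(labels) + nRejected))
  ids <- sample(ids)
  famIds <- ids[seq_along(labels)]
  rejIds <- setdiff(ids, famIds)
  mkRows <- function(id, doms) {
    start <- sort(sample(1:200, length(doms)))
    data.frame(transcript_id = id, domain = doms, start = start,
               end = start + sample(40:90, length(doms), replace = TRUE),
               evalue = 10^-runif(length(doms), 6, 40),
               stringsAsFactors = FALSE)
  }
  rows <- mapply(function(id, sf) {
    doms <- .SUBFAMILY_DOMAINS[[sf]]
    if (runif(1) < 0.3) doms <- c(doms, "HDZIP_NTERM")
    mkRows(id, doms)
  }, famIds, labels, SIMPLIFY = FALSE)
  rejRows <- lapply(rejIds, function(id)
    mkRows(id, .REJECT_DOMAINS[[sample(length(.REJECT_DOMAINS), 1)]]))
  hits <- do.call(rbind, c(rows, rejRows))
  if (is.null(hits))
    hits <- data.frame(transcript_id = character(), domain = character(),
                       start = integer(), end = integer(),
                       evalue = numeric())
  rownames(hits) <- NULL
  truth <- data.frame(
    transcript_id = c(famIds, rejIds),
    subfamily = c(labels, rep("rejected", length(rejIds))),
    stringsAsFactors = FALSE)
  list(hits = hits, truth = truth)
}

#' Generate overlapping multi-method candidate sets
#'
#' Constructs three candidate sets of prescribed sizes whose union has the
#' prescribed size, with exactly `nExclusiveSecond` ids found only by the
#' second method — the overlap structure of the study's three-method
#' family screen (114, 83 and 112 candidates merging to 117, one of them
#' exclusive to the second method).
#'
#' @param sizes integer(3), the three set sizes.
#' @param unionSize size of the union.
#' @param nExclusiveSecond ids exclusive to the second set.
#' @param seed integer seed.
#' @return list with `sets` (named list of id vectors) and `truth`
#'   (`unionIds`, `exclusiveSecond`).
#' @export
simCandidateSets <- function(sizes = c(114, 83, 112), unionSize = 117,
                             nExclusiveSecond = 1, seed) {
  stopifnot(!missing(seed), length(sizes) == 3,
            nExclusiveSecond <= sizes[2])
  nRest <- unionSize - nExclusiveSecond
  if (sizes[1] > nRest || sizes[3] > nRest)
    stop("sets 1/3 cannot exceed the union minus set-2 exclusives")
  set.seed(seed)
  ids <- sample(sprintf("cand_%04d", seq_len(unionSize)))
  excl2 <- ids[seq_len(nExclusiveSecond)]
  rest <- ids[-seq_len(nExclusiveSecond)]
  s1 <- sample(rest, sizes[1])
  missed1 <- setdiff(rest, s1)            # must come from set 3
  if (sizes[3] < length(missed1))
    stop("set 3 too small to cover the union")
  s3 <- c(missed1, sample(s1, sizes[3] - length(missed1)))
  overlap <- intersect(s1, s3)
  if (sizes[2] - nExclusiveSecond > length(overlap))
    stop("set 2 too large to keep its exclusives unique")
  s2 <- c(excl2, sample(overlap, sizes[2] - nExclusiveSecond))
  sets <- list(domain_tblastn = sort(s1), known_gene_blast = sort(s2),
               hmm_search = sort(s3))
  list(sets = sets,
       truth = list(unionIds = sort(ids), exclusiveSecond = sort(excl2)))
}

#' Generate transcript-to-genome alignment tables with planted loci
#'
#' Plants non-overlapping loci on the 24 chromosomes: `nShared` loci
#' carrying alignments from every genotype and `nFocalOnly` loci carrying
#' alignments from the focal genotype alone (the genotype-specific loci a
#' joint map should recover). Alignments of one locus all span the locus
#' midpoint, so they merge transitively; decoy alignments failing the
#' length/identity/E-value filters are added to exercise the screening.
#'
#' @param nShared loci shared by all genotypes (default 60).
#' @param nFocalOnly focal-genotype-specific loci (default 5).
#' @param focal focal genotype (default `"Damaya"`).
#' @param genotypes all genotypes (default Damaya, ChP, IR826).
#' @param nDecoy filter-failing alignments to add (default 6).
#' @param seed integer seed.
#' @return list with `alignments` (data.frame in [assignLoci()] format) and
#'   `truth` (data.frame: locus index, chromosome, start, end, focalOnly).
#' @export
simGenomeAlignments <- function(nShared = 60, nFocalOnly = 5,
                                focal = "Damaya",
                                genotypes = c("Damaya", "ChP", "IR826"),
                                nDecoy = 6, seed) {
  stopifnot(!missing(seed), focal %in% genotypes)
  set.seed(seed)
  nLoci <- nShared + nFocalOnly
  chrom <- paste0("chr", sample(1:24, nLoci, replace = TRUE))
  slot <- unlist(lapply(split(seq_len(nLoci), chrom), seq_along))
  slot <- slot[order(unlist(split(seq_len(nLoci), chrom)))]
  start <- 1e5 * slot + sample(0:5e4, nLoci, replace = TRUE)
  width <- sample(1500:4000, nLoci, replace = TRUE)
  focalOnly <- c(rep(FALSE, nShared), rep(TRUE, nFocalOnly))
  rows <- list(); tid <- 0
  for (i in seq_len(nLoci)) {
    gts <- if (focalOnly[i]) focal else genotypes
    mid <- start[i] + width[i] %/% 2
    for (g in gts) {
      tid <- tid + 1
      # span the midpoint with >= 100 bp on each side so every planted
      # alignment passes the 180 bp length filter and all alignments of a
      # locus overlap transitively
      aStart <- sample(start[i]:(mid - 100), 1)
      aEnd <- sample((mid + 100):(start[i] + width[i]), 1)
      rows[[tid]] <- data.frame(
        transcript_id = sprintf("%s_t%04d", tolower(substr(g, 1, 3)), tid),
        genotype = g, chromosome = chrom[i],
        start = aStart, end = aEnd,
        aligned_length = aEnd - aStart + 1,
        identity = round(runif(1, 99, 100), 2),
        evalue = 10^-runif(1, 10, 60),
        stringsAsFactors = FALSE)
    }
  }
  aln <- do.call(rbind, rows)
  if (nDecoy > 0) {
    fail <- sample(c("len", "ident", "eval"), nDecoy, replace = TRUE)
    decoys <- lapply(seq_len(nDecoy), function(j) {
      s <- 1e7 + j * 1e5
      data.frame(
        transcript_id = sprintf("decoy_t%02d", j),
        genotype = sample(genotypes, 1), chromosome = paste0("chr", 24),
        start = s, end = s + 500,
        aligned_length = if (fail[j] == "len") 120L else 501L,
        identity = if (fail[j] == "ident") 97.5 else 99.5,
        evalue = if (fail[j] == "eval") 1e-3 else 1e-20,
        stringsAsFactors = FALSE)
    })
    aln <- rbind(aln, do.call(rbind, decoys))
  }
  rownames(aln) <- NULL
  list(alignments = aln,
       truth = data.frame(locus = seq_len(nLoci), chromosome = chrom,
                          start = start, end = start + width,
                          focalOnly = focalOnly))
}

# single-nucleotide neighbour lists per sense codon:
# $syn (same aa), $non (different aa, not stop)
.codonNeighbours <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- .allCodons()
    aa <- .codonAA(codons)
    sense <- codons[aa != "*"]
    out <- lapply(sense, function(cod) {
      cs <- strsplit(cod, "")[[1]]
      muts <- character()
      for (pos in 1:3) for (b in setdiff(.BASES, cs[pos])) {
        m <- cs; m[pos] <- b
        muts <- c(muts, paste(m, collapse = ""))
      }
      maa <- .codonAA(muts)
      list(syn = muts[maa == .codonAA(cod)],
           non = muts[maa != .codonAA(cod) & maa != "*"])
    })
    names(out) <- sense
    cache <<- out
    cache
  }
})

#' Generate a divergence-controlled CDS pair with exact truth
#'
#' Draws an ancestor of `nCodons` sense codons uniformly and derives a
#' descendant by, per codon, at most one single-nucleotide substitution:
#' synonymous with probability `targetPS * s_c` and nonsynonymous with
#' probability `targetPN * n_c`, where `s_c`/`n_c` are the codon's
#' synonymous/nonsynonymous site counts — so the expected difference
#' proportions match the targets. No stop codons are ever introduced, and
#' because no codon carries more than one change, Nei-Gojobori counting
#' recovers the planted difference counts exactly.
#'
#' @param nCodons number of codons (>= 50).
#' @param targetPS,targetPN target proportions of synonymous /
#'   nonsynonymous differences per respective site, in `[0, 0.7)`;
#'   combinations that would require per-codon substitution probabilities
#'   above 1 (possible above 1/3) raise an error.
#' @param seed integer seed.
#' @return list with `seqs` (named character: ancestor, derived) and
#'   `truth` (Sd, Nd, SSites, NSites, pS, pN, seed).
#' @export
simCdsPair <- function(nCodons, targetPS, targetPN, seed) {
  stopifnot(!missing(seed), nCodons >= 50,
            targetPS >= 0, targetPS < 0.7, targetPN >= 0, targetPN < 0.7)
  set.seed(seed)
  nb <- .codonNeighbours()
  sense <- names(nb)
  syn <- .codonSynSites()
  anc <- sample(sense, nCodons, replace = TRUE)
  sC <- syn[anc]
  nC <- 3 - sC
  pSyn <- targetPS * sC
  pNon <- targetPN * nC
  if (any(pSyn + pNon > 1))
    stop("infeasible targets for the sampled ancestor ",
         "(per-codon substitution probability exceeds 1)")
  u <- runif(nCodons)
  der <- anc
  Sd <- 0L; Nd <- 0L
  for (i in seq_len(nCodons)) {
    if (u[i] < pSyn[i] && length(nb[[anc[i]]]$syn)) {
      der[i] <- sample(nb[[anc[i]]]$syn, 1)
      Sd <- Sd + 1L
    } else if (u[i] < pSyn[i] + pNon[i] && length(nb[[anc[i]]]$non)) {
      der[i] <- sample(nb[[anc[i]]]$non, 1)
      Nd <- Nd + 1L
    }
  }
  SSites <- (sum(syn[anc]) + sum(syn[der])) / 2
  NSites <- 3 * nCodons - SSites
  list(seqs = c(ancestor = paste(anc, collapse = ""),
                derived = paste(der, collapse = "")),
       truth = list(Sd = Sd, Nd = Nd, SSites = SSites, NSites = NSites,
                    pS = Sd / SSites, pN = Nd / NSites, seed = seed))
}

#' Generate a TPM expression matrix with planted structure
#'
#' Latent-factor Gaussian model exponentiated to non-negative TPM-like
#' values (Spearman statistics are invariant under the per-gene monotone
#' transform, so the planted rank correlations survive exactly). Family
#' genes can carry planted correlated modules and a hub gene; breadth
#' classes are realized by structural zeros, so the default TPM > 0
#' expression call recovers them exactly; pool genes are mutually
#' independent background.
#'
#' @param nFamily number of family genes (default 117).
#' @param nPool number of background pool genes (default 500).
#' @param design `"ages4"`, `"tissues14"` or `"cultivars42"`.
#' @param moduleSpec optional list of modules, each
#'   `list(size =, rho =)`: `size` family genes sharing a latent factor
#'   with pairwise Pearson correlation `rho` (at `noiseSd = 1`).
#' @param hubSpec optional `list(nPartners =, rho =)`: the first family
#'   gene after the modules becomes a hub correlated at `rho` with
#'   `nPartners` following genes (partners are conditionally independent
#'   given the hub).
#' @param breadthSpec optional list with integer vectors `family` and/or
#'   `pool`, per-gene breadth k (samples expressed); remaining samples are
#'   zeroed. Defaults to all samples expressed.
#' @param noiseSd idiosyncratic noise scale (0 = deterministic factors).
#' @param seed integer seed.
#' @return list with `experiment` ([TpmExperiment-class]) and `truth`
#'   (familyIds, poolIds, modules, hubId, partnerIds, breadth, seed).
#' @export
simExpression <- function(nFamily = 117, nPool = 500,
                          design = c("cultivars42", "tissues14", "ages4"),
                          moduleSpec = NULL, hubSpec = NULL,
                          breadthSpec = NULL, noiseSd = 1, seed) {
  stopifnot(!missing(seed))
  design <- match.arg(design)
  m <- .DESIGN_SIZES[[design]]
  set.seed(seed)
  famIds <- sprintf("fam_%03d", seq_len(nFamily))
  poolIds <- sprintf("bg_%04d", seq_len(nPool))
  ids <- c(famIds, poolIds)
  z <- matrix(rnorm((nFamily + nPool) * m), ncol = m,
              dimnames = list(ids, NULL)) * noiseSd
  cursor <- 0
  modules <- list()
  for (mod in moduleSpec) {
    stopifnot(mod$size >= 2, mod$rho >= 0, mod$rho <= 1)
    if (cursor + mod$size > nFamily)
      stop("module spec exceeds the number of family genes")
    gi <- famIds[cursor + seq_len(mod$size)]
    f <- rnorm(m)
    a <- sqrt(mod$rho)
    z[gi, ] <- a * rep(f, each = mod$size) +
      noiseSd * sqrt(1 - mod$rho) * matrix(rnorm(mod$size * m), ncol = m)
    modules <- c(modules, list(gi))
    cursor <- cursor + mod$size
  }
  hubId <- character(); partnerIds <- character()
  if (!is.null(hubSpec)) {
    stopifnot(hubSpec$nPartners >= 1, hubSpec$rho > 0, hubSpec$rho <= 1)
    if (cursor + 1 + hubSpec$nPartners > nFamily)
      stop("hub spec exceeds the number of family genes")
    hubId <- famIds[cursor + 1]
    partnerIds <- famIds[cursor + 1 + seq_len(hubSpec$nPartners)]
    f <- rnorm(m)
    z[hubId, ] <- f
    z[partnerIds, ] <- hubSpec$rho * rep(f, each = length(partnerIds)) +
      noiseSd * sqrt(1 - hubSpec$rho^2) *
        matrix(rnorm(length(partnerIds) * m), ncol = m)
    cursor <- cursor + 1 + hubSpec$nPartners
  }
  mu <- rnorm(length(ids), mean = 2, sd = 1)
  v <- exp(z + mu)
  colnames(v) <- sprintf("%s_s%02d", design, seq_len(m))
  breadth <- setNames(rep.int(m, length(ids)), ids)
  applyBreadth <- function(idsSub, ks) {
    stopifnot(length(ks) == length(idsSub), all(ks >= 0), all(ks <= m))
    for (j in seq_along(idsSub)) {
      off <- sample(m, m - ks[j])
      v[idsSub[j], off] <<- 0
      breadth[idsSub[j]] <<- ks[j]
    }
  }
  if (!is.null(breadthSpec$family)) applyBreadth(famIds, breadthSpec$family)
  if (!is.null(breadthSpec$pool)) applyBreadth(poolIds, breadthSpec$pool)
  te <- TpmExperiment(v, design)
  list(experiment = te,
       truth = list(familyIds = famIds, poolIds = poolIds,
                    modules = modules, hubId = hubId,
                    partnerIds = partnerIds, breadth = breadth,
                    seed = seed))
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Per gene, group and replicate: `ct_reference` is drawn around
#' `refCt`, and `ct_target = ct_reference + dCtBase - log2(fold) + noise`,
#' so the Livak 2^-ddCt analysis recovers the planted fold relative to the
#' calibrator group exactly when `ctNoiseSd = 0`.
#'
#' @param genes character vector of gene ids.
#' @param plantedFold numeric matrix genes x groups of fold changes
#'   relative to the calibrator (calibrator column must be 1); a single
#'   number is recycled.
#' @param groups treatment groups (default pH 4, 5, 6, 7, 8).
#' @param calibratorGroup control group (default 6), must be in `groups`.
#' @param nRep biological replicates per group (default 3).
#' @param ctNoiseSd Ct measurement noise sd (default 0.1).
#' @param seed integer seed.
#' @param dCtBase baseline dCt of the calibrator condition (default 2).
#' @param refCt,refNoiseSd reference-gene Ct level and its variation.
#' @return list with `ct` (data.frame: group, replicate, gene_id,
#'   ct_target, ct_reference) and `truth` (plantedFold matrix, seed).
#' @export
simQpcr <- function(genes, plantedFold = 1, groups = c(4, 5, 6, 7, 8),
                    calibratorGroup = 6, nRep = 3, ctNoiseSd = 0.1, seed,
                    dCtBase = 2, refCt = 20, refNoiseSd = 0.1) {
  stopifnot(!missing(seed), calibratorGroup %in% groups, nRep >= 2)
  if (!is.matrix(plantedFold))
    plantedFold <- matrix(plantedFold, length(genes), length(groups),
                          dimnames = list(genes, groups))
  stopifnot(all(plantedFold > 0),
            all(plantedFold[, as.character(calibratorGroup)] == 1))
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(nRep), group = groups,
                      gene_id = genes, stringsAsFactors = FALSE)
  ctRef <- refCt + rnorm(nrow(grid), sd = refNoiseSd)
  fold <- plantedFold[cbind(grid$gene_id, as.character(grid$group))]
  ctTar <- ctRef + dCtBase - log2(fold) + rnorm(nrow(grid), sd = ctNoiseSd)
  ct <- data.frame(group = grid$group, replicate = grid$replicate,
                   gene_id = grid$gene_id, ct_target = ctTar,
                   ct_reference = ctRef, stringsAsFactors = FALSE)
  list(ct = ct, truth = list(plantedFold = plantedFold, seed = seed))
}
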