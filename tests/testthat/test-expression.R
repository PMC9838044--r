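test_that("expression calls use a strict TPM threshold", {
  m <- matrix(c(0, 0.5, 1.0, 2.0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  b0 <- callExpressed(m)
  expect_identical(unname(b0), matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  b1 <- callExpressed(m, threshold = 1)
  expect_false(b1["g1", "s2"])   # TPM 1.0 at threshold 1.0 -> not expressed
  # monotone: raising the threshold never increases any breadth
  set.seed(8)
  v <- matrix(rexp(200), 20, 10)
  for (th in c(0, 0.1, 0.5, 1, 2)) {
    k1 <- rowSums(callExpressed(v, th))
    k2 <- rowSums(callExpressed(v, th + 0.5))
    expect_true(all(k2 <= k1))
  }
})

test_that("breadth histogram matches direct enumeration and conserves genes", {
  set.seed(15)
  b <- matrix(runif(120) > 0.4, 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  d <- breadthDistribution(b)
  direct <- vapply(0:6, function(k)
    sum(apply(b, 1, function(r) sum(r) == k)), integer(1))
  expect_identical(unname(d$counts), direct)
  expect_equal(sum(d$counts), nrow(b))
  # the published percentage arithmetic: 95 of 117 with k >= 1 -> 81.2
  bb <- matrix(FALSE, 117, 4)
  bb[1:95, 1] <- TRUE
  expect_equal(breadthDistribution(bb)$pctAtLeastOne, 81.2)
})

test_that("background comparison flags extreme separation and errors on small pools", {
  v <- rbind(matrix(5, 20, 4), matrix(0, 200, 4))
  rownames(v) <- c(sprintf("t%02d", 1:20), sprintf("p%03d", 1:200))
  target <- rownames(v)[1:20]
  pool <- rownames(v)[21:220]
  bc <- compareWithRandomBackground(target, pool, v, nBoot = 20, seed = 1)
  expect_equal(bc$targetAtLeastOne, 20)
  expect_true(all(bc$randomAtLeastOne == 0))
  expect_true(bc$significant)
  expect_equal(bc$nBoot, 20)
  expect_error(
    compareWithRandomBackground(rownames(v)[1:150], pool[1:100], v,
                                seed = 1),
    "smaller")
})

test_that("core gene set is the intersection of all-sample sets", {
  set.seed(21)
  mk <- function(design, k) {
    simExpression(nFamily = 40, nPool = 10, design = design,
                  breadthSpec = list(family = k), seed = 31)$experiment
  }
  # plant 19 ubiquitous family genes; the rest miss >= 1 sample somewhere
  kA <- c(rep(4, 19), rep(3, 21))
  kT <- c(rep(14, 19), sample(0:13, 21, replace = TRUE))
  kC <- c(rep(42, 19), rep(42, 21))   # ubiquitous here, not elsewhere
  core <- coreGeneSet(mk("ages4", kA), mk("tissues14", kT),
                      mk("cultivars42", kC))
  fam <- sprintf("fam_%03d", 1:19)
  expect_false(any(sprintf("fam_%03d", 20:40) %in% core))
  expect_true(all(fam %in% core))
  # pool genes are fully expressed in every design, so they are in the core
  expect_setequal(setdiff(core, fam), sprintf("bg_%04d", 1:10))
  expect_error(coreGeneSet(matrix(TRUE, 2, 2,
                                  dimnames = list(c("a", "b"), NULL)),
                           matrix(TRUE, 2, 2,
                                  dimnames = list(c("a", "c"), NULL))),
               "universes differ")
})

test_that("age trends require strict monotonicity and the fold span", {
  v <- rbind(up = c(1, 2, 4, 8), flat = c(3, 3, 3, 3),
             down = c(8, 4, 2, 1), wiggle = c(1, 3, 2, 8),
             weak = c(1, 1.2, 1.4, 1.6))
  tr <- ageTrendGenes(v, minFold = 2)
  expect_setequal(tr$gene_id, c("up", "down"))
  expect_identical(tr$direction[tr$gene_id == "up"], "increasing")
  expect_identical(tr$direction[tr$gene_id == "down"], "decreasing")
  expect_equal(tr$fold_span[tr$gene_id == "up"], 8)
  # noisy fixture at the fold boundary vs direct rule evaluation
  set.seed(12)
  for (i in 1:20) {
    x <- cumprod(c(1, runif(3, 0.8, 1.6)))
    got <- nrow(ageTrendGenes(rbind(g = x), minFold = 2))
    want <- as.integer((all(diff(x) > 0) || all(diff(x) < 0)) &&
                         max(x) / min(x) >= 2)
    expect_equal(got, want)
  }
})

test_that("sample clustering recovers planted blocks", {
  # two blocks with rho = 1 inside and rho = -1 across
  base <- rexp(30)
  v <- cbind(a1 = base, a2 = 2 * base + 1, b1 = -base, b2 = 1 - 3 * base)
  rownames(v) <- sprintf("g%02d", 1:30)
  grp <- clusterSamples(v, 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])
  # identical samples: arbitrary but deterministic cut
  vv <- matrix(rep(rexp(10), 3), 10, 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  expect_identical(clusterSamples(vv, 2), clusterSamples(vv, 2))
  # planted above/below-ground blocks with noise: >= 90% agreement
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    f <- rnorm(40)
    block <- rep(c(1, -1), each = 7)
    z <- sapply(block, function(b) 0.9 * b * f + 0.6 * rnorm(40))
    colnames(z) <- sprintf("t%02d", 1:14)
    g <- clusterSamples(exp(z), 2)
    agree <- max(mean(g == rep(1:2, each = 7)),
                 mean(g == rep(2:1, each = 7)))
    hits <- hits + (agree == 1)
  }
  expect_gte(hits / 50, 0.9)
})
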