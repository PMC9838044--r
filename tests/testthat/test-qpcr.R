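.ctTable <- function(dct, gene = "g1", groups = NULL, ref = 20) {
  # dct: named list group -> vector of per-replicate dCt values
  rows <- lapply(names(dct), function(g)
    data.frame(group = as.numeric(g),
               replicate = seq_along(dct[[g]]), gene_id = gene,
               ct_target = ref + dct[[g]], ct_reference = ref))
  do.call(rbind, rows)
}

test_that("Livak folds are anchored at the calibrator", {
  ct <- .ctTable(list(`6` = c(2, 2, 2), `4` = c(1, 1, 1),
                      `8` = c(2, 2, 2)))
  re <- relativeExpression(ct)
  s <- re$summary
  expect_equal(s$meanFold[s$group == 6], 1)     # dCt equal to calibrator
  expect_equal(s$meanFold[s$group == 4], 2)     # ddCt = -1 -> fold 2
  expect_equal(s$meanFold[s$group == 8], 1)
  expect_true(all(re$perReplicate$fold > 0))
  # calibrator geometric mean is exactly 1 even with replicate scatter
  ct2 <- .ctTable(list(`6` = c(1.7, 2.4, 2.1), `4` = c(0.9, 1.3, 1.1)))
  re2 <- relativeExpression(ct2)
  expect_identical(re2$summary$meanFold[re2$summary$group == 6], 1)
  expect_error(relativeExpression(.ctTable(list(`4` = c(1, 1, 1)))),
               "calibrator")
  ctNA <- .ctTable(list(`6` = c(2, 2, 2)))
  ctNA$ct_reference[1] <- NA
  expect_error(relativeExpression(ctNA), "missing reference")
})

test_that("planted qPCR folds are recovered from noisy fixtures", {
  # noise-free: exact recovery
  q0 <- simQpcr("g1", plantedFold = matrix(c(2, 1, 1, 1, 1), 1, 5,
                                           dimnames = list("g1", 4:8)),
                ctNoiseSd = 0, seed = 3)
  r0 <- relativeExpression(q0$ct)
  expect_equal(r0$summary$meanFold[r0$summary$group == 4], 2,
               tolerance = 1e-12)
  # planted 3x induction, Ct noise sd 0.1: mean fold within [2.5, 3.6]
  folds <- vapply(1:100, function(s) {
    q <- simQpcr("g1", plantedFold = matrix(c(3, 1, 1, 1, 1), 1, 5,
                                            dimnames = list("g1", 4:8)),
                 ctNoiseSd = 0.1, seed = s)
    r <- relativeExpression(q$ct)
    r$summary$meanFold[r$summary$group == 4]
  }, numeric(1))
  expect_gte(mean(folds), 2.5)
  expect_lte(mean(folds), 3.6)
  expect_gte(mean(folds >= 2.5 & folds <= 3.6), 0.95)
  expect_error(simQpcr("g1", plantedFold = matrix(c(-1, 1, 1, 1, 1), 1, 5,
                                                  dimnames = list("g1", 4:8)),
                       seed = 1))
})

test_that("treatment significance maps p to the star code", {
  expect_identical(treatmentSignificance(c(1, 1, 1), c(1, 1, 1))$stars, "")
  expect_equal(treatmentSignificance(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_identical(treatmentSignificance(c(1, 1, 1), c(2, 2, 2))$stars,
                   "**")
  g1 <- c(1.0, 1.1, 0.9); g2 <- c(1.6, 1.8, 1.5)
  r <- treatmentSignificance(g1, g2)
  expect_equal(r$p, stats::t.test(g1, g2)$p.value)
  expect_identical(r$stars, if (r$p <= 0.01) "**" else
    if (r$p <= 0.05) "*" else "")
  # star rule boundaries are deterministic in p
  starOf <- function(p) if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  expect_identical(starOf(0.03), "*")
  expect_identical(starOf(0.005), "**")
  expect_identical(starOf(0.2), "")
  # well-separated groups (10 sd at 3 replicates; Welch df ~ 4 needs a
  # wide gap for near-certain detection): ** in >= 99% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    treatmentSignificance(rnorm(3, 10, 1), rnorm(3, 0, 1))$stars == "**"
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("hub correlation matrix is symmetric with planted signs", {
  set.seed(44)
  base <- matrix(c(3, 2, 1, 1.5, 2.5), 1, 5, dimnames = list(NULL, 4:8))
  mk <- function(v) matrix(v / v[3], 1, 5)  # normalize calibrator to 1
  planted <- rbind(hubA = mk(c(3, 2, 1, 1.5, 2.5)),
                   hubB = mk(c(2.8, 1.9, 1, 1.4, 2.2)),
                   hubC = mk(c(2.5, 2.1, 1, 1.6, 2.4)),
                   hubD = mk(1 / c(3, 2, 1, 1.5, 2.5)))
  dimnames(planted) <- list(c("hubA", "hubB", "hubC", "hubD"), 4:8)
  signHits <- vapply(1:100, function(s) {
    q <- simQpcr(rownames(planted), plantedFold = planted,
                 ctNoiseSd = 0.15, seed = s)
    hc <- hubCorrelations(relativeExpression(q$ct))
    all(hc$rho["hubA", c("hubB", "hubC")] > 0, hc$rho["hubA", "hubD"] < 0)
  }, logical(1))
  expect_gte(mean(signHits), 0.95)
  q <- simQpcr(rownames(planted), plantedFold = planted, seed = 1)
  hc <- hubCorrelations(relativeExpression(q$ct))
  expect_equal(hc$rho, t(hc$rho))
  expect_equal(unname(diag(hc$rho)), rep(1, 4))
  expect_true(all(hc$significant[hc$p <= 0.05 & !is.na(hc$p)]))
  # a gene against its negation: rho -1 and significant
  v <- rbind(g1 = 1:15, g2 = 15:1)
  e <- spearmanEdges(v)
  expect_equal(e$rho, -1)
  expect_equal(e$p, 0)
})
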