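test_that("subfamily classification follows the diagnostic domain rules", {
  expect_identical(classifySubfamily(c("HD", "HALZ")), "I")
  expect_identical(classifySubfamily(c("HD", "HALZ", "CPSCE")), "II")
  expect_identical(classifySubfamily(c("HD", "START", "MEKHLA")), "III")
  expect_identical(classifySubfamily(c("HD", "START")), "IV")
  # the non-diagnostic N-terminal domain never changes the call
  expect_identical(classifySubfamily(c("HD", "HALZ", "HDZIP_NTERM")), "I")
  # HALZ takes precedence over START when both are present (nested rules)
  expect_identical(classifySubfamily(c("HD", "HALZ", "START")), "I")
  expect_true(is.na(classifySubfamily("HALZ")))
  expect_true(is.na(classifySubfamily("HD")))
  r <- classifySubfamily(character())
  expect_true(is.na(r))
  expect_identical(attr(r, "reason"), "no HD")
  expect_error(classifySubfamily("HOMEOBOX"), "unknown domain")
})

test_that("classification is total over all domain subsets", {
  doms <- c("HD", "HALZ", "START", "MEKHLA", "CPSCE", "HDZIP_NTERM")
  for (mask in 0:63) {
    s <- doms[bitwAnd(mask, 2^(0:5)) > 0]
    out <- classifySubfamily(s)
    expect_length(out, 1)
    expect_true(out %in% c("I", "II", "III", "IV") || is.na(out))
  }
})

test_that("identifyFamily recovers planted labels and logs rejections", {
  d <- simDomainTable(c(I = 10, II = 4, III = 3, IV = 5), nRejected = 6,
                      seed = 42)
  f <- identifyFamily(d$hits)
  truth <- setNames(d$truth$subfamily, d$truth$transcript_id)
  expect_identical(unname(truth[f$members$transcript_id]),
                   f$members$subfamily)
  expect_setequal(f$rejected$transcript_id,
                  d$truth$transcript_id[d$truth$subfamily == "rejected"])
  expect_true(all(nzchar(f$rejected$reason)))
})

test_that("candidate-set union keeps provenance and exclusives", {
  u <- mergeCandidateSets(list(a = c("A", "B"), b = c("B", "C"),
                               c = c("C", "D")))
  expect_identical(u$ids, c("A", "B", "C", "D"))
  expect_identical(mergeCandidateSets(list(x = "A"))$ids, "A")
  expect_true(all(rowSums(u$provenance) >= 1))
  expect_identical(u$exclusives$a, "A")
  expect_error(mergeCandidateSets(list()), "at least one")

  cs <- simCandidateSets(sizes = c(114, 83, 112), unionSize = 117,
                         nExclusiveSecond = 1, seed = 7)
  m <- mergeCandidateSets(cs$sets)
  expect_length(m$ids, 117)
  expect_identical(m$ids, cs$truth$unionIds)
  expect_identical(m$exclusives$known_gene_blast, cs$truth$exclusiveSecond)
  expect_lte(length(m$ids), sum(lengths(cs$sets)))
})

.aln <- function(id, chr, s, e, gt = "Damaya", len = e - s + 1,
                 ident = 99.5, ev = 1e-20) {
  data.frame(transcript_id = id, genotype = gt, chromosome = chr,
             start = s, end = e, aligned_length = len, identity = ident,
             evalue = ev, stringsAsFactors = FALSE)
}

test_that("locus assignment filters and merges overlapping alignments", {
  a <- rbind(
    .aln("t1", "chr1", 1000, 1800),
    .aln("t2", "chr1", 1500, 2300),
    .aln("short", "chr1", 5000, 5149, len = 150),   # < 180 bp
    .aln("diverged", "chr1", 6000, 6400, ident = 98.5),
    .aln("weak", "chr1", 7000, 7400, ev = 1e-3))
  L <- assignLoci(a)
  expect_equal(nrow(L), 1)
  expect_equal(L$n_transcripts, 2)
  expect_setequal(unlist(L$members), c("t1", "t2"))
  expect_setequal(attr(L, "unplaced"), c("short", "diverged", "weak"))
  expect_error(assignLoci(.aln("t1", "chrX", 1, 400)), "unknown chromosome")
})

test_that("locus merging matches a brute-force interval oracle", {
  a <- rbind(
    .aln("a1", "chr1", 100, 500), .aln("a2", "chr1", 450, 900),
    .aln("a3", "chr1", 2000, 2400), .aln("b1", "chr2", 100, 500),
    .aln("b2", "chr2", 300, 700), .aln("b3", "chr2", 700, 1100))
  L <- assignLoci(a)
  expect_equal(nrow(L), 3)
  for (chr in c("chr1", "chr2")) {
    sub <- a[a$chromosome == chr, ]
    want <- orcMergeIntervals(sub$start, sub$end)
    got <- L[L$chromosome == chr, c("start", "end")]
    expect_equal(unname(as.matrix(got)), unname(want))
  }
  # random fixtures: merged loci never overlap on one chromosome
  set.seed(1)
  for (rep in 1:20) {
    s <- sample(1:5000, 30, replace = TRUE)
    rnd <- .aln(sprintf("r%02d", 1:30), sample(paste0("chr", 1:3), 30,
                                               replace = TRUE),
                s, s + sample(180:800, 30, replace = TRUE))
    Lr <- assignLoci(rnd)
    expect_lte(sum(Lr$n_transcripts), 30)
    for (chr in unique(Lr$chromosome)) {
      iv <- Lr[Lr$chromosome == chr, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1)
        expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    }
  }
})

test_that("genotype-specific loci are exactly the planted ones", {
  ga <- simGenomeAlignments(nShared = 60, nFocalOnly = 5, seed = 11)
  L <- assignLoci(ga$alignments)
  expect_equal(nrow(L), 65)
  sp <- findGenotypeSpecific(L, "Damaya")
  expect_equal(nrow(sp), 5)
  expect_true(all(vapply(sp$members, function(m)
    identical(names(m), "Damaya"), logical(1))))
  shared <- L[!L$locus_id %in% sp$locus_id, ]
  expect_true(all(vapply(shared$members, function(m)
    length(names(m)) == 3, logical(1))))
  expect_error(findGenotypeSpecific(L, "Yunpoong"), "absent")
})

test_that("GO Venn cells partition the annotated members", {
  members <- data.frame(
    transcript_id = sprintf("t%02d", 1:15),
    subfamily = rep(c("I", "II", "III"), each = 5),
    stringsAsFactors = FALSE)
  ann <- rbind(
    data.frame(transcript_id = "t01", category = c("BP", "MF", "CC")),
    do.call(rbind, lapply(sprintf("t%02d", 11:15), function(id)
      data.frame(transcript_id = id, category = c("MF", "CC")))))
  g <- summarizeGo(ann, members)
  expect_equal(g$venn[["BP&MF&CC"]], 1)
  expect_equal(g$venn[["MF&CC"]], 5)
  expect_equal(sum(g$venn), g$nAnnotated)
  expect_equal(unname(g$bySubfamily["MF&CC", "III"]), 5)
  expect_warning(
    g2 <- summarizeGo(rbind(ann, data.frame(transcript_id = "ghost",
                                            category = "BP")), members),
    "skipped")
  expect_equal(sum(g2$venn), g2$nAnnotated)

  # random fixture: cells always sum to the annotated total
  set.seed(3)
  for (rep in 1:10) {
    ids <- sample(members$transcript_id, 10)
    rnd <- do.call(rbind, lapply(ids, function(id) {
      k <- sample(1:3, 1)
      data.frame(transcript_id = id,
                 category = sample(c("BP", "MF", "CC"), k))
    }))
    gr <- summarizeGo(rnd, members)
    expect_equal(sum(gr$venn), length(ids))
  }
})
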