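# Homoeolog alignment: per-reference candidates, assignment rules,
# SV-tolerant gap handling, coverage statistics and consensus building.

test_that("error-free reads align with identity 1 to their own reference", {
  refs <- fxRefs()
  read <- substr(refSeq(refs$A), 2001, 10000)
  cand <- alignToReferences(read, refs, refineAll = TRUE)
  expect_equal(cand$identity[cand$ref_id == "A"], 1.0)
  asg <- assignHomoeolog(cand)
  expect_equal(asg$assignment, "unique")
  expect_equal(asg$ref_id, "A")
})

test_that("cross-homoeolog identity matches the reference divergence", {
  refs <- fxRefs()
  read <- refSeq(refs$B)
  cand <- alignToReferences(read, refs, refineAll = TRUE)
  idAB <- cand$identity[cand$ref_id == "A"]
  # the B amplicon scored against the A reference reads out the ~8%
  # homoeolog divergence (gap-compressed, so slightly above the full-column
  # pairwise identity)
  expect_gt(idAB, 0.88)
  expect_lt(idAB, 0.96)
})

test_that("reads spanning a multi-kb deletion keep it as one operation", {
  run <- fxSvRun("b1a", "B", knownSvEdits()[["Vrn-B1a"]])
  s <- alignmentSummary(run$aln)
  expect_true(all(s$assignment == "unique"))
  expect_true(all(s$ref_id == "B"))
  ops <- alignmentOps(run$aln)
  bigD <- vapply(ops, function(op)
    sum(op[, 2][op[, 1] == 4 & op[, 2] >= 6000]), 0)
  expect_true(all(bigD == 6851))
})

test_that("low identity or tied references are rejected from assignment", {
  refs <- fxRefs()
  set.seed(15)
  junk <- rseq(4000)
  cand <- alignToReferences(junk, refs)
  asg <- assignHomoeolog(cand)
  expect_equal(asg$assignment, "unaligned")
  # identical references cannot be separated: ambiguous
  twin <- list(A = refs$A, A2 = refs$A)
  read <- substr(refSeq(refs$A), 3001, 9000)
  asg2 <- assignHomoeolog(alignToReferences(read, twin, refineAll = TRUE))
  expect_equal(asg2$assignment, "ambiguous")
})

test_that("assignment is near-perfect for full-length reads at 8% divergence", {
  refs <- fxRefs()
  genos <- list(cultivarGenotype("x", list(
    templateCopy("A", alleleEdit(), "a", 1),
    templateCopy("B", alleleEdit(), "b", 1),
    templateCopy("D", alleleEdit(), "d", 1))))
  p <- simulatePanel(genos, refs, 25, errorModel(),
                     barcodes = ontLikeBarcodes(1), seed = 17)
  d <- demuxPanel(p)
  keep <- d$status == "assigned"
  aln <- alignPanel(trimmedReads(p, d), refs,
                    sample_ids = rep("x", sum(keep)))
  s <- alignmentSummary(aln)
  tr <- panelTruth(p)[keep, ]
  ok <- s$assignment == "unique" & s$ref_id == tr$homoeolog
  expect_gte(mean(ok), 0.95)
})

test_that("coverage statistics recompute CV and expose amplification skew", {
  refs <- fxRefs()
  # Highbury-like: short deletion-carrying B amplicon amplifies strongly
  g <- cultivarGenotype("hb", list(
    templateCopy("A", alleleEdit(), "a", 1),
    templateCopy("B", knownSvEdits()[["Vrn-B1a"]], "b", 60),
    templateCopy("D", alleleEdit(), "d", 1)))
  g2 <- cultivarGenotype("ev", list(
    templateCopy("A", alleleEdit(), "a", 1),
    templateCopy("B", alleleEdit(), "b", 1),
    templateCopy("D", alleleEdit(), "d", 1)))
  p <- simulatePanel(list(g, g2), refs, 40, fxErrorFree(),
                     barcodes = ontLikeBarcodes(2), seed = 19)
  d <- demuxPanel(p)
  aln <- alignPanel(trimmedReads(p, d), refs,
                    sample_ids = d$sample_id[d$status == "assigned"])
  cov <- coverageStats(aln, refs)
  # CV equals an independent sd/mean recomputation on the depth table
  for (h in colnames(cov$depth)) {
    expect_equal(cov$cv[[h]], sd(cov$depth[, h]) / mean(cov$depth[, h]))
  }
  expect_gt(cov$ratios["hb", "B/D"], 50)
  # even sample: near-equal depths
  expect_gt(cov$ratios["ev", "A/B"], 0.5)
  expect_lt(cov$ratios["ev", "A/B"], 2)
})

test_that("consensus from error-free reads reproduces the template exactly", {
  run <- fxSvRun("d1r", "D", knownSvEdits()[["vrn-D1r"]])
  refs <- fxRefs()
  pu <- buildPileup(run$aln, refs$D, sample = "d1r")
  cons <- referenceGuidedConsensus(pu, refs$D)
  tmpl <- applyAllele(refs$D, knownSvEdits()[["vrn-D1r"]])
  expect_identical(cons$seq, tmpl)
  expect_equal(length(cons$depth), nchar(tmpl))
})

test_that("consensus fails explicitly below the read-support minimum", {
  refs <- fxRefs()
  g <- cultivarGenotype("lc", list(templateCopy("D", alleleEdit(), "h", 1)))
  p <- simulatePanel(list(g), refs["D"], 2, fxErrorFree(),
                     barcodes = ontLikeBarcodes(1), seed = 3)
  d <- demuxPanel(p)
  aln <- alignPanel(trimmedReads(p, d), refs,
                    sample_ids = rep("lc", sum(d$status == "assigned")))
  pu <- buildPileup(aln, refs$D, sample = "lc")
  expect_error(referenceGuidedConsensus(pu, refs$D, minReads = 3L),
               class = "lowCoverageError")
})

test_that("consensus identity does not degrade with more coverage", {
  refs <- fxRefs()
  em <- errorModel()
  tmpl <- refSeq(refs$D)
  idAt <- function(cvg, seed) {
    g <- cultivarGenotype("cc", list(templateCopy("D", alleleEdit(), "h", 1)))
    p <- simulatePanel(list(g), refs["D"], cvg, em,
                       barcodes = ontLikeBarcodes(1), seed = seed)
    d <- demuxPanel(p)
    aln <- alignPanel(trimmedReads(p, d), refs,
                      sample_ids = rep("cc", sum(d$status == "assigned")))
    pu <- buildPileup(aln, refs$D, sample = "cc")
    globalIdentity(referenceGuidedConsensus(pu, refs$D)$seq, tmpl)
  }
  i10 <- idAt(12, 41); i40 <- idAt(45, 41)
  expect_gte(i40, i10 - 0.001)
  expect_gt(i40, 0.995)
})
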