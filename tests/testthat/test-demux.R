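# Demultiplexing: mean-Q definition, barcode classification with chimera
# detection, read filtering, partition property and rate recovery.

test_that("meanQscore averages error probabilities before the log", {
  expect_equal(meanQscore(rep(10L, 50)), 10)
  expect_equal(meanQscore(c(rep(20L, 10), rep(10L, 10))),
               -10 * log10((0.01 + 0.1) / 2), tolerance = 1e-9)
  q <- rep(20L, 100)
  expect_lt(meanQscore(c(q, rep(2L, 5))), meanQscore(q))
  expect_error(meanQscore(integer(0)), "empty")
})

test_that("barcode hits classify reads as assigned, chimeric or unclassified", {
  set.seed(7)
  bcs <- setNames(ontLikeBarcodes(3), c("s1", "s2", "s3"))
  body <- rseq(4000)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # exact barcode within the head window
  r1 <- paste0(bcs[["s2"]], body, rc(bcs[["s2"]]))
  c1 <- classifyBarcode(r1, bcs)
  expect_equal(c1$status, "assigned")
  expect_equal(c1$sample_id, "s2")
  # barcode in the middle of the read = fusion
  r2 <- paste0(bcs[["s1"]], substr(body, 1, 2000), bcs[["s2"]],
               substr(body, 2001, 4000))
  expect_equal(classifyBarcode(r2, bcs)$status, "chimeric")
  # conflicting barcodes at the two ends
  r3 <- paste0(bcs[["s1"]], body, rc(bcs[["s3"]]))
  expect_equal(classifyBarcode(r3, bcs)$status, "chimeric")
  # no assignable barcode
  expect_equal(classifyBarcode(body, bcs)$status, "unclassified")
  expect_error(classifyBarcode(r1, character(0)), "empty")
})

test_that("read filter applies length and quality bounds in order", {
  expect_equal(filterRead(1999, 12), list(pass = FALSE, reason = "length_short"))
  expect_equal(filterRead(16001, 12), list(pass = FALSE, reason = "length_long"))
  expect_equal(filterRead(6000, 8), list(pass = TRUE, reason = "none"))
  expect_equal(filterRead(6000, 7.9), list(pass = FALSE, reason = "low_quality"))
  expect_equal(filterRead(1999, 2), list(pass = FALSE, reason = "length_short"))
})

test_that("every read receives exactly one terminal status", {
  refs <- fxRefs()
  genos <- vrnA1PanelGenotypes(c("GT3", "GT4"))
  em <- errorModel(sub = 0.01, ins = 0.005, del = 0.005,
                   chimeraProb = 0.1, barcodeLossProb = 0.15)
  p <- simulatePanel(genos, refs["A"], 40, em, barcodes = ontLikeBarcodes(2),
                     seed = 13)
  d <- demuxPanel(p)
  expect_equal(nrow(d), length(panelReads(p)))
  expect_true(all(d$status %in% c("assigned", "unclassified", "chimeric",
                                  "filtered")))
  expect_equal(sum(table(d$status)), nrow(d))
  expect_true(all(!is.na(d$sample_id[d$status == "assigned"])))
  expect_true(all(is.na(d$sample_id[d$status != "assigned"])))
})

test_that("configured barcode-loss rate is recovered as the unclassified fraction", {
  refs <- fxRefs()
  g <- cultivarGenotype("c1", list(templateCopy("A", alleleEdit(), "h", 1)))
  em <- errorModel(sub = 0.01, ins = 0.005, del = 0.005,
                   barcodeLossProb = 0.3)
  p <- simulatePanel(list(g), refs["A"], 1500, em,
                     barcodes = ontLikeBarcodes(1), seed = 23,
                     fullLengthFrac = 0.02, minReadLen = 600L)
  d <- demuxPanel(p)
  uncl <- mean(d$status == "unclassified")
  expect_lt(abs(uncl - 0.30), 0.025)
})

test_that("chimera detection has high recall and low false-positive rate", {
  refs <- fxRefs()
  genos <- vrnA1PanelGenotypes(c("GT3", "GT4", "GT6"))
  em <- errorModel(chimeraProb = 0.15)   # default ONT-like error rates
  p <- simulatePanel(genos, refs["A"], 55, em, barcodes = ontLikeBarcodes(3),
                     seed = 29)
  d <- demuxPanel(p)
  tr <- panelTruth(p)
  isChim <- tr$chimera
  recall <- mean(d$status[isChim] == "chimeric")
  falseRate <- mean(d$status[!isChim] == "chimeric")
  expect_gte(recall, 0.9)
  expect_lte(falseRate, 0.02)
})
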