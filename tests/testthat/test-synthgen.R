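# Synthetic-data generator: reference divergence, allele editing, read
# simulation with error/chimera/barcode models, phenotype simulation.

test_that("generated homoeolog references hit the target identity", {
  refs <- generateReferences(3, 0.92)
  im <- attr(refs, "identity")
  expect_equal(dim(im), c(3, 3))
  offdiag <- im[upper.tri(im)]
  expect_true(all(abs(offdiag - 0.92) <= 0.02))
  for (r in refs) {
    expect_s4_class(r, "HomoeologReference")
    f <- featureMap(r)
    expect_true(all(sort(names(f)) ==
                      sort(c("promoter", paste0("exon", 1:8),
                             paste0("intron", 1:7)))))
  }
})

test_that("reported identity agrees with an independent quadratic-time NW oracle", {
  refs <- generateReferences(3, 0.92)
  im <- attr(refs, "identity")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(refSeq(refs$A)), Biostrings::DNAString(refSeq(refs$B)),
    type = "global", gapOpening = 10, gapExtension = 0.5)
  oracle <- Biostrings::pid(pa, type = "PID1") / 100
  expect_lt(abs(im["A", "B"] - oracle), 0.005)
})

test_that("zero divergence gives identical references and bad targets error", {
  refs <- generateReferences(5, 1.0, geneLen = 10000L)
  expect_identical(refSeq(refs$A), refSeq(refs$B))
  expect_identical(refSeq(refs$B), refSeq(refs$D))
  expect_error(generateReferences(1, 0.4), "targetIdentity")
  expect_error(generateReferences(1, 0.92, geneLen = 5000L), "geneLen")
})

test_that("references carry quadruplex-eligible motifs in promoter and intron 1", {
  refs <- generateReferences(3, 0.92)
  for (r in refs) {
    f <- featureMap(r)
    pr <- substr(refSeq(r), IRanges::start(f["promoter"]), IRanges::end(f["promoter"]))
    i1 <- substr(refSeq(r), IRanges::start(f["intron1"]), IRanges::end(f["intron1"]))
    expect_gte(nrow(findG4(pr)), 1)
    expect_gte(nrow(findG4(i1)), 1)
  }
})

test_that("applyAllele edits obey length bookkeeping and right-to-left order", {
  refs <- fxRefs()
  s <- refSeq(refs$A)
  expect_identical(applyAllele(s, alleleEdit()), s)
  # duplication adds exactly its length
  dup <- alleleEdit("DUP", 6900L, 838L, "")
  expect_equal(nchar(applyAllele(s, dup)), nchar(s) + 838L)
  expect_identical(substr(applyAllele(s, dup), 6901, 6901 + 837),
                   substr(s, 6063, 6900))
  # property: signed length sum over random edit lists
  set.seed(42)
  for (rep in 1:20) {
    pos <- sort(sample(seq(100, nchar(s) - 100, by = 50), 6))
    kind <- sample(c("SNP", "INS", "DEL", "DUP"), 6, replace = TRUE)
    len <- ifelse(kind == "SNP", 1L, sample(1:20, 6, replace = TRUE))
    alt <- vapply(seq_len(6), function(i) {
      if (kind[i] == "SNP")
        sample(setdiff(c("A", "C", "G", "T"), substr(s, pos[i], pos[i])), 1)
      else if (kind[i] == "INS") rseq(len[i]) else ""
    }, "")
    e <- alleleEdit(kind, pos, len, alt)
    signed <- sum(ifelse(e$kind == "DEL", -e$length,
                         ifelse(e$kind == "SNP", 0L, e$length)))
    expect_equal(nchar(applyAllele(s, e)), nchar(s) + signed)
  }
})

test_that("a planted large deletion re-aligns as one deletion gap (alignment oracle)", {
  refs <- fxRefs()
  ed <- applyAllele(refs$B, knownSvEdits()[["Vrn-B1a"]])
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ed), Biostrings::DNAString(refSeq(refs$B)),
    type = "global", gapOpening = 20, gapExtension = 0.1)
  gaps <- Biostrings::deletion(pa)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(IRanges::width(gaps), 6851L)
})

test_that("applyAllele rejects invalid edits", {
  s <- "ACGTACGTACGT"
  expect_error(applyAllele(s, alleleEdit("SNP", 2L, 1L, "C")), "equals")
  expect_error(applyAllele(s, alleleEdit("DEL", 10L, 10L)), "range")
  expect_error(applyAllele(s, combineEdits(alleleEdit("DEL", 2L, 3L),
                                           alleleEdit("SNP", 3L, 1L, "A"))),
               "overlap")
})

test_that("zero-rate error model reproduces exact template substrings", {
  refs <- fxRefs()
  g <- cultivarGenotype("c1", list(templateCopy("A", alleleEdit(), "h", 1)))
  p <- simulatePanel(list(g), refs["A"], 20, fxErrorFree(),
                     barcodes = ontLikeBarcodes(1), seed = 9,
                     fullLengthFrac = 0.5)
  tr <- panelTruth(p)
  bc <- panelBarcodes(p)[[1]]
  tmpl <- refSeq(refs$A)
  for (i in seq_len(nrow(tr))) {
    read <- as.character(panelReads(p)[[i]])
    if (tr$strand[i] == "-") read <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(read)))
    insert <- if (tr$barcode_lost[i]) read else
      substr(read, nchar(bc) + 1L, nchar(read) - nchar(bc))
    expect_identical(insert,
                     substr(tmpl, tr$template_start[i], tr$template_end[i]))
  }
})

test_that("panels are byte-identical under a fixed seed", {
  refs <- fxRefs()
  g <- vrnA1PanelGenotypes(c("GT3", "GT4"))
  em <- errorModel(chimeraProb = 0.1, barcodeLossProb = 0.1)
  p1 <- simulatePanel(g, refs["A"], 12, em, barcodes = ontLikeBarcodes(2), seed = 77)
  p2 <- simulatePanel(g, refs["A"], 12, em, barcodes = ontLikeBarcodes(2), seed = 77)
  expect_identical(as.character(panelReads(p1)), as.character(panelReads(p2)))
  expect_identical(as.character(panelQuals(p1)), as.character(panelQuals(p2)))
  expect_identical(panelTruth(p1), panelTruth(p2))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writePanelFastq(p1, f1); writePanelFastq(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configured chimera and barcode-loss fractions are recovered", {
  refs <- fxRefs()
  g <- cultivarGenotype("c1", list(templateCopy("A", alleleEdit(), "h", 1)))
  em <- errorModel(chimeraProb = 0.12, barcodeLossProb = 0.25)
  p <- simulatePanel(list(g), refs["A"], 2000, em,
                     barcodes = ontLikeBarcodes(1), seed = 21,
                     fullLengthFrac = 0.05, minReadLen = 500L)
  tr <- panelTruth(p)
  expect_lt(abs(mean(tr$chimera) - 0.12), 0.02)
  expect_lt(abs(mean(tr$barcode_lost) - 0.25), 0.02)
  # read-length support under defaults: within [500, 1.1 x longest template]
  lens <- nchar(as.character(panelReads(p)))
  expect_true(all(lens >= 500))
  expect_true(all(lens <= 1.1 * 2 * (nchar(refSeq(refs$A)) + 48)))
})

test_that("template dosage follows amplification weights (binomial check)", {
  refs <- fxRefs()
  g <- cultivarGenotype("c1", list(
    templateCopy("A", alleleEdit("SNP", 11109L, 1L, "T"), "T1", 1),
    templateCopy("A", alleleEdit("SNP", 11109L, 1L, "T"), "T2", 1),
    templateCopy("A", alleleEdit(), "C1", 1)))
  p <- simulatePanel(list(g), refs["A"], 300, fxErrorFree(),
                     barcodes = ontLikeBarcodes(1), seed = 31)
  tr <- panelTruth(p)
  tFrac <- mean(tr$copy <= 2)
  ci <- binom.test(sum(tr$copy <= 2), nrow(tr), 2 / 3)$conf.int
  expect_true(tFrac > 0.55 && tFrac < 0.78)
  expect_true(ci[1] <= 2 / 3 && 2 / 3 <= ci[2] || abs(tFrac - 2 / 3) < 0.06)
})

test_that("simulatePhenotypes emits 20 traits with null and planted effects", {
  pm <- defaultPhenoModel()
  expect_equal(length(pm@traits), 20L)
  ph <- simulatePhenotypes(c("g1", "g2"), pm, nPerGroup = 40, seed = 4)
  expect_equal(sum(vapply(ph, is.numeric, TRUE)), 20L)
  # null case: group means within 3 standard errors
  for (tr in c("grain_yield", "nri")) {
    m <- tapply(ph[[tr]], ph$group, mean)
    se <- sd(ph[[tr]]) * sqrt(2 / 40)
    expect_lt(abs(diff(m)), 3 * se)
  }
  expect_error(simulatePhenotypes(character(0), pm, nPerGroup = 5), "empty")
})

test_that("a planted yield deficit is detectable with high power", {
  eff <- matrix(0, 1, 20, dimnames = list("SV", defaultPhenoModel()@traits))
  eff["SV", "grain_yield"] <- -9.5   # about -10 percent of the baseline
  pm <- defaultPhenoModel(eff)
  hits <- 0L
  for (r in 1:400) {
    ph <- simulatePhenotypes(c("intact", "SV"), pm, nPerGroup = 20,
                             seed = 1000 + r)
    p <- wilcox.test(grain_yield ~ group, data = ph)$p.value
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 400, 0.8)
})
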