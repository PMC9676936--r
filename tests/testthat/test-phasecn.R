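# Read-backed phasing and the haplotype-count / dosage copy-number
# classifier.

# read-level allele-vector simulator: draws reads from planted copy
# configurations with substitution-style miscalls at the sites
simAlleleMatrix <- function(copies, nReads, subRate = 0.03, seed = 1) {
  set.seed(seed)
  nSites <- length(copies[[1]])
  pick <- sample(length(copies), nReads, replace = TRUE)
  m <- matrix(NA_character_, nReads, nSites)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(nReads)) {
    al <- copies[[pick[r]]]
    err <- runif(nSites) < subRate
    al[err] <- vapply(al[err], function(b) sample(setdiff(bases, b), 1), "")
    m[r, ] <- al
  }
  m
}

test_that("planted haplotype combinations are recovered by phasing", {
  # four combinations over two het sites (the 4-copy configuration)
  four <- list(c("G", "C"), c("G", "T"), c("A", "C"), c("A", "T"))
  m <- simAlleleMatrix(four, 200, seed = 3)
  hs <- phaseHaplotypes(m, c(4138L, 11109L),
                        alleles = list(c("G", "A"), c("C", "T")))
  expect_equal(nHaplotypes(hs), 4L)
  expect_setequal(haplotypeTable(hs)$haplotype,
                  c("G-C", "G-T", "A-C", "A-T"))
  # two combinations
  two <- list(c("G", "C"), c("G", "T"))
  hs2 <- phaseHaplotypes(simAlleleMatrix(two, 200, seed = 4), c(1L, 2L),
                         alleles = list("G", c("C", "T")))
  expect_equal(nHaplotypes(hs2), 2L)
  # homozygous sample: one haplotype
  hs1 <- phaseHaplotypes(simAlleleMatrix(list(c("G", "C")), 100, seed = 5),
                         c(1L, 2L), alleles = list("G", "C"))
  expect_equal(nHaplotypes(hs1), 1L)
})

test_that("phasing without spanning reads is explicitly unphaseable", {
  m <- matrix(c("G", NA, NA, "C"), 2, 2)
  hs <- phaseHaplotypes(m, c(1L, 2L))
  expect_equal(hs@status, "unphaseable")
  expect_equal(nHaplotypes(hs), 0L)
})

test_that("error-free phasing never exceeds the planted haplotype count", {
  for (seed in 1:10) {
    k <- sample(1:4, 1)
    copies <- lapply(seq_len(k), function(i)
      c(c("A", "G")[1 + i %% 2], c("C", "T")[1 + (i %/% 2) %% 2]))
    m <- simAlleleMatrix(copies, 120, subRate = 0, seed = seed)
    hs <- phaseHaplotypes(m, c(1L, 2L))
    expect_lte(nHaplotypes(hs), length(unique(vapply(
      copies, paste, "", collapse = "-"))))
  }
})

test_that("allele dosage recovers a planted 2:1 ratio with a calibrated test", {
  refs <- fxRefs()
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  pC <- which(refCh == "C")[500]
  okFreq <- 0L; okRej <- 0L
  set.seed(11)
  for (r in 1:400) {
    tCount <- rbinom(1, 300, 2 / 3)
    counts <- matrix(0L, nchar(refSeq(refs$A)), 5,
                     dimnames = list(NULL, c("A", "C", "G", "T", "-")))
    counts[pC, ] <- as.integer(c(0, 300 - tCount, 0, tCount, 0))
    pu <- new("Pileup", refId = "A", counts = counts,
              insertions = data.frame(read_id = character(0),
                                      pos = integer(0), seq = character(0)),
              meanQ = NA_real_, nReads = 300L)
    dos <- alleleDosage(pu, pC, "C", "T")
    if (dos$frequency >= 0.60 && dos$frequency <= 0.73) okFreq <- okFreq + 1L
    if (dos$p_value < 0.01) okRej <- okRej + 1L
  }
  expect_gt(okFreq / 400, 0.95)
  expect_gt(okRej / 400, 0.99)
})

test_that("balanced dosage keeps 0.5 inside the confidence interval", {
  refs <- fxRefs()
  counts <- matrix(0L, nchar(refSeq(refs$A)), 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  counts[100, ] <- c(0L, 150L, 0L, 150L, 0L)
  pu <- new("Pileup", refId = "A", counts = counts,
            insertions = data.frame(read_id = character(0),
                                    pos = integer(0), seq = character(0)),
            meanQ = NA_real_, nReads = 300L)
  dos <- alleleDosage(pu, 100L, "C", "T")
  expect_true(dos$ci[1] <= 0.5 && 0.5 <= dos$ci[2])
  # below the depth minimum the dosage is unreliable
  counts[100, ] <- c(0L, 10L, 0L, 10L, 0L)
  puLow <- new("Pileup", refId = "A", counts = counts,
               insertions = data.frame(read_id = character(0),
                                       pos = integer(0), seq = character(0)),
               meanQ = NA_real_, nReads = 20L)
  expect_false(alleleDosage(puLow, 100L, "C", "T")$reliable)
})

test_that("dosage clusters follow the frequency/interval rule", {
  ciAt <- function(x, n) {
    p <- x / n; z <- qnorm(0.975); den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(ctr - hw, ctr + hw)
  }
  expect_equal(dosageCluster(0.70, ciAt(210, 300)), "skewed")
  expect_equal(dosageCluster(0.51, ciAt(153, 300)), "balanced")
  expect_equal(dosageCluster(0.50, ciAt(150, 300)), "balanced")
  expect_equal(dosageCluster(0.30, ciAt(90, 300)), "indeterminate")
  expect_equal(dosageCluster(NA_real_, c(NA, NA)), "indeterminate")
})

test_that("the copy-number rule reproduces the published mapping", {
  hapSet <- function(n, supp = 50L) new(
    "HaplotypeSet", sites = c(1L, 2L),
    haplotypes = data.frame(haplotype = paste0("h", seq_len(n)),
                            support = rep(supp, n)),
    ambiguous = 0L, spanning = as.integer(n * supp + 10L), status = "phased")
  skew <- list(frequency = 0.70, ci = c(0.645, 0.751), p_value = 1e-12)
  bal <- list(frequency = 0.51, ci = c(0.453, 0.567), p_value = 0.76)
  expect_equal(copyNumberValue(copyNumberCall(hapSet(2), skew, "het")), 3L)
  expect_equal(copyNumberValue(copyNumberCall(hapSet(2), bal, "het")), 2L)
  expect_equal(copyNumberValue(copyNumberCall(hapSet(4), bal, "het")), 4L)
  expect_equal(copyNumberValue(copyNumberCall(hapSet(1), NULL, "hom")), 1L)
  # contradiction: flagged, haplotype minimum kept
  contra <- copyNumberCall(hapSet(4), skew, "het")
  expect_equal(copyNumberValue(contra), 4L)
  expect_match(contra@evidence, "contradict")
  # invariant: copy number never below the haplotype count
  for (n in 1:4) for (dos in list(skew, bal, NULL)) {
    cn <- copyNumberCall(hapSet(n), dos,
                         if (n == 1 && is.null(dos)) "hom" else "het")
    expect_gte(copyNumberValue(cn), n)
  }
})
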