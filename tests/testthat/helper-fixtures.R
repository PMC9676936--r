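# Shared fixtures, memoised across test files (helpers are sourced once per
# session). All fixtures are generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# pinned panel references used throughout (identity 0.92, seed 1)
fxRefs <- function() fxMemo("refs", vrnPanelReferences(1))

fxErrorFree <- function() errorModel(0, 0, 0, 1)

# simulate + demux + align one single-copy genotype; memoised by key
fxSvRun <- function(key, hom, edits, nReads = 50, em = fxErrorFree(),
                    seed = 3, fullLengthFrac = 1) {
  fxMemo(key, {
    refs <- fxRefs()
    g <- cultivarGenotype(key, list(templateCopy(hom, edits, "h", 1)))
    p <- simulatePanel(list(g), refs[hom], nReads, em,
                       barcodes = ontLikeBarcodes(1), seed = seed,
                       fullLengthFrac = fullLengthFrac)
    d <- demuxPanel(p)
    aln <- alignPanel(trimmedReads(p, d), refs,
                      sample_ids = rep(key, sum(d$status == "assigned")))
    list(panel = p, demux = d, aln = aln)
  })
}

# brute-force QGRS oracle: enumerate every placement of four equal-length
# all-G tracts by direct position loops (character checks, no cumulative
# tables), score, and select non-overlapping motifs with the same ordering
# rules as the scanner
bruteG4 <- function(seq, minTract = 2, maxLen = 30, maxLoop = maxLen,
                    scoreC = 1) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  isTract <- function(p, x) p >= 1 && p + x - 1 <= n && all(ch[p:(p + x - 1)] == "G")
  cand <- list()
  for (s in seq_len(n)) {
    for (x in minTract:(maxLen %/% 4)) {
      if (!isTract(s, x)) next
      lastStart <- min(n - x + 1, s + maxLen - x)
      if (s + x > lastStart) next
      for (p2 in (s + x):lastStart) {
        if (p2 - s - x > maxLoop || !isTract(p2, x)) next
        if (p2 + x > lastStart) next
        for (p3 in (p2 + x):lastStart) {
          if (p3 - p2 - x > maxLoop || !isTract(p3, x)) next
          if (p3 + x > lastStart) next
          for (p4 in (p3 + x):lastStart) {
            if (p4 - p3 - x > maxLoop) next
            if (p4 + x - 1 - s + 1 > maxLen) next
            if (!isTract(p4, x)) next
            loops <- c(p2 - s - x, p3 - p2 - x, p4 - p3 - x)
            cand[[length(cand) + 1L]] <-
              data.frame(start = s, end = p4 + x - 1, tract = x,
                         loop1 = loops[1], loop2 = loops[2],
                         loop3 = loops[3],
                         score = scoreC * (maxLen - mean(loops)) +
                           2 * (x - minTract))
          }
        }
      }
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      tract = integer(0), loop1 = integer(0),
                      loop2 = integer(0), loop3 = integer(0),
                      score = numeric(0)))
  df <- unique(do.call(rbind, cand))
  o <- order(-df$score, df$start, -df$tract, df$end - df$start)
  sel <- logical(nrow(df))
  covered <- rep(FALSE, n)
  for (i in o) {
    span <- df$start[i]:df$end[i]
    if (!any(covered[span])) { sel[i] <- TRUE; covered[span] <- TRUE }
  }
  out <- df[sel, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$score, out$start), , drop = FALSE]
}

# random DNA string
rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
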