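# G-quadruplex (QGRS) motif scanning on the sense strand. A motif is four
# equal-length G-tracts (tract length >= minTract) separated by three
# loops, with a total span of at most maxLen. The score favours short
# motifs with even loops and long tracts:
#   score = scoreC * (maxLen - mean loop length) + 2 * (tract - minTract)
# Non-overlapping motifs are selected greedily by descending score, ties
# by leftmost start, longer tract, then shorter span.

#' Find G-quadruplex (QGRS) motifs
#'
#' Enumerates every placement of four equal-length G-tracts within windows
#' of at most \code{maxLen} bases, scores each candidate, and greedily
#' selects non-overlapping motifs in descending score order.
#'
#' @param seq uppercase nucleotide sequence
#' @param minTract minimum G-tract length (default 2)
#' @param maxLen maximum motif span (default 30)
#' @param maxLoop maximum loop length (default \code{maxLen}, i.e. bounded
#'   by the window); loops of length 0 are allowed
#' @param scoreC loop-evenness score constant (default 1)
#' @param revStrand also scan the reverse strand (off by default; the
#'   workflow scans the sense strand)
#' @return data.frame: start, end (1-based inclusive), tract, loop1-3,
#'   score, sequence, strand; best scoring first
#' @export
findG4 <- function(seq, minTract = 2L, maxLen = 30L, maxLoop = maxLen,
                   scoreC = 1, revStrand = FALSE) {
  res <- .findG4OneStrand(seq, minTract, maxLen, maxLoop, scoreC)
  if (nrow(res)) res$strand <- "+"
  if (revStrand) {
    n <- nchar(seq)
    rc <- .findG4OneStrand(revComp(seq), minTract, maxLen, maxLoop, scoreC)
    if (nrow(rc)) {
      tmp <- rc
      rc$start <- n - tmp$end + 1L
      rc$end <- n - tmp$start + 1L
      rc$strand <- "-"
      res <- rbind(res, rc)
    }
  }
  res[order(-res$score, res$start), , drop = FALSE]
}

.emptyG4 <- function() {
  data.frame(start = integer(0), end = integer(0), tract = integer(0),
             loop1 = integer(0), loop2 = integer(0), loop3 = integer(0),
             score = numeric(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

.findG4OneStrand <- function(seq, minTract, maxLen, maxLoop, scoreC) {
  ch <- seqChars(seq)
  n <- length(ch)
  isG <- ch == "G"
  if (n < 4 * minTract) return(.emptyG4())
  cg <- cumsum(isG)
  allG <- function(p, x) cg[p + x - 1L] - (if (p > 1) cg[p - 1L] else 0L) == x
  runs <- rle(isG)
  maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  maxX <- min(maxRun, maxLen %/% 4L)
  cand <- list()
  for (x in seq.int(minTract, length.out = max(0L, maxX - minTract + 1L))) {
    Tx <- which(vapply(seq_len(n - x + 1L), allG, TRUE, x = x))
    if (length(Tx) < 4) next
    for (p1 in Tx) {
      hi <- p1 + maxLen - x  # last allowed tract start
      t4s <- Tx[Tx >= p1 + 3L * x & Tx <= hi]
      if (!length(t4s)) next
      t2s <- Tx[Tx >= p1 + x & Tx <= hi - 2L * x]
      for (p2 in t2s) {
        if (p2 - (p1 + x) > maxLoop) next
        t3s <- Tx[Tx >= p2 + x & Tx <= hi - x]
        for (p3 in t3s) {
          if (p3 - (p2 + x) > maxLoop) next
          for (p4 in t4s[t4s >= p3 + x]) {
            if (p4 - (p3 + x) > maxLoop) next
            l <- c(p2 - (p1 + x), p3 - (p2 + x), p4 - (p3 + x))
            cand[[length(cand) + 1L]] <- c(p1, p4 + x - 1L, x, l)
          }
        }
      }
    }
  }
  if (!length(cand)) return(.emptyG4())
  m <- do.call(rbind, cand)
  df <- data.frame(start = m[, 1], end = m[, 2], tract = m[, 3],
                   loop1 = m[, 4], loop2 = m[, 5], loop3 = m[, 6])
  df$score <- scoreC * (maxLen - rowMeans(m[, 4:6, drop = FALSE])) +
    2 * (df$tract - minTract)
  # greedy non-overlapping selection
  o <- order(-df$score, df$start, -df$tract, df$end - df$start)
  sel <- logical(nrow(df))
  covered <- rep(FALSE, n)
  for (i in o) {
    span <- df$start[i]:df$end[i]
    if (!any(covered[span])) { sel[i] <- TRUE; covered[span] <- TRUE }
  }
  out <- df[sel, , drop = FALSE]
  out$sequence <- substr(rep(paste(ch, collapse = ""), nrow(out)),
                         out$start, out$end)
  out[order(-out$score, out$start), , drop = FALSE]
}

#' Variant impact on G-quadruplex motifs
#'
#' Computes motifs on the reference and on the variant-applied sequence,
#' and annotates each variant with the overlapping reference motif (if
#' any) and the motif score change. A motif overlapped by a deletion that
#' removes it entirely is reported lost.
#'
#' @param ref reference sequence (character) or
#'   \linkS4class{HomoeologReference}
#' @param edits allele-edit data frame (see \code{\link{alleleEdit}})
#' @param ... passed to \code{\link{findG4}}
#' @return data.frame: one row per variant with kind, position, overlapping
#'   motif coordinates (NA when none), ref and alt scores, score_delta and
#'   impact ("none", "unchanged", "changed", "lost")
#' @export
variantG4Report <- function(ref, edits, ...) {
  refStr <- if (is(ref, "HomoeologReference")) refSeq(ref) else ref
  altStr <- applyAllele(refStr, edits)
  mr <- findG4(refStr, ...)
  ma <- findG4(altStr, ...)
  rows <- list()
  for (i in seq_len(nrow(edits))) {
    k <- edits$kind[i]; p <- edits$position[i]; l <- edits$length[i]
    lo <- p
    hi <- if (k == "DEL") p + l - 1L else p
    ov <- which(mr$start <= hi & mr$end >= lo)
    if (!length(ov)) {
      rows[[i]] <- data.frame(kind = k, position = p,
                              motif_start = NA_integer_, motif_end = NA_integer_,
                              ref_score = NA_real_, alt_score = NA_real_,
                              score_delta = 0, impact = "none",
                              stringsAsFactors = FALSE)
      next
    }
    j <- ov[which.max(mr$score[ov])]
    # map the motif interval into alt coordinates and look for a motif there
    aLo <- mapThroughEdits(mr$start[j], edits)
    aHi <- mapThroughEdits(mr$end[j], edits)
    am <- which(ma$start <= aHi & ma$end >= aLo)
    altScore <- if (length(am)) max(ma$score[am]) else NA_real_
    delta <- (if (is.na(altScore)) 0 else altScore) - mr$score[j]
    impact <- if (!length(am)) "lost" else if (delta != 0) "changed"
              else "unchanged"
    rows[[i]] <- data.frame(kind = k, position = p,
                            motif_start = mr$start[j], motif_end = mr$end[j],
                            ref_score = mr$score[j], alt_score = altScore,
                            score_delta = delta, impact = impact,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
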