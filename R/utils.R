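# Internal sequence helpers. Sequences are plain uppercase character strings
# at module boundaries; Biostrings objects are used at I/O boundaries.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revComp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(seqChars(x)), collapse = ""))
}

#' @noRd
checkSeq <- function(x) {
  grepl("^[ACGT]+$", x)
}

# 1-based inclusive <-> internal arithmetic happens in the callers; all
# user-facing positions are 1-based counted from the amplicon start (the
# 3' end of the forward primer).

# positions (1-based) of bases sitting in or immediately adjacent to a
# single-base run of length >= runLen
homopolymerMask <- function(seq, runLen = 4L) {
  ch <- seqChars(seq)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= runLen
  if (!any(keep)) return(integer(0))
  lo <- pmax(starts[keep] - 1L, 1L)
  hi <- pmin(ends[keep] + 1L, length(ch))
  unique(unlist(Map(seq.int, lo, hi), use.names = FALSE))
}

# map a 1-based reference position through a sorted edit table to the
# coordinate system of the edited sequence; positions inside deletions map
# to the base preceding the deletion
mapThroughEdits <- function(pos, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(pos)
  out <- pos
  for (i in seq_len(nrow(edits))) {
    k <- edits$kind[i]; p <- edits$position[i]; l <- edits$length[i]
    if (k == "SNP") next
    if (k == "INS" || k == "DUP") {
      ins <- if (k == "INS") nchar(edits$alt[i]) else l
      out <- ifelse(pos > p, out + ins, out)
    } else if (k == "DEL") {
      out <- ifelse(pos >= p + l, out - l, ifelse(pos >= p, p - 1L, out))
    }
  }
  out
}

wilsonCI <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

phredQual <- function(count, depth, errRate) {
  p <- pbinom(count - 1, depth, errRate, lower.tail = FALSE)
  q <- -10 * log10(pmax(p, 1e-12))
  pmin(q, 120)
}
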