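# Barcode demultiplexing with chimera detection and read-level filtering.
# Barcodes are matched by banded edit distance (pigeonhole-seeded scan in
# the compiled core); a qualifying hit inside the end windows assigns the
# read, a qualifying hit outside them marks a fusion (chimera), and
# conflicting barcodes at the two ends also mark a chimera.

#' Mean Phred quality of a read
#'
#' Per-base error probabilities are averaged before the log transform:
#' \eqn{-10 \log_{10}(\mathrm{mean}(10^{-q/10}))}. Appending low-quality
#' bases therefore always decreases the mean Q.
#'
#' @param q integer vector of per-base Phred scores
#' @return mean Q (numeric)
#' @export
meanQscore <- function(q) {
  if (length(q) == 0) stop("empty quality vector")
  -10 * log10(mean(10^(-q / 10)))
}

#' Classify one read against a barcode set
#'
#' All barcodes (both orientations) are scanned across the read allowing up
#' to \code{barcode_max_mismatch} edits. Hits starting within
#' \code{end_window} bases of either read end are terminal; any qualifying
#' hit outside the end windows marks the read chimeric (barcode in the
#' middle of the read), as do conflicting barcodes at the two ends. A read
#' without a qualifying hit is unclassified. Terminal ties break on the
#' fewest edits, then the lowest sample index.
#'
#' @param read read sequence (character)
#' @param barcodes named character vector (sample -> barcode, equal widths)
#' @param params a \linkS4class{PipelineParams}
#' @return list: status ("assigned", "chimeric", "unclassified"),
#'   sample_id, edits
#' @export
classifyBarcode <- function(read, barcodes, params = pipelineParams()) {
  if (length(barcodes) == 0) stop("empty barcode set")
  maxMM <- param(params, "barcode_max_mismatch")
  win <- param(params, "end_window")
  n <- nchar(read)
  blen <- nchar(barcodes[1])
  hits <- list()
  for (i in seq_along(barcodes)) {
    for (orient in 1:2) {
      pat <- if (orient == 1) barcodes[[i]] else revComp(barcodes[[i]])
      h <- cpp_scan_barcode(read, pat, maxMM)
      if (nrow(h)) hits[[length(hits) + 1L]] <- data.frame(
        sample = i, start = h[, "start"], edits = h[, "edits"])
    }
  }
  if (!length(hits)) return(list(status = "unclassified",
                                 sample_id = NA_character_, edits = NA_integer_))
  hits <- do.call(rbind, hits)
  terminal <- hits$start <= win | (hits$start + blen - 1L) >= (n - win + 1L)
  if (any(!terminal)) return(list(status = "chimeric",
                                  sample_id = NA_character_, edits = NA_integer_))
  headSamp <- unique(hits$sample[hits$start <= win])
  tailSamp <- unique(hits$sample[(hits$start + blen - 1L) >= (n - win + 1L)])
  if (length(headSamp) && length(tailSamp) &&
      length(intersect(headSamp, tailSamp)) == 0)
    return(list(status = "chimeric", sample_id = NA_character_,
                edits = NA_integer_))
  o <- order(hits$edits, hits$sample)
  best <- hits[o[1], ]
  # barcode-trimmed insert coordinates (terminal hits removed)
  headHits <- hits[hits$start <= win, , drop = FALSE]
  tailHits <- hits[(hits$start + blen - 1L) >= (n - win + 1L), , drop = FALSE]
  trimFrom <- if (nrow(headHits)) max(headHits$start + blen) else 1L
  trimTo <- if (nrow(tailHits)) min(tailHits$start) - 1L else n
  list(status = "assigned",
       sample_id = if (!is.null(names(barcodes))) names(barcodes)[best$sample]
                   else as.character(best$sample),
       edits = best$edits,
       trim_start = max(1L, trimFrom), trim_end = min(n, max(trimTo, 1L)))
}

#' Length/quality read filter
#'
#' A read passes when its length is within [min_read_len, max_read_len]
#' (defaults 2000 and 16000, inclusive) and its mean Q is at least
#' \code{min_q} (default 8). The first violated reason is reported in the
#' order length_short, length_long, low_quality.
#'
#' @param len read length
#' @param meanQ mean Phred quality (see \code{\link{meanQscore}})
#' @param params a \linkS4class{PipelineParams}
#' @return list: pass (logical), reason ("none" when passing)
#' @export
filterRead <- function(len, meanQ, params = pipelineParams()) {
  if (len < param(params, "min_read_len"))
    return(list(pass = FALSE, reason = "length_short"))
  if (len > param(params, "max_read_len"))
    return(list(pass = FALSE, reason = "length_long"))
  if (meanQ < param(params, "min_q"))
    return(list(pass = FALSE, reason = "low_quality"))
  list(pass = TRUE, reason = "none")
}

#' Demultiplex a read panel
#'
#' Applies \code{\link{classifyBarcode}} to every read and the length/
#' quality filter to assigned reads. Every read receives exactly one
#' terminal status: assigned, unclassified, chimeric or filtered.
#'
#' @param panel a \linkS4class{SimPanel}, or a named character vector of
#'   reads (then \code{quals} may supply Phred+33 strings)
#' @param barcodes named character vector (defaults to the panel's)
#' @param params a \linkS4class{PipelineParams}
#' @param quals optional quality strings when \code{panel} is a vector
#' @return data.frame: read_id, status, sample_id, filter_reason, mean_q
#' @export
demuxPanel <- function(panel, barcodes = NULL, params = pipelineParams(),
                       quals = NULL) {
  if (is(panel, "SimPanel")) {
    reads <- as.character(panelReads(panel))
    quals <- as.character(panelQuals(panel))
    names(quals) <- names(reads)
    if (is.null(barcodes)) barcodes <- panelBarcodes(panel)
  } else {
    reads <- panel
  }
  if (is.null(barcodes)) stop("barcodes required")
  n <- length(reads)
  status <- character(n); sample_id <- rep(NA_character_, n)
  reason <- rep("none", n); mq <- rep(NA_real_, n)
  trimS <- rep(NA_integer_, n); trimE <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cb <- classifyBarcode(reads[[i]], barcodes, params)
    status[i] <- cb$status
    if (!is.null(quals))
      mq[i] <- meanQscore(utf8ToInt(quals[[i]]) - 33L)
    if (cb$status == "assigned") {
      sample_id[i] <- cb$sample_id
      trimS[i] <- cb$trim_start; trimE[i] <- cb$trim_end
      f <- filterRead(nchar(reads[[i]]),
                      if (is.na(mq[i])) Inf else mq[i], params)
      if (!f$pass) {
        status[i] <- "filtered"; reason[i] <- f$reason
        sample_id[i] <- NA_character_
      }
    }
  }
  data.frame(read_id = names(reads), status = status, sample_id = sample_id,
             filter_reason = reason, mean_q = mq,
             trim_start = trimS, trim_end = trimE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Barcode-trimmed sequences of assigned reads
#'
#' @param panel a \linkS4class{SimPanel} or named character vector of reads
#' @param dmx classification table from \code{\link{demuxPanel}}
#' @return named character vector of trimmed reads (assigned reads only)
#' @export
trimmedReads <- function(panel, dmx) {
  reads <- if (is(panel, "SimPanel")) as.character(panelReads(panel)) else panel
  keep <- which(dmx$status == "assigned")
  out <- substr(reads[keep], dmx$trim_start[keep], dmx$trim_end[keep])
  names(out) <- dmx$read_id[keep]
  out
}
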