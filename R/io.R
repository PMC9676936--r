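# Standard-format I/O: FASTQ/FASTA via Biostrings, VCF 4.2 and BED writers,
# plain TSV tables.

#' Write panel reads as FASTQ (Phred+33)
#'
#' Records are written directly (4-line records, unwrapped). Chimeric
#' long-amplicon reads exceed the per-record length that the Biostrings
#' FASTQ writer supports, so the writer is plain text by design.
#'
#' @param panel a \linkS4class{SimPanel}
#' @param path output file
#' @export
writePanelFastq <- function(panel, path) {
  reads <- as.character(panelReads(panel))
  quals <- as.character(panelQuals(panel))
  ids <- names(panelReads(panel))
  out <- character(4L * length(reads))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- reads
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into reads plus quality strings
#'
#' Expects unwrapped 4-line records (as written by
#' \code{\link{writePanelFastq}} and typical basecaller output).
#'
#' @param path FASTQ file
#' @return list: reads (named character), quals (named character, Phred+33)
#' @export
readFastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4 != 0) stop("truncated FASTQ (expect 4-line records)")
  ids <- sub("^@", "", sub("\\s.*$", "", x[seq(1, length(x), 4)]))
  reads <- x[seq(2, length(x), 4)]
  quals <- x[seq(4, length(x), 4)]
  names(reads) <- ids
  names(quals) <- ids
  list(reads = reads, quals = quals)
}

#' Write references as FASTA
#'
#' @param refs named list of \linkS4class{HomoeologReference}
#' @param path output file
#' @export
writeRefsFasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(vapply(refs, refSeq, ""))
  names(x) <- vapply(refs, refId, "")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' SV calls carry SVTYPE/SVLEN/END/SUPPORT INFO fields; small-variant
#' calls carry DP/AC and the original filter flag. Deletion alleles are
#' emitted with the anchor-base convention.
#'
#' @param calls SV or small-variant call data.frame
#' @param refs named list of \linkS4class{HomoeologReference} (for anchor
#'   bases and contig headers)
#' @param path output file
#' @param type "sv" or "snp"
#' @export
writeVcf <- function(calls, refs, path, type = c("sv", "snp")) {
  type <- match.arg(type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=homeoplex",
               vapply(refs, function(r) sprintf("##contig=<ID=%s,length=%d>",
                                                refId(r), nchar(refSeq(r))),
                      "")), con)
  if (type == "sv") {
    writeLines(c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
      '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
      '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Supporting reads">'),
      con)
  } else {
    writeLines(c(
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
      '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alt count">'), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (!nrow(calls)) return(invisible(path))
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    refSeqStr <- refSeq(refs[[r$ref_id]])
    if (type == "sv") {
      anchor <- substr(refSeqStr, r$position, r$position)
      endPos <- if (r$type == "DEL") r$position + r$length - 1L else r$position
      alt <- paste0("<", r$type, ">")
      svlen <- if (r$type == "DEL") -r$length else r$length
      info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPPORT=%d",
                      r$type, svlen, endPos, r$support)
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                         r$ref_id, r$position, anchor, alt, info), con)
    } else {
      if (r$alt == "-") {
        # single-base deletion: anchor-base representation
        pos <- r$position - 1L
        refA <- substr(refSeqStr, pos, r$position)
        altA <- substr(refSeqStr, pos, pos)
      } else {
        pos <- r$position; refA <- r$ref; altA <- r$alt
      }
      filt <- if (r$filter == "pass") "PASS" else r$filter
      info <- sprintf("DP=%d;AC=%d", r$depth, r$alt_count)
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\t%s\t%s",
                         r$ref_id, pos, refA, altA, r$quality, filt, info),
                 con)
    }
  }
  invisible(path)
}

#' Write G4 motifs as BED (0-based half-open) plus a score TSV
#'
#' @param motifs data.frame from \code{\link{findG4}}
#' @param chrom sequence name
#' @param path BED output file
#' @export
writeG4Bed <- function(motifs, chrom, path) {
  if (nrow(motifs)) {
    bed <- data.frame(chrom = chrom, start = motifs$start - 1L,
                      end = motifs$end, name = sprintf("G4_%d", seq_len(nrow(motifs))),
                      score = round(motifs$score, 1),
                      strand = if ("strand" %in% names(motifs)) motifs$strand
                               else "+")
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(path)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame
#' @param path output file
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
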