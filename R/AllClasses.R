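#' Homoeolog reference sequence with feature annotation
#'
#' Container for one synthetic (or real) homoeolog amplicon reference:
#' promoter plus full gene body, with a named feature map (promoter, exons,
#' introns) tiling the sequence. Positions are 1-based and counted from the
#' amplicon start, i.e. the 3' end of the forward primer.
#'
#' @slot id single character label (e.g. "A", "B", "D")
#' @slot seq uppercase A/C/G/T sequence
#' @slot promoterLen promoter length in bases (700 by default upstream of the
#'   gene body)
#' @slot features named \link[IRanges]{IRanges} tiling the sequence
#' @export
setClass("HomoeologReference",
  representation(id = "character", seq = "character",
                 promoterLen = "integer", features = "ANY"))

setValidity("HomoeologReference", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L) msg <- c(msg, "id must be length 1")
  if (!checkSeq(object@seq)) msg <- c(msg, "sequence must be uppercase A/C/G/T")
  if (nchar(object@seq) < object@promoterLen + 10000L)
    msg <- c(msg, "sequence must be at least promoterLen + 10000 bases")
  f <- object@features
  if (!is(f, "IRanges")) {
    msg <- c(msg, "features must be an IRanges")
  } else {
    o <- order(IRanges::start(f))
    s <- IRanges::start(f)[o]; e <- IRanges::end(f)[o]
    if (s[1] != 1L || e[length(e)] != nchar(object@seq) ||
        (length(s) > 1 && any(s[-1] != e[-length(e)] + 1L)))
      msg <- c(msg, "features must tile the sequence without gaps or overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HomoeologReference construct a reference
#' @param id,seq,promoterLen,features slot values
#' @export
homoeologReference <- function(id, seq, promoterLen = 700L, features = NULL) {
  if (is.null(features)) features <- buildFeatureMap(promoterLen, nchar(seq) - promoterLen)
  new("HomoeologReference", id = as.character(id), seq = toupper(seq),
      promoterLen = as.integer(promoterLen), features = features)
}

#' @describeIn HomoeologReference reference label
#' @param x a HomoeologReference
#' @export
refId <- function(x) x@id

#' @describeIn HomoeologReference reference sequence as a character string
#' @export
refSeq <- function(x) x@seq

#' @describeIn HomoeologReference named feature ranges
#' @export
featureMap <- function(x) x@features

#' @describeIn HomoeologReference promoter length in bases
#' @export
promoterLen <- function(x) x@promoterLen

setMethod("show", "HomoeologReference", function(object) {
  cat("HomoeologReference", object@id, "-", nchar(object@seq), "bp,",
      "promoter", object@promoterLen, "bp,",
      length(object@features), "features\n")
})

#' Per-base error model for ONT-like read simulation
#'
#' Substitution, insertion and deletion rates are per base; indel rates are
#' multiplied by \code{hpMult} inside single-base runs of length >=
#' \code{hpRun} (nanopore homopolymer error inflation). Chimera probability is
#' the fraction of reads formed by fusing two barcoded molecules;
#' barcode-loss probability is the fraction of molecules emitted without any
#' barcode. Per-base qualities are emitted from the local error rate with
#' Gaussian per-read and per-base jitter.
#'
#' @slot sub,ins,del per-base rates, each in [0, 0.2]
#' @slot hpMult homopolymer indel multiplier (>= 1)
#' @slot hpRun run length at which the multiplier applies
#' @slot chimeraProb,barcodeLossProb probabilities in [0, 1]
#' @slot qualSd,qualReadSd per-base and per-read quality jitter (Phred units)
#' @export
setClass("ErrorModel",
  representation(sub = "numeric", ins = "numeric", del = "numeric",
                 hpMult = "numeric", hpRun = "integer",
                 chimeraProb = "numeric", barcodeLossProb = "numeric",
                 qualSd = "numeric", qualReadSd = "numeric"))

setValidity("ErrorModel", function(object) {
  msg <- character(0)
  for (s in c("sub", "ins", "del")) {
    v <- slot(object, s)
    if (v < 0 || v > 0.2) msg <- c(msg, paste(s, "rate must be in [0, 0.2]"))
  }
  if (object@hpMult < 1) msg <- c(msg, "hpMult must be >= 1")
  for (s in c("chimeraProb", "barcodeLossProb")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ErrorModel construct an error model; defaults approximate
#'   R9.4.1-era ONT accuracy
#' @param sub,ins,del,hpMult,hpRun,chimeraProb,barcodeLossProb,qualSd,qualReadSd
#'   slot values
#' @export
errorModel <- function(sub = 0.03, ins = 0.02, del = 0.04, hpMult = 3,
                       hpRun = 4L, chimeraProb = 0, barcodeLossProb = 0,
                       qualSd = 3, qualReadSd = 2) {
  new("ErrorModel", sub = sub, ins = ins, del = del, hpMult = hpMult,
      hpRun = as.integer(hpRun), chimeraProb = chimeraProb,
      barcodeLossProb = barcodeLossProb, qualSd = qualSd,
      qualReadSd = qualReadSd)
}

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel sub=%.3f ins=%.3f del=%.3f hpMult=%g chimera=%.3f bcLoss=%.3f\n",
    object@sub, object@ins, object@del, object@hpMult, object@chimeraProb,
    object@barcodeLossProb))
})

#' Cultivar genotype: template copies per homoeolog
#'
#' Each copy carries an allele-edit table (relative to the homoeolog
#' reference), a haplotype label and a relative amplification weight. The
#' number of reads simulated from each copy is proportional to its weight.
#'
#' @slot cultivar sample label
#' @slot copies list of lists with elements \code{homoeolog}, \code{edits}
#'   (an allele-edit data frame), \code{haplotype}, \code{weight}
#' @export
setClass("CultivarGenotype",
  representation(cultivar = "character", copies = "list"))

setValidity("CultivarGenotype", function(object) {
  msg <- character(0)
  if (length(object@copies) < 1) msg <- c(msg, "at least one template copy required")
  for (cp in object@copies) {
    if (!all(c("homoeolog", "edits", "haplotype", "weight") %in% names(cp)))
      msg <- c(msg, "each copy needs homoeolog, edits, haplotype, weight")
    else if (!is.finite(cp$weight) || cp$weight < 0)
      msg <- c(msg, "weights must be finite and >= 0")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn CultivarGenotype construct a genotype
#' @param cultivar,copies slot values
#' @export
cultivarGenotype <- function(cultivar, copies) {
  new("CultivarGenotype", cultivar = cultivar, copies = copies)
}

#' @describeIn CultivarGenotype one template copy descriptor
#' @param homoeolog reference id the copy belongs to
#' @param edits allele-edit data frame (see \code{\link{alleleEdit}})
#' @param haplotype haplotype label
#' @param weight relative amplification weight (>= 0)
#' @export
templateCopy <- function(homoeolog, edits = alleleEdit(), haplotype = "hap1",
                         weight = 1) {
  list(homoeolog = homoeolog, edits = edits, haplotype = haplotype,
       weight = weight)
}

setMethod("show", "CultivarGenotype", function(object) {
  h <- vapply(object@copies, function(cp) cp$homoeolog, "")
  cat("CultivarGenotype", object@cultivar, "-", length(object@copies),
      "copies (", paste(sort(unique(h)), collapse = "/"), ")\n")
})

#' Phenotype simulation model
#'
#' Trait values are simulated as baseline + group effect + Gaussian noise.
#'
#' @slot traits trait names
#' @slot baseline per-trait baseline means
#' @slot sd per-trait standard deviations (> 0)
#' @slot effects matrix of additive group effects (groups x traits); missing
#'   groups have zero effect
#' @export
setClass("PhenoModel",
  representation(traits = "character", baseline = "numeric", sd = "numeric",
                 effects = "matrix"))

setValidity("PhenoModel", function(object) {
  msg <- character(0)
  n <- length(object@traits)
  if (length(object@baseline) != n || length(object@sd) != n)
    msg <- c(msg, "baseline and sd must match trait count")
  if (any(object@sd <= 0)) msg <- c(msg, "trait SDs must be > 0")
  if (ncol(object@effects) > 0 && ncol(object@effects) != n)
    msg <- c(msg, "effects columns must match traits")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhenoModel", function(object) {
  cat("PhenoModel -", length(object@traits), "traits,",
      nrow(object@effects), "group effect rows\n")
})

#' Simulated read panel with ground truth
#'
#' Reads are held as a \link[Biostrings]{DNAStringSet} with parallel Phred
#' quality strings and a truth table recording, per read: cultivar,
#' homoeolog, template copy, haplotype, chimera flag, barcode-loss flag and
#' strand.
#'
#' @slot reads DNAStringSet of reads
#' @slot quals BStringSet of Phred+33 quality strings
#' @slot truth data.frame of per-read ground truth
#' @slot barcodes named character vector (cultivar -> barcode)
#' @export
setClass("SimPanel",
  representation(reads = "ANY", quals = "ANY", truth = "data.frame",
                 barcodes = "character"))

setValidity("SimPanel", function(object) {
  msg <- character(0)
  if (length(object@reads) != nrow(object@truth))
    msg <- c(msg, "truth table must have one row per read")
  if (length(object@reads) != length(object@quals))
    msg <- c(msg, "qualities must parallel reads")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimPanel", function(object) {
  cat("SimPanel -", length(object@reads), "reads,",
      length(unique(object@truth$cultivar)), "cultivars,",
      sum(object@truth$chimera), "chimeric\n")
})

#' @describeIn SimPanel read sequences
#' @param x a SimPanel
#' @export
panelReads <- function(x) x@reads

#' @describeIn SimPanel Phred+33 quality strings
#' @export
panelQuals <- function(x) x@quals

#' @describeIn SimPanel ground-truth table
#' @export
panelTruth <- function(x) x@truth

#' @describeIn SimPanel cultivar barcodes
#' @export
panelBarcodes <- function(x) x@barcodes

#' Set of read-to-reference alignments
#'
#' Produced by \code{\link{alignPanel}}. Holds a per-read summary table
#' (reference, span, identity, aligned fraction, assignment status, score)
#' plus the run-length edit operations and the reference-oriented read
#' sequence needed by the pileup, SV and phasing modules.
#'
#' @slot summary per-read alignment summary data.frame
#' @slot ops list of two-column matrices (op code, run length)
#' @slot seqs reference-oriented read sequences
#' @export
setClass("AlignmentSet",
  representation(summary = "data.frame", ops = "list", seqs = "character"))

setMethod("show", "AlignmentSet", function(object) {
  s <- object@summary
  cat("AlignmentSet -", nrow(s), "reads;",
      sum(s$assignment == "unique"), "unique,",
      sum(s$assignment == "ambiguous"), "ambiguous,",
      sum(s$assignment == "unaligned"), "unaligned\n")
})

#' @describeIn AlignmentSet per-read summary table
#' @param x an AlignmentSet
#' @export
alignmentSummary <- function(x) x@summary

#' @describeIn AlignmentSet run-length edit operations per read
#' @export
alignmentOps <- function(x) x@ops

#' Phased haplotype set over heterozygous sites
#'
#' @slot sites ordered heterozygous site positions
#' @slot haplotypes data.frame: one row per haplotype with its allele vector
#'   (collapsed string) and supporting-read count
#' @slot ambiguous number of spanning reads with a non-called allele
#' @slot spanning number of reads covering all sites
#' @slot status "phased" or "unphaseable"
#' @export
setClass("HaplotypeSet",
  representation(sites = "integer", haplotypes = "data.frame",
                 ambiguous = "integer", spanning = "integer",
                 status = "character"))

setValidity("HaplotypeSet", function(object) {
  msg <- character(0)
  if (nrow(object@haplotypes) &&
      sum(object@haplotypes$support) + object@ambiguous > object@spanning)
    msg <- c(msg, "support + ambiguous cannot exceed spanning reads")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet -", nrow(object@haplotypes), "haplotypes over",
      length(object@sites), "sites (", object@status, ");",
      object@ambiguous, "ambiguous reads\n")
})

#' @describeIn HaplotypeSet number of distinct haplotypes (the minimum copy
#'   number)
#' @param x a HaplotypeSet
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)

#' @describeIn HaplotypeSet haplotype table
#' @export
haplotypeTable <- function(x) x@haplotypes

#' Copy-number estimate from haplotype count and allele dosage
#'
#' Combines the minimum copy number implied by the number of phased
#' haplotypes with the allele-dosage frequency at a diagnostic heterozygous
#' site and its dosage cluster (balanced vs skewed), mirroring combined
#' haplotype/KASP-cluster copy-number reasoning.
#'
#' @slot nHaplotypes number of phased haplotypes
#' @slot dosageSite diagnostic site position (NA when unavailable)
#' @slot frequency alt-allele read frequency at the dosage site
#' @slot ci Wilson 95\% confidence interval for the frequency
#' @slot cluster "balanced", "skewed" or "indeterminate"
#' @slot copyNumber integer copy number (>= nHaplotypes)
#' @slot evidence human-readable evidence string
#' @export
setClass("CopyNumberEstimate",
  representation(nHaplotypes = "integer", dosageSite = "integer",
                 frequency = "numeric", ci = "numeric", cluster = "character",
                 copyNumber = "integer", evidence = "character"))

setValidity("CopyNumberEstimate", function(object) {
  if (object@copyNumber < object@nHaplotypes)
    "copy number cannot be below the haplotype count" else TRUE
})

setMethod("show", "CopyNumberEstimate", function(object) {
  cat(sprintf("CopyNumberEstimate: %d copies (%d haplotypes, cluster %s)\n  %s\n",
              object@copyNumber, object@nHaplotypes, object@cluster,
              object@evidence))
})

#' @describeIn CopyNumberEstimate estimated integer copy number
#' @param x a CopyNumberEstimate
#' @export
copyNumberValue <- function(x) x@copyNumber

#' Pipeline parameters: all analysis thresholds in one object
#'
#' Defaults follow the amplicon analysis workflow: read-level filters
#' (length 2000-16000, mean Q >= 8), homoeolog assignment (identity >= 0.80,
#' aligned fraction >= 0.50, uniqueness margin 50 score units), SV calling
#' (>= 30 bp, >= 10 supporting reads, merge window 500), SNP calling (minor
#' count >= 3, site quality >= 30, homopolymer run 4, minimum depth 11) and
#' grouping/association settings (sequence-type identity 0.99, alpha 0.05).
#'
#' @slot values named list of parameters
#' @export
setClass("PipelineParams", representation(values = "list"))

.paramDefaults <- list(
  min_read_len = 2000L, max_read_len = 16000L, min_q = 8,
  barcode_max_mismatch = 3L, end_window = 150L,
  min_identity = 0.80, min_aligned_fraction = 0.50, uniq_margin = 50,
  sv_min_len = 30L, sv_min_support = 10L, sv_cluster_window = 100L,
  sv_merge_window = 500L,
  snp_min_count = 3L, snp_min_qual = 30, snp_het_freq = 0.20,
  snp_del_min_freq = 0.45, snp_err_rate = 0.05, homopolymer_run = 4L,
  consensus_min_reads = 3L, low_coverage = 11,
  dosage_min_depth = 30L, hap_min_support = 10L,
  seqtype_identity = 0.99, alpha = 0.05,
  aln_match = 2, aln_mismatch = 4, aln_gap_open = 4, aln_gap_ext = 2,
  aln_k = 15L, aln_max_dp = 4e6)

setValidity("PipelineParams", function(object) {
  v <- object@values
  msg <- character(0)
  miss <- setdiff(names(.paramDefaults), names(v))
  if (length(miss)) msg <- c(msg, paste("missing:", paste(miss, collapse = ", ")))
  else {
    if (v$min_read_len >= v$max_read_len) msg <- c(msg, "min_read_len < max_read_len required")
    if (v$min_q < 0) msg <- c(msg, "min_q must be >= 0")
    if (v$min_identity < 0 || v$min_identity > 1) msg <- c(msg, "min_identity in [0,1]")
    if (v$alpha <= 0 || v$alpha >= 1) msg <- c(msg, "alpha in (0,1)")
    if (v$sv_min_len < 1 || v$sv_min_support < 1) msg <- c(msg, "sv thresholds must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PipelineParams construct parameters, overriding defaults by name
#' @param ... named overrides of the defaults
#' @export
pipelineParams <- function(...) {
  ov <- list(...)
  bad <- setdiff(names(ov), names(.paramDefaults))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  v <- .paramDefaults
  v[names(ov)] <- ov
  new("PipelineParams", values = v)
}

#' @describeIn PipelineParams fetch one parameter value
#' @param x a PipelineParams
#' @param name parameter name
#' @export
param <- function(x, name) {
  if (!name %in% names(x@values)) stop("unknown parameter: ", name)
  x@values[[name]]
}

setMethod("show", "PipelineParams", function(object) {
  cat("PipelineParams with", length(object@values), "settings\n")
  v <- unlist(lapply(object@values, format))
  cat(paste0("  ", names(v), " = ", v, collapse = "\n"), "\n")
})
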