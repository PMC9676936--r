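# Published VRN1 allele definitions used to plant ground truth in the
# synthetic panel: the five structural variants (the Vrn-A1a promoter
# insertion, Vrn-B1f intron-1 tandem duplication, Vrn-B1a intron-1
# deletion, Vrn-B1b 37 bp deletion, Vrn-D1x intron-1 insertion and the
# small vrn-D1r 17 bp deletion), the 51-site VRN-A1 variant set across the
# six genotype groups, the 6-site VRN-B1 haplotype table and the
# three-variant VRN-D1 haplotype groups. Positions are 1-based from the
# amplicon start (3' end of the forward primer). Inserted sequences for
# which only the length is published are generated from a fixed RNG stream
# and are synthetic stand-ins.

.fixedSeq <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  randSeq(n)
}

#' Known structural-variant allele edits
#'
#' The five published SVs larger than 30 bp plus the 17 bp vrn-D1r
#' deletion, as allele-edit tables on the synthetic homoeolog references:
#' \itemize{
#'   \item \code{Vrn-A1a}: 231 bp foldback-repeat insertion in the VRN-A1
#'     promoter
#'   \item \code{Vrn-B1f}: 838 bp tandem duplication in intron 1 of VRN-B1
#'   \item \code{Vrn-B1a}: 6851 bp deletion in intron 1 of VRN-B1
#'   \item \code{Vrn-B1b}: 37 bp deletion downstream of the large deletion
#'   \item \code{Vrn-D1x}: 163 bp insertion in intron 1 of VRN-D1
#'   \item \code{vrn-D1r}: 17 bp deletion in intron 1 of VRN-D1
#' }
#' Insertion payloads are synthetic: the foldback element is a sequence
#' joined to its reverse complement; the 163 bp insertion is random.
#'
#' @return named list of allele-edit data frames, with a \code{homoeolog}
#'   attribute on each
#' @export
knownSvEdits <- function() {
  fb <- .fixedSeq(7L, 116L)
  foldback <- paste0(fb, revComp(substr(fb, 2L, 116L)))  # 231 bp
  e <- list(
    `Vrn-A1a` = alleleEdit("INS", 300L, 231L, foldback),
    `Vrn-B1f` = alleleEdit("DUP", 9387L, 838L, ""),
    `Vrn-B1a` = alleleEdit("DEL", 1760L, 6851L, ""),
    `Vrn-B1b` = alleleEdit("DEL", 9200L, 37L, ""),
    `Vrn-D1x` = alleleEdit("INS", 5500L, 163L, .fixedSeq(11L, 163L)),
    `vrn-D1r` = alleleEdit("DEL", 4000L, 17L, ""))
  hom <- c("A", "B", "B", "B", "D", "D")
  for (i in seq_along(e)) attr(e[[i]], "homoeolog") <- hom[i]
  e
}

#' The 51-site VRN-A1 variant table
#'
#' Positions and per-genotype-group alleles of the 51 polymorphic VRN-A1
#' sites (three promoter sites, the bulk in intron 1, plus intron 2, exon
#' 4, intron 4, intron 6 and exon 7). "-" denotes a single-base deletion
#' allele; "X/Y" a heterozygous call. The reference allele at each site is
#' the Weebill-type (GT3) base, or the GT1 base at the two sites where the
#' Weebill-type groups carry the deletion allele.
#'
#' @return data.frame: site, position, region, ref, GT1..GT6
#' @export
vrnA1SiteTable <- function() {
  pos <- c(147L, 244L, 381L, 1781L, 1890L, 2066L, 3184L, 3296L, 3298L,
           3386L, 3393L, 3408L, 3431L, 3459L, 3463L, 3701L, 3999L, 4138L,
           4646L, 4703L, 4740L, 4757L, 5270L, 5634L, 5722L, 5801L, 5928L,
           5932L, 6129L, 6160L, 6568L, 6907L, 6978L, 7468L, 7625L, 7738L,
           8036L, 8201L, 8266L, 9062L, 9736L, 10201L, 10802L, 10909L,
           11109L, 11234L, 11235L, 11236L, 11344L, 11639L, 11735L)
  gt1 <- c("A","T","C","T","A","A","C","T","G","C","C","C","G","G","C",
           "A","T","G","C","C","T","G","G","G","C","G","C","A","A","A",
           "G","C","C","C","C","T","T","C","T","T","A","T","T","T","C",
           "G","-","-","-","A","C")
  gt2 <- c("A","G","C","T","T","G","C","C","T","T","T","T","G","C","T",
           "G","G","G","T","T","T","G","G","A","G","T","C","G","G","A",
           "T","C","T","G","C","G","C","C","C","T","G","C","G","C","C",
           "A","A","C","-","A","C")
  gt3 <- c("G","G","C","-","A","A","G","T","G","C","C","T","A","G","C",
           "G","G","G","C","C","G","G","T","G","G","G","G","A","G","T",
           "T","T","C","G","A","G","C","G","C","G","G","C","G","T","C",
           "A","A","C","A","-","T")
  gt4 <- gt3; gt4[45] <- "C/T"
  gt5 <- gt3; gt5[3] <- "C/G"; gt5[22] <- "G/A"; gt5[45] <- "C/T"
  gt6 <- gt3; gt6[18] <- "G/A"; gt6[45] <- "C/T"
  refA <- ifelse(gt3 == "-", gt1, gt3)
  region <- cut(pos, breaks = c(0, 700, 1750, 10700, 10990, 11160, 11380,
                                11680, 11780, Inf),
                labels = c("promoter", "exon1", "intron1", "intron2",
                           "exon4", "intron4", "intron6", "exon7", "exon8"))
  data.frame(site = paste0("SNP", seq_along(pos)), position = pos,
             region = as.character(region), ref = refA,
             GT1 = gt1, GT2 = gt2, GT3 = gt3, GT4 = gt4, GT5 = gt5,
             GT6 = gt6, stringsAsFactors = FALSE)
}

#' VRN-A1 haplotype allele vectors
#'
#' The eight VRN-A1 haplotypes over the 51 sites: Hap1 and Hap2 are the
#' divergent GT1/GT2 backbones; Hap3 is the Weebill-type backbone; Hap4-8
#' are Hap3 carrying the alternate allele at the diagnostic heterozygous
#' sites (SNP45 in exon 4; SNP3/SNP22 for GT5; SNP18 for GT6).
#'
#' @return character matrix haplotypes x sites
#' @export
vrnA1Haplotypes <- function() {
  tb <- vrnA1SiteTable()
  hap <- rbind(Hap1 = tb$GT1, Hap2 = tb$GT2, Hap3 = tb$GT3,
               Hap4 = tb$GT3, Hap5 = tb$GT3, Hap6 = tb$GT3,
               Hap7 = tb$GT3, Hap8 = tb$GT3)
  colnames(hap) <- tb$site
  hap["Hap4", 45] <- "T"
  hap["Hap5", 3] <- "G"; hap["Hap5", 22] <- "A"
  hap["Hap6", 22] <- "A"; hap["Hap6", 45] <- "T"
  hap["Hap7", 18] <- "A"
  hap["Hap8", 18] <- "A"; hap["Hap8", 45] <- "T"
  hap
}

#' The 6-site VRN-B1 haplotype table
#'
#' Five VRN-B1 haplotype groups over six intron-1/intron-2 sites; Hap2
#' additionally carries the 838 bp tandem duplication (the heterozygous
#' entries at 9080 and 9387 reflect single-base differences between the
#' duplicated segments) and Hap5 the 6851 bp intron-1 deletion (hence the
#' missing alleles at the first two sites).
#'
#' @return data.frame: haplotype, n_cultivars, alleles at the six positions
#' @export
vrnB1SiteTable <- function() {
  out <- data.frame(
    haplotype = paste0("Hap", 1:5),
    n_cultivars = c(163L, 9L, 2L, 11L, 4L),
    p7505  = c("G", "A", "G", "G", NA),
    p8351  = c("G", "A", "G", "G", NA),
    p8615  = c("G", "G", "G", "A", "G"),
    p9080  = c("T", "T/C", "T", "T", "T"),
    p9387  = c("A", "A/C", "A", "A", "A"),
    p10971 = c("G", "A", "A", "G", "G"),
    stringsAsFactors = FALSE)
  out
}

# per-haplotype edit list for the A homoeolog relative to the synthetic
# Weebill-type reference alleles
.hapEditsA <- function(hapName) {
  tb <- vrnA1SiteTable()
  hp <- vrnA1Haplotypes()[hapName, ]
  diffs <- which(hp != tb$ref)
  if (!length(diffs)) return(alleleEdit())
  kind <- ifelse(hp[diffs] == "-", "DEL", "SNP")
  alt <- ifelse(hp[diffs] == "-", "", hp[diffs])
  alleleEdit(kind, tb$position[diffs], rep(1L, length(diffs)), alt)
}

#' Synthetic homoeolog references with planted variant contexts
#'
#' Generates the three homoeolog references and pins the bases at every
#' published variant position to the reference allele, with a
#' non-homopolymeric local context (so planted variants are recoverable
#' under the homopolymer exclusion rule).
#'
#' @param seed integer seed
#' @param targetIdentity pairwise identity (default 0.92)
#' @return named list of \linkS4class{HomoeologReference} (A, B, D)
#' @export
vrnPanelReferences <- function(seed, targetIdentity = 0.92) {
  refs <- generateReferences(seed, targetIdentity)
  tbA <- vrnA1SiteTable()
  avoidA <- lapply(seq_len(nrow(tbA)), function(i) {
    al <- unlist(strsplit(unlist(tbA[i, c("GT1", "GT2", "GT3", "GT4",
                                          "GT5", "GT6")]), "/", fixed = TRUE))
    setdiff(unique(al), c("-", tbA$ref[i]))
  })
  names(avoidA) <- as.character(tbA$position)
  refs$A <- .pinSites(refs$A, tbA$position, tbA$ref, avoidA)
  tbB <- vrnB1SiteTable()
  posB <- c(7505L, 8351L, 8615L, 9080L, 9387L, 10971L)
  avoidB <- list(`7505` = "A", `8351` = "A", `8615` = "A", `9080` = "C",
                 `9387` = "C", `10971` = "A")
  refs$B <- .pinSites(refs$B, posB, unlist(tbB[1, 3:8]), avoidB)
  refs$D <- .pinSites(refs$D, 5607L, "A", list(`5607` = "G"))
  refs
}

.pinSites <- function(ref, positions, bases, avoid = NULL) {
  ch <- seqChars(refSeq(ref))
  # set the reference allele first so the context cleaner keeps the final
  # neighbourhood free of equal adjacent bases (unambiguous indel placement)
  ch[positions] <- bases
  ch <- .cleanContext(ch, positions, avoid)
  homoeologReference(refId(ref), paste(ch, collapse = ""),
                     promoterLen(ref), featureMap(ref))
}

#' Genotype-group cultivar configurations for the VRN-A1 panel
#'
#' One cultivar per genotype group: GT1 (Hap1 plus the Vrn-A1a promoter
#' insertion, one copy), GT2 (Hap2, one copy), GT3 (Hap3, one copy), GT4
#' (Hap3 + 2x Hap4: three copies, skewed dosage at SNP45), GT5 (Hap3-6,
#' four copies) and GT6 (Hap3/4/7/8, four copies, balanced dosage).
#' \code{"GT4_2copy"} gives the two-copy balanced variant of GT4.
#'
#' @param groups which groups to build
#' @return list of \linkS4class{CultivarGenotype}
#' @export
vrnA1PanelGenotypes <- function(groups = c("GT1", "GT2", "GT3", "GT4",
                                           "GT5", "GT6")) {
  sv <- knownSvEdits()
  mk <- function(cult, haps, weights = rep(1, length(haps)), extra = NULL) {
    copies <- lapply(seq_along(haps), function(i) {
      ed <- .hapEditsA(haps[i])
      if (!is.null(extra)) ed <- combineEdits(ed, extra)
      templateCopy("A", ed, haps[i], weights[i])
    })
    cultivarGenotype(cult, copies)
  }
  all <- list(
    GT1 = function() mk("GT1", "Hap1", extra = sv[["Vrn-A1a"]]),
    GT2 = function() mk("GT2", "Hap2"),
    GT3 = function() mk("GT3", "Hap3"),
    GT4 = function() mk("GT4", c("Hap3", "Hap4", "Hap4")),
    GT4_2copy = function() mk("GT4_2copy", c("Hap3", "Hap4")),
    GT5 = function() mk("GT5", c("Hap3", "Hap4", "Hap5", "Hap6")),
    GT6 = function() mk("GT6", c("Hap3", "Hap4", "Hap7", "Hap8")))
  lapply(groups, function(g) all[[g]]())
}

#' VRN-D1 haplotype-group configurations
#'
#' The four published VRN-D1 groups: intact, the 163 bp intron-1 insertion
#' (Vrn-D1x), the 17 bp intron-1 deletion (vrn-D1r) and the intron-1 SNP
#' at position 5607.
#'
#' @return named list of allele-edit data frames (one per group)
#' @export
vrnD1GroupEdits <- function() {
  sv <- knownSvEdits()
  list(intact = alleleEdit(),
       ins163 = sv[["Vrn-D1x"]],
       del17 = sv[["vrn-D1r"]],
       snp5607 = alleleEdit("SNP", 5607L, 1L, "G"))
}
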