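#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames strand
#' @importFrom IRanges IRanges
NULL

#' Call open reading frames in all six frames
#'
#' Deterministic six-frame ORF caller: an ORF runs from a start codon
#' (`ATG` only by default) to the next in-frame stop under the bacterial
#' genetic code (table 11). For nested ORFs sharing a stop, the longest
#' (first start after the previous stop) is reported. Reverse-strand ORFs
#' are reported in forward-axis coordinates. The interval includes the
#' stop codon, so `width == 3 * (aa_len + 1)`.
#'
#' This intentionally trades the GC-frame and start-site models of
#' metagenome gene callers for determinism: the pipeline only needs
#' candidate proteins near arrays, and synthetic fixtures control the
#' ground truth.
#'
#' @param contig contig sequence (character or [Biostrings::DNAString]).
#' @param minAa minimum protein length in residues (stop excluded).
#' @param contigId contig identifier for the output.
#' @param altStarts also allow `GTG`/`TTG` starts. Such ORFs are
#'   translated by plain codon lookup (no forced initiator `M`), so they
#'   do not begin with methionine and are caught by the downstream
#'   Met-start filter; off by default.
#' @return a [GenomicRanges::GRanges] with metadata columns `protein`
#'   (character) and `aa_len`, sorted by start.
#' @examples
#' orfs <- callOrfs(paste0("CCTCCTCC", "ATGAAATAG", "CCTCCTCC"), minAa = 2)
#' orfs$protein
#' @export
callOrfs <- function(contig, minAa = 100L, contigId = "contig",
                     altStarts = FALSE) {
  stopifnot(minAa >= 1L)
  s <- toupper(as.character(contig))
  n <- nchar(s)
  startCodons <- if (altStarts) c("ATG", "GTG", "TTG") else "ATG"
  startAa <- if (altStarts) c("M", "V", "L") else "M"
  rows <- list()
  for (str in c("+", "-")) {
    ss <- if (str == "+") s else revComp(s)
    for (frame in 0:2) {
      usable <- n - frame
      usable <- usable - usable %% 3L
      if (usable < 6L) next
      sub <- substring(ss, frame + 1L, frame + usable)
      prot <- translateDna(sub)
      aa <- .seq_chars(prot)
      stops <- which(aa == "*")
      prev <- 0L
      for (t in stops) {
        seg <- if (t - prev > 1L) (prev + 1L):(t - 1L) else integer()
        prev <- t
        if (!length(seg)) next
        codons <- substring(sub, 3L * (seg - 1L) + 1L, 3L * seg)
        mpos <- seg[codons %in% startCodons]
        if (!length(mpos)) next
        m <- mpos[1L]
        aaLen <- t - m
        if (aaLen < minAa) next
        ntStart <- frame + 3L * (m - 1L) + 1L  # 1-based on strand ss
        ntEnd <- frame + 3L * t                # end of stop codon
        if (str == "+") {
          fs <- ntStart; fe <- ntEnd
        } else {
          fs <- n - ntEnd + 1L; fe <- n - ntStart + 1L
        }
        rows[[length(rows) + 1L]] <- list(
          start = fs, end = fe, strand = str,
          protein = substring(prot, m, t - 1L), aa_len = aaLen)
      }
    }
  }
  if (!length(rows)) {
    gr <- GRanges(character(), IRanges())
    mcols(gr)$protein <- character()
    mcols(gr)$aa_len <- integer()
    return(gr)
  }
  gr <- GRanges(contigId,
                IRanges(vapply(rows, `[[`, integer(1), "start"),
                        vapply(rows, `[[`, integer(1), "end")),
                strand = vapply(rows, `[[`, character(1), "strand"))
  mcols(gr)$protein <- vapply(rows, `[[`, character(1), "protein")
  mcols(gr)$aa_len <- vapply(rows, `[[`, integer(1), "aa_len")
  gr[order(GenomicRanges::start(gr))]
}

#' ORFs within the CRISPR neighbourhood
#'
#' Selects the ORFs whose interval intersects the window extending
#' `window` nt on each side of the array footprint (clipped at contig
#' bounds), mirroring the 15-kb harvesting window used when mining
#' effectors next to arrays.
#'
#' @param array a [CrisprArray-class].
#' @param orfs a [GenomicRanges::GRanges] from [callOrfs()] on the same
#'   contig.
#' @param window flank size in nt (default 15000).
#' @param contigLen optional contig length for clipping.
#' @return the subset of `orfs` intersecting the window, sorted by start.
#' @export
crisprNeighborhood <- function(array, orfs, window = 15000L,
                               contigLen = NULL) {
  if (!length(orfs)) return(orfs)
  same <- as.character(seqnames(orfs)) == contigId(array)
  orfs <- orfs[same]
  if (!length(orfs)) return(orfs)
  rng <- arrayRange(array)
  lo <- max(1L, IRanges::start(rng) - as.integer(window))
  hi <- IRanges::end(rng) + as.integer(window)
  if (!is.null(contigLen)) hi <- min(hi, as.integer(contigLen))
  win <- GRanges(contigId(array), IRanges(lo, hi))
  hits <- IRanges::overlapsAny(orfs, win, ignore.strand = TRUE)
  out <- orfs[hits]
  out[order(GenomicRanges::start(out))]
}

#' Annotate adaptor-cas genes (Cas1/Cas2/Cas4)
#'
#' Assigns each ORF the label of its best-scoring adaptor bait by local
#' alignment score, when that score reaches `minScore`; otherwise the ORF
#' is left unlabeled. Bait labels are taken from `labels`, or parsed from
#' bait names (first match of `Cas1`/`Cas2`/`Cas4`, case-insensitive).
#'
#' @param orfs [GenomicRanges::GRanges] from [callOrfs()].
#' @param adaptorBaits named [Biostrings::AAStringSet] (or named
#'   character) of adaptor bait proteins.
#' @param minScore minimum local alignment raw score for a label.
#' @param labels optional character vector of labels parallel to
#'   `adaptorBaits`.
#' @return a data.frame with one row per labeled ORF: `orf_index`,
#'   `start`, `end`, `strand`, `label`, `bait`, `score`.
#' @export
annotateAdaptors <- function(orfs, adaptorBaits, minScore = 100,
                             labels = NULL) {
  if (length(adaptorBaits) == 0L) stop("empty adaptor bait panel")
  baitSeq <- as.character(adaptorBaits)
  names(baitSeq) <- names(adaptorBaits)
  baitNames <- names(baitSeq)
  if (is.null(baitNames)) stop("adaptor baits must be named")
  if (is.null(labels)) {
    m <- regmatches(baitNames,
                    regexpr("cas[124]", baitNames, ignore.case = TRUE))
    labels <- ifelse(lengths(regmatches(baitNames,
      gregexpr("cas[124]", baitNames, ignore.case = TRUE))) > 0,
      paste0("Cas", sub("(?i)cas", "", m, perl = TRUE)), baitNames)
  }
  out <- list()
  for (i in seq_along(orfs)) {
    prot <- mcols(orfs)$protein[i]
    scores <- vapply(baitSeq, function(b)
      smithWaterman(prot, b)$score, numeric(1))
    best <- which.max(scores)
    if (scores[best] >= minScore) {
      out[[length(out) + 1L]] <- data.frame(
        orf_index = i,
        start = GenomicRanges::start(orfs)[i],
        end = GenomicRanges::end(orfs)[i],
        strand = as.character(strand(orfs))[i],
        label = labels[best], bait = baitNames[best],
        score = scores[best])
    }
  }
  if (!length(out)) {
    return(data.frame(orf_index = integer(), start = integer(),
                      end = integer(), strand = character(),
                      label = character(), bait = character(),
                      score = numeric()))
  }
  do.call(rbind, out)
}

#' Write ORFs to GFF3 (CDS features)
#'
#' @param orfs [GenomicRanges::GRanges] from [callOrfs()].
#' @param path output path.
#' @param products optional character vector of product tags parallel to
#'   `orfs`.
#' @return `path`, invisibly.
#' @export
orfsToGff3 <- function(orfs, path, products = NULL) {
  if (is.null(products)) products <- rep("hypothetical protein",
                                         length(orfs))
  df <- data.frame(
    seqid = as.character(seqnames(orfs)), type = "CDS",
    start = GenomicRanges::start(orfs), end = GenomicRanges::end(orfs),
    strand = as.character(strand(orfs)),
    attributes = sprintf("ID=orf%04d;product=%s", seq_along(orfs),
                         products))
  writeGff3(df, path)
}
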