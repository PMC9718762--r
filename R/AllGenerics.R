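#' @include AllClasses.R
NULL

#' Accessors for CrisprArray objects
#'
#' @param x a [CrisprArray-class] object.
#' @return `contigId` the contig identifier; `repeatRanges` /
#'   `spacerRanges` the repeat/spacer [IRanges::IRanges]; `nRepeats` /
#'   `nSpacers` their counts; `consensusRepeat` the majority-rule repeat
#'   consensus (DNA, forward strand); `arrayOrientation` one of
#'   "forward", "reverse", "unknown".
#' @name CrisprArray-accessors
#' @examples
#' arr <- exampleArray()
#' nRepeats(arr)
#' consensusRepeat(arr)
NULL

#' @rdname CrisprArray-accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("spacerRanges", function(x) standardGeneric("spacerRanges"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("nSpacers", function(x) standardGeneric("nSpacers"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("consensusRepeat", function(x, ...) standardGeneric("consensusRepeat"))
#' @rdname CrisprArray-accessors
#' @export
setGeneric("arrayOrientation", function(x) standardGeneric("arrayOrientation"))

#' Detect CRISPR arrays in DNA sequence
#'
#' @param x the sequence(s) to scan: a character string, a
#'   [Biostrings::DNAString] or a [Biostrings::DNAStringSet].
#' @param params a [DetectorParams-class] object.
#' @param ... passed between methods (e.g. `contigId` for single
#'   sequences).
#' @return a list of [CrisprArray-class] objects (possibly empty).
#' @seealso [detectorParams()]
#' @export
setGeneric("findArrays", function(x, params = detectorParams(), ...)
  standardGeneric("findArrays"))

#' Accessors for DigestResult objects
#'
#' @param x a [DigestResult-class] object.
#' @name DigestResult-accessors
NULL

#' @rdname DigestResult-accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname DigestResult-accessors
#' @export
setGeneric("overhangLength", function(x) standardGeneric("overhangLength"))
#' @rdname DigestResult-accessors
#' @export
setGeneric("isCut", function(x) standardGeneric("isCut"))

setMethod("contigId", "CrisprArray", function(x) x@contigId)
setMethod("repeatRanges", "CrisprArray", function(x) x@repeats)
setMethod("spacerRanges", "CrisprArray", function(x) x@spacers)
setMethod("nRepeats", "CrisprArray", function(x) length(x@repeats))
setMethod("nSpacers", "CrisprArray", function(x) length(x@spacers))
setMethod("arrayOrientation", "CrisprArray", function(x) x@orientation)

setMethod("fragments", "DigestResult", function(x) x@fragments)
setMethod("overhangLength", "DigestResult", function(x) x@overhang)
setMethod("isCut", "DigestResult", function(x) !is.na(x@cutNonTarget))

#' Start/end of the full array footprint
#' @param x a [CrisprArray-class] object.
#' @rdname CrisprArray-accessors
#' @export
arrayRange <- function(x) {
  IRanges::IRanges(min(IRanges::start(x@repeats)),
                   max(IRanges::end(x@repeats)))
}

setMethod("show", "CrisprArray", function(object) {
  rng <- arrayRange(object)
  cat(sprintf(
    "CrisprArray on %s [%d-%d] (%s): %d repeats x %d nt, %d spacers\n",
    object@contigId, IRanges::start(rng), IRanges::end(rng),
    object@orientation, length(object@repeats),
    nchar(object@consensusRepeat), length(object@spacers)))
  cat("  consensus: ", object@consensusRepeat, "\n", sep = "")
})

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf(
    paste0("DetectorParams: >=%d repeats, repeat %d-%d nt, ",
           "spacer %d-%d nt, seed %d-mer, <=%d mismatches/copy\n"),
    object@minRepeats, object@minRepeatLen, object@maxRepeatLen,
    object@minSpacerLen, object@maxSpacerLen, object@seedK,
    object@maxMismatches))
})

setMethod("show", "RepeatHandle", function(object) {
  cat(sprintf("RepeatHandle: %d-nt repeat, cut after %d nt, %d-nt handle\n",
              nchar(object@directRepeat), object@maturationCut,
              nchar(object@handle)))
  cat("  handle: ", object@handle, "\n  stem: ", nrow(object@stemPairs),
      " pairs, loop [", object@loop[1], ",", object@loop[2], "]\n",
      sep = "")
})

setMethod("show", "DigestResult", function(object) {
  if (is.na(object@cutNonTarget)) {
    cat(sprintf("DigestResult: %d bp target, no cut site\n",
                object@targetLen))
  } else {
    cat(sprintf(
      "DigestResult: %d bp target, PAM %d-%d (%s), cuts %d/%d (%d-nt 5' overhang)\n  fragments: %s bp\n",
      object@targetLen, object@pamStart, object@pamEnd, object@strand,
      object@cutNonTarget, object@cutTarget, object@overhang,
      paste(object@fragments, collapse = " + ")))
  }
})

setMethod("show", "DiscoveryReport", function(object) {
  nc <- if (nrow(object@candidates))
    sum(object@candidates$passed) else 0L
  cat(sprintf(
    "DiscoveryReport: %d array(s), %d candidate(s) passing all filters (%d rows incl. flagged exclusions)\n",
    length(object@arrays), nc, nrow(object@candidates)))
  if (!is.null(object@tree))
    cat(sprintf("  tree: %d tips\n", length(object@tree$tip.label)))
})

#' A small worked CrisprArray example
#'
#' Builds a three-repeat array on a toy contig; used in documentation
#' examples.
#' @return a [CrisprArray-class] object.
#' @export
exampleArray <- function() {
  rep1 <- "GTCTAAGAACTTTAAATAATTTCTACTGTTGTAGAT"
  sp1 <- "CAGTTCGAAGCTCAGGCTAGCTAGGTACC"
  sp2 <- "TGACCTTGAGCATCCGATACGGTTACACG"
  seq <- paste0(strrep("A", 10), rep1, sp1, rep1, sp2, rep1,
                strrep("A", 10))
  findArrays(seq, contigId = "toy")[[1]]
}
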