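#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Detector parameters for CRISPR array scanning
#'
#' Tuning knobs of the CRT-style repeat finder. The defaults follow the
#' CRT lineage of array detectors: at least 3 repeat copies, repeat length
#' 19--38 nt, spacer length 19--48 nt, an 8-nt exact seed and up to 2
#' mismatches per repeat copy against the array consensus.
#'
#' @slot minRepeats minimum number of repeat copies in a reported array.
#' @slot minRepeatLen,maxRepeatLen allowed repeat length range (nt).
#' @slot minSpacerLen,maxSpacerLen allowed spacer length range (nt).
#' @slot seedK exact seed k-mer length used to anchor candidate arrays.
#' @slot maxMismatches maximum mismatches tolerated per repeat copy
#'   relative to the array consensus.
#'
#' @seealso [detectorParams()], [findArrays()]
#' @exportClass DetectorParams
setClass("DetectorParams",
  representation(
    minRepeats = "integer",
    minRepeatLen = "integer", maxRepeatLen = "integer",
    minSpacerLen = "integer", maxSpacerLen = "integer",
    seedK = "integer", maxMismatches = "integer"
  )
)

setValidity("DetectorParams", function(object) {
  msg <- character()
  if (object@minRepeats < 2L)
    msg <- c(msg, "minRepeats must be >= 2")
  if (object@minRepeatLen > object@maxRepeatLen)
    msg <- c(msg, "minRepeatLen must be <= maxRepeatLen")
  if (object@minSpacerLen > object@maxSpacerLen)
    msg <- c(msg, "minSpacerLen must be <= maxSpacerLen")
  if (object@seedK > object@minRepeatLen)
    msg <- c(msg, "seedK must be <= minRepeatLen")
  if (object@seedK < 4L)
    msg <- c(msg, "seedK must be >= 4")
  if (object@maxMismatches < 0L)
    msg <- c(msg, "maxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct detector parameters
#'
#' @param minRepeats minimum repeat copies per array (default 3).
#' @param minRepeatLen,maxRepeatLen repeat length bounds in nt (19/38).
#' @param minSpacerLen,maxSpacerLen spacer length bounds in nt (19/48).
#' @param seedK seed k-mer length (default 8).
#' @param maxMismatches per-copy mismatch budget against the consensus
#'   (default 2).
#'
#' @return A [DetectorParams-class] object.
#' @examples
#' detectorParams()
#' detectorParams(minRepeats = 4, maxSpacerLen = 60)
#' @export
detectorParams <- function(minRepeats = 3, minRepeatLen = 19,
                           maxRepeatLen = 38, minSpacerLen = 19,
                           maxSpacerLen = 48, seedK = 8,
                           maxMismatches = 2) {
  new("DetectorParams",
    minRepeats = as.integer(minRepeats),
    minRepeatLen = as.integer(minRepeatLen),
    maxRepeatLen = as.integer(maxRepeatLen),
    minSpacerLen = as.integer(minSpacerLen),
    maxSpacerLen = as.integer(maxSpacerLen),
    seedK = as.integer(seedK),
    maxMismatches = as.integer(maxMismatches)
  )
}

#' A detected CRISPR repeat-spacer array
#'
#' Coordinates are 1-based closed intervals (IRanges convention) on the
#' forward strand of the source contig. Repeats and spacers strictly
#' alternate; an array with n repeats has n - 1 spacers. Orientation is
#' "unknown" at detection time and is resolved by [orientArray()] from the
#' foldability of the repeat's 3' terminal handle.
#'
#' @slot contigId identifier of the contig the array lies on.
#' @slot repeats [IRanges::IRanges] of the repeat copies, ascending.
#' @slot spacers [IRanges::IRanges] of the spacers, ascending.
#' @slot consensusRepeat per-column majority consensus of the repeat
#'   copies (DNA, forward strand).
#' @slot orientation one of "forward", "reverse", "unknown".
#'
#' @seealso [findArrays()], [consensusRepeat()], [orientArray()]
#' @exportClass CrisprArray
setClass("CrisprArray",
  representation(
    contigId = "character",
    repeats = "IRanges",
    spacers = "IRanges",
    consensusRepeat = "character",
    orientation = "character"
  )
)

setValidity("CrisprArray", function(object) {
  msg <- character()
  nr <- length(object@repeats)
  ns <- length(object@spacers)
  if (nr < 2L) msg <- c(msg, "an array needs at least 2 repeats")
  if (ns != nr - 1L) msg <- c(msg, "n_spacers must equal n_repeats - 1")
  if (!object@orientation %in% c("forward", "reverse", "unknown"))
    msg <- c(msg, "orientation must be forward/reverse/unknown")
  rs <- IRanges::start(object@repeats); re <- IRanges::end(object@repeats)
  ss <- IRanges::start(object@spacers); se <- IRanges::end(object@spacers)
  if (nr >= 2L && ns == nr - 1L) {
    if (is.unsorted(rs, strictly = TRUE))
      msg <- c(msg, "repeats must be ascending")
    # strict alternation repeat/spacer/repeat/...
    if (!all(ss == re[-nr] + 1L) || !all(se == rs[-1L] - 1L))
      msg <- c(msg, "repeats and spacers must alternate without gaps")
  }
  if (nchar(object@consensusRepeat) > 0 &&
      !grepl("^[ACGT]+$", object@consensusRepeat))
    msg <- c(msg, "consensusRepeat must be over {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

#' A direct repeat with its predicted crRNA maturation products
#'
#' Cas12a matures its own pre-crRNA by cleaving inside the direct repeat;
#' the retained 3' portion of the repeat becomes the stem-loop-forming
#' 5' handle of the mature crRNA. `maturationCut` counts the nucleotides
#' removed from the repeat 5' end, so
#' `handle == rna(substring(directRepeat, maturationCut + 1))`.
#'
#' @slot directRepeat oriented direct repeat (DNA, 5'->3').
#' @slot maturationCut number of 5' nucleotides removed during maturation.
#' @slot handle mature 5' handle (RNA, 5'->3').
#' @slot stemPairs two-column integer matrix of paired handle positions
#'   (1-based, column 1 < column 2), nested, Watson-Crick or G.U.
#' @slot loop integer vector `c(start, end)` of the unpaired loop within
#'   the handle (1-based closed); covers the whole handle when no stem.
#'
#' @seealso [predictMaturationSite()], [foldHairpin()], [classifyHandle()]
#' @exportClass RepeatHandle
setClass("RepeatHandle",
  representation(
    directRepeat = "character",
    maturationCut = "integer",
    handle = "character",
    stemPairs = "matrix",
    loop = "integer"
  )
)

setValidity("RepeatHandle", function(object) {
  msg <- character()
  dr <- object@directRepeat
  if (!grepl("^[ACGT]+$", dr))
    msg <- c(msg, "directRepeat must be DNA over {A,C,G,T}")
  if (object@maturationCut < 0L || object@maturationCut >= nchar(dr))
    msg <- c(msg, "maturationCut out of range")
  expected <- chartr("T", "U", substring(dr, object@maturationCut + 1L))
  if (!identical(object@handle, expected))
    msg <- c(msg, "handle must be the transcribed repeat suffix")
  if (ncol(object@stemPairs) != 2L)
    msg <- c(msg, "stemPairs must have two columns")
  if (length(object@loop) != 2L)
    msg <- c(msg, "loop must be c(start, end)")
  if (length(msg)) msg else TRUE
})

#' Result of one in-silico Cas12a cut-site prediction
#'
#' Cut positions count nucleotides 5' of the scissile bond on the forward
#' axis: a cut value of k separates positions k and k + 1. Cas12a cuts the
#' two strands at different distances from the PAM, producing a 5'
#' overhang of `abs(cutTargetStrand - cutNonTargetStrand)` nt. Fragment
#' lengths are computed at the non-target-strand (PAM-proximal) cut and
#' always sum to the target length.
#'
#' @slot targetLen length of the (linear) target in bp.
#' @slot pamStart,pamEnd 1-based closed interval of the PAM match on the
#'   forward axis (0/0 when no site was found).
#' @slot strand "+", "-" or "*" (no site).
#' @slot protoStart,protoEnd protospacer interval on the forward axis.
#' @slot cutNonTarget,cutTarget cut positions (see above); `NA` if uncut.
#' @slot overhang length of the 5' overhang in nt (0 if uncut).
#' @slot fragments integer vector of predicted fragment lengths (bp).
#'
#' @seealso [inSilicoDigest()], [findPamSites()]
#' @exportClass DigestResult
setClass("DigestResult",
  representation(
    targetLen = "integer",
    pamStart = "integer", pamEnd = "integer", strand = "character",
    protoStart = "integer", protoEnd = "integer",
    cutNonTarget = "integer", cutTarget = "integer",
    overhang = "integer", fragments = "integer"
  )
)

setValidity("DigestResult", function(object) {
  msg <- character()
  if (sum(object@fragments) != object@targetLen)
    msg <- c(msg, "fragments must sum to targetLen")
  if (any(object@fragments < 1L))
    msg <- c(msg, "fragments must all be >= 1 bp")
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "strand must be +, - or *")
  if (!is.na(object@cutNonTarget) && !is.na(object@cutTarget) &&
      object@overhang != abs(object@cutTarget - object@cutNonTarget))
    msg <- c(msg, "overhang must equal |cutTarget - cutNonTarget|")
  if (length(msg)) msg else TRUE
})

#' End-to-end discovery report
#'
#' Container for the output of [runDiscovery()]: detected arrays, their
#' handle analyses, the filtered effector candidates with scores, adaptor
#' gene labels, and (when at least three sequences are available) a
#' neighbor-joining tree of candidates plus baits.
#'
#' @slot arrays list of [CrisprArray-class] objects.
#' @slot candidates [S4Vectors::DataFrame] of effector candidates
#'   (one row each; includes flagged exclusions).
#' @slot adaptors [S4Vectors::DataFrame] of adaptor-gene annotations.
#' @slot handles [S4Vectors::DataFrame] of per-array handle analyses.
#' @slot tree an [ape::read.tree] style `phylo` object or `NULL`.
#' @slot config the configuration list the run used.
#' @slot seed integer RNG seed recorded for reproducibility.
#'
#' @seealso [runDiscovery()], [writeDiscoveryReport()]
#' @exportClass DiscoveryReport
setClass("DiscoveryReport",
  representation(
    arrays = "list",
    candidates = "DataFrame",
    adaptors = "DataFrame",
    handles = "DataFrame",
    tree = "ANY",
    config = "list",
    seed = "integer"
  )
)
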