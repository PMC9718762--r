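#' @include AllClasses.R
NULL

#' Configuration for a discovery run
#'
#' Collects the parameters of every pipeline stage. "Adjacent to a
#' CRISPR array" is operationalized as the same `window` used for ORF
#' harvesting (no second distance exists in the screening protocol this
#' mirrors).
#'
#' @param detector a [detectorParams()].
#' @param window neighbourhood half-width in nt (default 15000).
#' @param orfMinAa minimum ORF length for the neighbourhood scan
#'   (default 100; small enough not to lose Cas2).
#' @param effectorMinAa,effectorMaxAa effector length filter (800/1500).
#' @param minScore minimum local-alignment raw score for an effector
#'   hit.
#' @param adaptorMinScore minimum score for an adaptor label.
#' @param handleLen mature handle length (default 19).
#' @param usePrefilter k-mer prefilter before full alignment.
#' @param seed RNG seed recorded in the report.
#' @return a named list.
#' @export
discoveryConfig <- function(detector = detectorParams(),
                            window = 15000L, orfMinAa = 100L,
                            effectorMinAa = 800L,
                            effectorMaxAa = 1500L, minScore = 200,
                            adaptorMinScore = 100,
                            handleLen = 19L, usePrefilter = FALSE,
                            seed = 1L) {
  list(detector = detector, window = as.integer(window),
       orfMinAa = as.integer(orfMinAa),
       effectorMinAa = as.integer(effectorMinAa),
       effectorMaxAa = as.integer(effectorMaxAa),
       minScore = minScore, adaptorMinScore = adaptorMinScore,
       handleLen = as.integer(handleLen),
       usePrefilter = isTRUE(usePrefilter), seed = as.integer(seed))
}

.stage_fail <- function(stage, id, e) {
  stop("pipeline stage '", stage, "' failed on '", id, "': ",
       conditionMessage(e), call. = FALSE)
}

#' Run the discovery pipeline end to end
#'
#' Executes the full mining cascade on assembled contigs: (1) detect
#' CRISPR arrays; (2) call ORFs on array-bearing contigs; (3) harvest the
#' ORFs within `window` nt of each array; (4) label adaptor genes
#' (Cas1/Cas2/Cas4) when adaptor baits are supplied; (5) screen
#' neighbourhood ORFs against the Cas12a bait panel with the
#' length/methionine/score filters (Met-start failures are kept in the
#' report, flagged, rather than silently dropped); (6) analyse each
#' array's direct repeat (orientation, maturation cut, handle fold and
#' classification); (7) compute each candidate's isoelectric point; (8)
#' when candidates plus baits number at least three, build the
#' neighbor-joining tree placing candidates among the baits.
#'
#' @param contigs named [Biostrings::DNAStringSet] (or named character).
#' @param baits named [Biostrings::AAStringSet] or named character of
#'   Cas12a bait proteins (non-empty).
#' @param adaptorBaits optional named baits for Cas1/Cas2/Cas4.
#' @param config a [discoveryConfig()].
#' @param handleRefs reference handles for classification.
#' @return a [DiscoveryReport-class].
#' @export
runDiscovery <- function(contigs, baits, adaptorBaits = NULL,
                         config = discoveryConfig(),
                         handleRefs = handleReferences()) {
  # configuration validation happens before any compute
  if (length(baits) == 0L) stop("configuration error: empty bait panel")
  if (length(contigs) == 0L)
    stop("configuration error: no input contigs")
  if (is.character(contigs)) contigs <- DNAStringSet(toupper(contigs))
  if (is.null(names(contigs)))
    stop("configuration error: contigs must be named")

  arrays <- list()
  for (id in names(contigs)) {
    arrays <- c(arrays, tryCatch(
      findArrays(as.character(contigs[[id]]), config$detector,
                 contigId = id),
      error = function(e) .stage_fail("detect", id, e)))
  }

  orfsByContig <- list()
  for (a in arrays) {
    id <- contigId(a)
    if (is.null(orfsByContig[[id]])) {
      orfsByContig[[id]] <- tryCatch(
        callOrfs(as.character(contigs[[id]]), minAa = config$orfMinAa,
                 contigId = id),
        error = function(e) .stage_fail("orf-call", id, e))
    }
  }

  candRows <- list()
  adaptRows <- list()
  handleRows <- list()
  candProteins <- character()
  for (ai in seq_along(arrays)) {
    a <- arrays[[ai]]
    id <- contigId(a)
    hood <- crisprNeighborhood(a, orfsByContig[[id]],
                               window = config$window,
                               contigLen = length(contigs[[id]]))
    if (!is.null(adaptorBaits) && length(hood)) {
      ad <- tryCatch(
        annotateAdaptors(hood, adaptorBaits,
                         minScore = config$adaptorMinScore),
        error = function(e) .stage_fail("adaptor-annotate", id, e))
      if (nrow(ad)) {
        ad$contig <- id
        ad$array_index <- ai
        adaptRows[[length(adaptRows) + 1L]] <- ad
      }
    }
    scr <- tryCatch(
      screenCandidates(hood, baits, minScore = config$minScore,
                       minAa = config$effectorMinAa,
                       maxAa = config$effectorMaxAa,
                       usePrefilter = config$usePrefilter,
                       keepExcluded = TRUE),
      error = function(e) .stage_fail("screen", id, e))
    if (nrow(scr)) {
      scr$array_index <- ai
      prot <- mcols(hood)$protein[scr$orf_index]
      scr$pI <- vapply(prot, isoelectricPoint, numeric(1),
                       USE.NAMES = FALSE)
      nm <- sprintf("%s_orf%d", id,
                    scr$orf_index)
      scr$candidate_id <- nm
      passed <- scr$passed
      candProteins <- c(candProteins,
                        setNames(prot[passed], nm[passed]))
      candRows[[length(candRows) + 1L]] <- scr
    }
    ha <- tryCatch(analyzeArrayHandle(a, handleLen = config$handleLen,
                                      refs = handleRefs),
      error = function(e) .stage_fail("handle", id, e))
    arrays[[ai]]@orientation <- ha$orientation
    handleRows[[length(handleRows) + 1L]] <- DataFrame(
      array_index = ai, contig = id,
      consensus = consensusRepeat(a),
      orientation = ha$orientation,
      maturation_cut = maturationCut(ha$handle),
      handle = handleSeq(ha$handle),
      stem_pairs = nrow(stemPairs(ha$handle)),
      best_reference = ha$classification$best,
      mismatches = ha$classification$mismatches,
      loop_mismatches = ha$classification$loopMismatches)
  }

  emptyCand <- screenCandidates(
    callOrfs("A", minAa = 1L)[0], baits, minScore = Inf)
  candidates <- if (length(candRows)) do.call(rbind, candRows) else
    emptyCand
  adaptors <- if (length(adaptRows))
    DataFrame(do.call(rbind, adaptRows)) else
    DataFrame(orf_index = integer(), start = integer(),
              end = integer(), strand = character(),
              label = character(), bait = character(),
              score = numeric(), contig = character(),
              array_index = integer())
  handles <- if (length(handleRows)) do.call(rbind, handleRows) else
    DataFrame(array_index = integer(), contig = character(),
              consensus = character(), orientation = character(),
              maturation_cut = integer(), handle = character(),
              stem_pairs = integer(), best_reference = character(),
              mismatches = integer(), loop_mismatches = integer())

  # phylogeny of passing candidates among the baits
  tree <- NULL
  baitSeqs <- as.character(baits)
  names(baitSeqs) <- names(baits)
  treeSeqs <- c(candProteins, baitSeqs)
  treeSeqs <- treeSeqs[!duplicated(names(treeSeqs))]
  if (length(candProteins) && length(treeSeqs) >= 3L) {
    tree <- tryCatch(njTree(distanceMatrix(treeSeqs)),
      error = function(e) .stage_fail("tree", "panel", e))
  }

  new("DiscoveryReport", arrays = arrays, candidates = candidates,
      adaptors = adaptors, handles = handles, tree = tree,
      config = config, seed = config$seed)
}

#' Accessors for DiscoveryReport objects
#'
#' @param x a [DiscoveryReport-class].
#' @param passedOnly return only candidates passing all filters
#'   (default TRUE); `FALSE` includes flagged exclusions.
#' @return `reportCandidates`: candidate [S4Vectors::DataFrame];
#'   `reportArrays`: list of [CrisprArray-class]; `reportHandles` /
#'   `reportAdaptors`: annotation tables; `reportTree`: the `phylo` or
#'   `NULL`.
#' @name DiscoveryReport-accessors
#' @export
reportCandidates <- function(x, passedOnly = TRUE) {
  cand <- x@candidates
  if (passedOnly && nrow(cand)) cand[cand$passed, , drop = FALSE] else
    cand
}

#' @rdname DiscoveryReport-accessors
#' @export
reportArrays <- function(x) x@arrays

#' @rdname DiscoveryReport-accessors
#' @export
reportHandles <- function(x) x@handles

#' @rdname DiscoveryReport-accessors
#' @export
reportAdaptors <- function(x) x@adaptors

#' @rdname DiscoveryReport-accessors
#' @export
reportTree <- function(x) x@tree

#' Write all artifacts of a discovery run
#'
#' Emits `arrays.gff3`, `arrays.tsv`, `candidates.tsv`, `adaptors.tsv`,
#' `handles.tsv`, `tree.nwk` (when a tree exists) and `report.json`
#' into `dir`.
#'
#' @param report a [DiscoveryReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDiscoveryReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) utils::write.table(as.data.frame(x),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report@arrays))
    arraysToGff3(report@arrays, file.path(dir, "arrays.gff3"))
  wtsv(arrayTable(report@arrays), "arrays.tsv")
  wtsv(report@candidates, "candidates.tsv")
  wtsv(report@adaptors, "adaptors.tsv")
  wtsv(report@handles, "handles.tsv")
  if (!is.null(report@tree))
    writeNewick(report@tree, file.path(dir, "tree.nwk"))
  json <- list(
    version = as.character(utils::packageVersion("casProspector")),
    seed = report@seed,
    n_arrays = length(report@arrays),
    n_candidates = sum(report@candidates$passed),
    candidates = as.data.frame(reportCandidates(report)),
    handles = as.data.frame(report@handles))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
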