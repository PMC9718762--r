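#' @include AllClasses.R AllGenerics.R
NULL

# ---- internal engine -------------------------------------------------------
#
# CRT-style detection on a plain character string:
#   1. hash all exact seedK-mers (skipping any containing N);
#   2. chain seed occurrences whose successive spacing lies within
#      [minRepeatLen + minSpacerLen, maxRepeatLen + maxSpacerLen];
#   3. extend each chain left/right into equal-length repeat copies while
#      per-copy mismatches against the column consensus stay within budget
#      and a column keeps >= 75% agreement;
#   4. search beyond the chain for further copies matching the consensus
#      within the mismatch budget at a valid spacing;
#   5. validate length bounds, then keep maximal non-overlapping arrays
#      (more repeats first, then leftmost).

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# majority base per column over equal-length copies; ties broken by the
# earliest copy carrying one of the tied bases
.column_consensus <- function(mat) {
  apply(mat, 2L, function(col) {
    tab <- table(col)
    winners <- names(tab)[tab == max(tab)]
    col[col %in% winners][1]
  })
}

.copies_matrix <- function(chars, starts, len) {
  do.call(rbind, lapply(starts, function(s) chars[s:(s + len - 1L)]))
}

# grow [offL, offR] extensions around seed starts; returns c(offL, offR).
# strict mode demands unanimous columns (exact boundaries of clean
# arrays); tolerant mode allows one dissenting copy per column within
# the per-copy budget (full-width recovery of mutated arrays). Both
# variants enter the candidate pool and the quality score arbitrates.
.extend_copies <- function(chars, seedStarts, k, p, n, strict = FALSE) {
  offL <- 0L; offR <- 0L
  m <- length(seedStarts)
  mism <- integer(m)
  repeat_len <- function() k + offL + offR
  # minimal gap between adjacent copies under current extension
  min_gap <- function(oL, oR) {
    if (m < 2L) return(Inf)
    min(diff(seedStarts)) - k - oL - oR
  }
  grow <- function(side) {
    if (side == "L") {
      pos <- seedStarts - offL - 1L
      if (any(pos < 1L)) return(FALSE)
    } else {
      pos <- seedStarts + k + offR
      if (any(pos > n)) return(FALSE)
    }
    if (repeat_len() + 1L > p@maxRepeatLen) return(FALSE)
    newGap <- if (side == "L") min_gap(offL + 1L, offR)
              else min_gap(offL, offR + 1L)
    if (newGap < p@minSpacerLen) return(FALSE)
    col <- chars[pos]
    if (any(col == "N")) return(FALSE)
    tab <- table(col)
    winners <- names(tab)[tab == max(tab)]
    cons <- col[col %in% winners][1]
    # column must be conserved: at most one dissenting copy
    # (none in strict mode)
    need <- if (strict || m <= 2L) m else m - 1L
    if (max(tab) < need) return(FALSE)
    newMism <- mism + (col != cons)
    if (any(newMism > p@maxMismatches)) return(FALSE)
    mism <<- newMism
    if (side == "L") offL <<- offL + 1L else offR <<- offR + 1L
    TRUE
  }
  while (grow("L")) {}
  while (grow("R")) {}
  c(offL, offR)
}

# count mismatches between chars[at..at+len-1] and consensus vector
.mismatches_at <- function(chars, at, cons, n) {
  len <- length(cons)
  if (at < 1L || at + len - 1L > n) return(Inf)
  win <- chars[at:(at + len - 1L)]
  if (any(win == "N")) return(Inf)
  sum(win != cons)
}

# try to add copies beyond the current set, scanning valid spacings
.chain_more <- function(chars, starts, len, p, n) {
  cons <- .column_consensus(.copies_matrix(chars, starts, len))
  lo <- p@minSpacerLen; hi <- p@maxSpacerLen
  repeat {  # forward
    base <- starts[length(starts)] + len
    cand <- (base + lo):(base + hi)
    mm <- vapply(cand, .mismatches_at, numeric(1), chars = chars,
                 cons = cons, n = n)
    if (!any(mm <= p@maxMismatches)) break
    best <- cand[which(mm == min(mm))[1]]
    starts <- c(starts, best)
  }
  repeat {  # backward
    base <- starts[1L] - len
    cand <- (base - hi):(base - lo)
    cand <- cand[cand >= 1L]
    if (!length(cand)) break
    mm <- vapply(cand, .mismatches_at, numeric(1), chars = chars,
                 cons = cons, n = n)
    if (!any(mm <= p@maxMismatches)) break
    best <- cand[which(mm == min(mm))[1]]
    starts <- c(best, starts)
  }
  starts
}

.find_arrays_chr <- function(seq, params, contigId) {
  p <- params
  n <- nchar(seq)
  k <- p@seedK
  minNeed <- p@minRepeats * p@minRepeatLen +
    (p@minRepeats - 1L) * p@minSpacerLen
  if (n < minNeed) return(list())
  chars <- .seq_chars(seq)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  posByKmer <- split(starts[keep], kmers[keep])
  posByKmer <- posByKmer[lengths(posByKmer) >= 2L]
  loP <- p@minRepeatLen + p@minSpacerLen
  hiP <- p@maxRepeatLen + p@maxSpacerLen

  candidates <- list()
  sigs <- character()
  for (pos in posByKmer) {
    # greedy chains over valid spacings
    i <- 1L
    while (i <= length(pos)) {
      chain <- pos[i]
      last <- pos[i]
      j <- i + 1L
      while (j <= length(pos)) {
        gap <- pos[j] - last
        if (gap > hiP) break
        if (gap >= loP) { chain <- c(chain, pos[j]); last <- pos[j] }
        j <- j + 1L
      }
      i <- i + 1L
      if (length(chain) < 2L) next
      for (strict in c(TRUE, FALSE)) {
      offs <- .extend_copies(chars, chain, k, p, n, strict = strict)
      rStarts <- chain - offs[1]
      rLen <- k + offs[1] + offs[2]
      rStarts <- .chain_more(chars, rStarts, rLen, p, n)
      if (length(rStarts) < p@minRepeats) next
      if (rLen < p@minRepeatLen || rLen > p@maxRepeatLen) next
      gaps <- diff(rStarts) - rLen
      if (any(gaps < p@minSpacerLen | gaps > p@maxSpacerLen)) next
      # spacer-dissimilarity filter: true spacers are unique acquired
      # sequence; tandem/satellite repeats read as arrays whose "spacers"
      # resemble the repeat unit (any periodicity) or one another
      consTmp <- paste(.column_consensus(
        .copies_matrix(chars, rStarts, rLen)), collapse = "")
      spacs <- substring(seq, rStarts[-length(rStarts)] + rLen,
                         rStarts[-1L] - 1L)
      sim <- function(a, b) {
        L <- min(nchar(a), nchar(b))
        mean(.seq_chars(substring(a, 1L, L)) ==
               .seq_chars(substring(b, 1L, L)))
      }
      if (any(vapply(spacs, sim, numeric(1), b = consTmp) >= 0.8)) next
      if (length(spacs) > 1L &&
          any(vapply(seq_len(length(spacs) - 1L), function(i)
            sim(spacs[i], spacs[i + 1L]), numeric(1)) >= 0.8)) next
      sig <- paste(rStarts, collapse = ",")
      sig <- paste0(sig, ":", rLen)
      if (sig %in% sigs) next
      sigs <- c(sigs, sig)
      mat <- .copies_matrix(chars, rStarts, rLen)
      cons <- .column_consensus(mat)
      mism <- sum(t(mat) != cons)
      candidates[[length(candidates) + 1L]] <-
        list(starts = rStarts, len = rLen, mism = mism)
      }
    }
  }
  if (!length(candidates)) return(list())

  # maximal non-overlapping: more repeats first, then the best
  # CRT-like similarity score (a clean column adds its matches, a noisy
  # one is penalized), then leftmost
  nrep <- vapply(candidates, function(c) length(c$starts), integer(1))
  left <- vapply(candidates, function(c) c$starts[1L], integer(1))
  len <- vapply(candidates, function(c) c$len, integer(1))
  mism <- vapply(candidates, function(c) c$mism, numeric(1))
  # quality: matched characters minus a penalty that makes a column with
  # one dissenting copy a net loss (boundary columns are optional; a
  # mutated interior column is paid by every candidate width alike)
  qual <- nrep * len - (nrep + 1) * mism
  ord <- order(-nrep, -qual, left)
  chosen <- list()
  occupied <- IRanges::IRanges()
  for (idx in ord) {
    cand <- candidates[[idx]]
    rng <- IRanges::IRanges(cand$starts[1L],
                            cand$starts[length(cand$starts)] + cand$len - 1L)
    if (length(occupied) &&
        any(IRanges::overlapsAny(rng, occupied))) next
    occupied <- c(occupied, rng)
    chosen[[length(chosen) + 1L]] <- cand
  }
  chosen <- chosen[order(vapply(chosen, function(c) c$starts[1L],
                                integer(1)))]
  lapply(chosen, function(cand) {
    rs <- cand$starts; len <- cand$len
    repeats <- IRanges::IRanges(rs, width = len)
    spacers <- IRanges::IRanges(rs[-length(rs)] + len,
                                rs[-1L] - 1L)
    cons <- paste(.column_consensus(.copies_matrix(chars, rs, len)),
                  collapse = "")
    new("CrisprArray", contigId = contigId, repeats = repeats,
        spacers = spacers, consensusRepeat = cons,
        orientation = "unknown")
  })
}

# ---- methods ---------------------------------------------------------------

#' @describeIn findArrays scan a single sequence given as a character
#'   string; `contigId` names the source contig in the result.
#' @param contigId contig identifier recorded on the resulting arrays.
#' @export
setMethod("findArrays", "character",
  function(x, params = detectorParams(), contigId = "contig") {
    stopifnot(length(x) == 1L)
    s <- toupper(x)
    if (!grepl("^[ACGTN]*$", s))
      stop("non-DNA character in contig sequence")
    .find_arrays_chr(s, params, contigId)
  })

#' @describeIn findArrays scan a [Biostrings::DNAString].
#' @export
setMethod("findArrays", "DNAString",
  function(x, params = detectorParams(), contigId = "contig") {
    findArrays(as.character(x), params, contigId = contigId)
  })

#' @describeIn findArrays scan every contig of a
#'   [Biostrings::DNAStringSet]; contig ids are taken from `names(x)`.
#' @export
setMethod("findArrays", "DNAStringSet",
  function(x, params = detectorParams()) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("contig_", seq_along(x))
    out <- list()
    for (i in seq_along(x)) {
      out <- c(out, findArrays(as.character(x[[i]]), params,
                               contigId = ids[i]))
    }
    out
  })

#' @describeIn consensusRepeat majority-rule consensus stored on the
#'   array; when `contig` is supplied the consensus is recomputed from the
#'   contig sequence (per-column majority over the aligned equal-length
#'   repeat copies, ties broken by the earliest copy).
#' @param contig optional contig sequence (character or
#'   [Biostrings::DNAString]) to recompute the consensus from.
#' @param ... unused.
#' @export
setMethod("consensusRepeat", "CrisprArray", function(x, contig = NULL, ...) {
  if (is.null(contig)) return(x@consensusRepeat)
  s <- toupper(as.character(contig))
  chars <- .seq_chars(s)
  mat <- .copies_matrix(chars, IRanges::start(x@repeats),
                        IRanges::width(x@repeats)[1])
  paste(.column_consensus(mat), collapse = "")
})

#' Summarise arrays as a data.frame
#'
#' One row per array: contig, footprint start/end (1-based closed),
#' repeat count, spacer count, repeat length and consensus.
#'
#' @param arrays list of [CrisprArray-class] objects.
#' @return a data.frame.
#' @export
arrayTable <- function(arrays) {
  if (!length(arrays)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), n_repeats = integer(),
                      n_spacers = integer(), repeat_len = integer(),
                      consensus = character(),
                      orientation = character()))
  }
  do.call(rbind, lapply(arrays, function(a) {
    rng <- arrayRange(a)
    data.frame(contig = contigId(a), start = IRanges::start(rng),
               end = IRanges::end(rng), n_repeats = nRepeats(a),
               n_spacers = nSpacers(a),
               repeat_len = nchar(a@consensusRepeat),
               consensus = a@consensusRepeat,
               orientation = arrayOrientation(a))
  }))
}

#' Write arrays to GFF3
#'
#' Emits one `CRISPR` feature per array and one `repeat_region` feature
#' per repeat copy, 1-based inclusive per the GFF3 standard.
#'
#' @param arrays list of [CrisprArray-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
arraysToGff3 <- function(arrays, path) {
  rows <- list()
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    rng <- arrayRange(a)
    id <- sprintf("array%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = contigId(a), type = "CRISPR",
      start = IRanges::start(rng), end = IRanges::end(rng),
      strand = ".", attributes = sprintf(
        "ID=%s;n_repeats=%d;consensus=%s", id, nRepeats(a),
        a@consensusRepeat))
    reps <- repeatRanges(a)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = contigId(a), type = "repeat_region",
      start = IRanges::start(reps), end = IRanges::end(reps),
      strand = ".",
      attributes = sprintf("Parent=%s", id))
  }
  writeGff3(do.call(rbind, rows), path)
}
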