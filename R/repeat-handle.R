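#' @include AllClasses.R
NULL

.rna_chars <- function(rna) .seq_chars(chartr("T", "U", toupper(rna)))

.can_pair <- function(x, y, allowGU = TRUE) {
  wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (allowGU) wc | (x == "G" & y == "U") | (x == "U" & y == "G") else wc
}

#' Fold an RNA into its best single hairpin
#'
#' Exhaustive search over single-hairpin structures: one helix, an
#' optional single internal bulge of at most 2 nt on one side, and a
#' terminal loop of at least 3 nt. Among all such structures the one with
#' the most base pairs wins; ties are broken by the smaller loop, then by
#' the 5'-most helix. Pairs may be Watson-Crick or (by default) G.U
#' wobble. This is a deliberate approximation of the Cas12a 5' handle
#' fold --- no thermodynamic model, no pseudoknot (see the package
#' vignette).
#'
#' @param rna RNA (or DNA, transcribed on the fly) string of length >=
#'   10.
#' @param allowGU allow G.U wobble pairs (default TRUE).
#' @return list with `stemPairs` (two-column matrix of paired 1-based
#'   positions, outermost first) and `loop` (`c(start, end)`, 1-based
#'   closed; the whole sequence when no pair exists).
#' @examples
#' foldHairpin("GGGGAAACCCC")$stemPairs
#' @export
foldHairpin <- function(rna, allowGU = TRUE) {
  ch <- .rna_chars(rna)
  n <- length(ch)
  if (n < 10L) stop("sequence shorter than 10 nt")
  if (!all(ch %in% c("A", "C", "G", "U", "N")))
    stop("illegal RNA character")
  best <- list(npairs = 0L, loop = c(1L, n), firstI = NA_integer_,
               pairs = cbind(i = integer(), j = integer()))
  consider <- function(pairs) {
    np <- nrow(pairs)
    a <- pairs[np, 1L]; b <- pairs[np, 2L]
    loopLen <- b - a - 1L
    better <- np > best$npairs ||
      (np == best$npairs && np > 0L &&
         (loopLen < (best$loop[2L] - best$loop[1L] + 1L) ||
          (loopLen == (best$loop[2L] - best$loop[1L] + 1L) &&
             pairs[1L, 1L] < best$firstI)))
    if (better)
      best <<- list(npairs = np, loop = c(a + 1L, b - 1L),
                    firstI = pairs[1L, 1L], pairs = pairs)
  }
  extend <- function(pairs, bulgeUsed) {
    consider(pairs)
    a <- pairs[nrow(pairs), 1L]; b <- pairs[nrow(pairs), 2L]
    steps <- list(c(1L, 1L))
    if (!bulgeUsed)
      steps <- c(steps, list(c(2L, 1L), c(3L, 1L), c(1L, 2L), c(1L, 3L)))
    for (st in steps) {
      a2 <- a + st[1L]; b2 <- b - st[2L]
      if (b2 - a2 - 1L < 3L) next
      if (!.can_pair(ch[a2], ch[b2], allowGU)) next
      extend(rbind(pairs, c(a2, b2)),
             bulgeUsed || any(st != c(1L, 1L)))
    }
  }
  for (i in seq_len(n - 4L)) {
    for (j in n:(i + 4L)) {
      if (j - i - 1L < 3L) break
      if (.can_pair(ch[i], ch[j], allowGU))
        extend(cbind(i = i, j = j), FALSE)
    }
  }
  colnames(best$pairs) <- c("i", "j")
  list(stemPairs = best$pairs, loop = best$loop)
}

#' Orient a repeat consensus from handle foldability
#'
#' CRT-style detection is strand-agnostic, but the biology is not: the
#' mature crRNA 5' handle comes from the repeat 3' end and folds into a
#' stem-loop. The terminal 19 nt of the given strand and of its reverse
#' complement are folded; the strand whose terminal window yields more
#' stem pairs is the array's sense strand. A tie returns "forward" with
#' attribute `tie = TRUE`.
#'
#' @param consensus repeat consensus (DNA, length >= 20).
#' @param handleLen terminal window folded (default 19).
#' @return `"forward"` or `"reverse"`, with attributes `pairsForward`,
#'   `pairsReverse` and `tie`.
#' @export
orientArray <- function(consensus, handleLen = 19L) {
  s <- toupper(as.character(consensus))
  if (nchar(s) < 20L) stop("consensus shorter than 20 nt")
  term <- function(x) substring(x, nchar(x) - handleLen + 1L)
  fwd <- nrow(foldHairpin(term(s))$stemPairs)
  rev <- nrow(foldHairpin(term(revComp(s)))$stemPairs)
  out <- if (fwd >= rev) "forward" else "reverse"
  attr(out, "pairsForward") <- fwd
  attr(out, "pairsReverse") <- rev
  attr(out, "tie") <- fwd == rev
  if (fwd == rev)
    warning("handle fold does not discriminate strands; ",
            "defaulting to forward")
  out
}

#' Predict the crRNA maturation cut within a direct repeat
#'
#' Cas12a processes its pre-crRNA inside the direct repeat, discarding
#' the repeat 5' portion and retaining a fixed-length 3' suffix as the
#' mature crRNA 5' handle. The cut is placed `handleLen` nt from the
#' repeat 3' end (default 19 nt, configurable 18--20); the retained
#' suffix is transcribed and folded with [foldHairpin()].
#'
#' @param directRepeat oriented direct repeat (DNA string).
#' @param handleLen retained handle length in nt.
#' @return a [RepeatHandle-class] object.
#' @examples
#' rh <- predictMaturationSite("GTCTAAGAACTTTAAATAATTTCTACTGTTGTAGAT")
#' rh
#' @export
predictMaturationSite <- function(directRepeat, handleLen = 19L) {
  s <- toupper(as.character(directRepeat))
  if (!grepl("^[ACGT]+$", s)) stop("direct repeat must be DNA")
  handleLen <- as.integer(handleLen)
  if (nchar(s) < handleLen)
    stop("repeat (", nchar(s), " nt) shorter than handle length ",
         handleLen)
  cut <- nchar(s) - handleLen
  handle <- chartr("T", "U", substring(s, cut + 1L))
  fold <- foldHairpin(handle)
  new("RepeatHandle", directRepeat = s, maturationCut = cut,
      handle = handle, stemPairs = fold$stemPairs,
      loop = as.integer(fold$loop))
}

#' Accessors for RepeatHandle objects
#' @param x a [RepeatHandle-class] object.
#' @return `handleSeq`: the mature handle (RNA); `maturationCut`: number
#'   of nt removed from the repeat 5' end; `stemPairs`: the paired
#'   positions; `removedSeq`: the discarded 5' portion (DNA).
#' @name RepeatHandle-accessors
#' @export
handleSeq <- function(x) x@handle

#' @rdname RepeatHandle-accessors
#' @export
maturationCut <- function(x) x@maturationCut

#' @rdname RepeatHandle-accessors
#' @export
stemPairs <- function(x) x@stemPairs

#' @rdname RepeatHandle-accessors
#' @export
removedSeq <- function(x) substring(x@directRepeat, 1L, x@maturationCut)

#' Reference 5' handle sequences
#'
#' Mature crRNA 5' handle sequences of the three workhorse Cas12a
#' orthologs (AsCas12a, FnCas12a, LbCas12a), shipped as an editable FASTA
#' file (`inst/extdata/handle_references.fa`). These are the canonical
#' handle sequences from the Cas12a literature; replace or extend the
#' file (or pass your own named vector to [classifyHandle()]) to use a
#' different reference set.
#'
#' @param path optional path to an alternative reference FASTA.
#' @return named character vector of RNA handle sequences.
#' @export
handleReferences <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "handle_references.fa",
                        package = "casProspector")
  x <- readBStringSet(path)
  out <- chartr("T", "U", toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Classify a mature handle against reference handles
#'
#' Right-justifies each reference against the query (padding the shorter
#' sequence on the 5' side --- handles are anchored at their 3' end, next
#' to the spacer) and counts Hamming mismatches; pad-versus-base
#' positions count as mismatches. Mismatches falling inside the query's
#' folded loop are reported separately, since known orthologs differ
#' mostly at the loop. Best reference = fewest total mismatches, ties
#' broken alphabetically.
#'
#' @param handle query handle (RNA string) or a [RepeatHandle-class].
#' @param refs named character vector of reference handles (default
#'   [handleReferences()]).
#' @return list with `best`, `mismatches`, `loopMismatches`, and `table`
#'   (per-reference data.frame).
#' @export
classifyHandle <- function(handle, refs = handleReferences()) {
  if (is(handle, "RepeatHandle")) {
    loop <- handle@loop
    q <- handle@handle
  } else {
    q <- chartr("T", "U", toupper(as.character(handle)))
    loop <- foldHairpin(q)$loop
  }
  if (!length(refs)) stop("empty reference set")
  if (is.null(names(refs))) stop("references must be named")
  qc <- .rna_chars(q)
  res <- lapply(names(refs), function(nm) {
    rc <- .rna_chars(refs[[nm]])
    L <- max(length(qc), length(rc))
    pad <- function(v) c(rep("-", L - length(v)), v)
    qq <- pad(qc); rr <- pad(rc)
    mm <- qq != rr
    # map padded columns back to query positions to test loop membership
    qpos <- cumsum(qq != "-")
    inLoop <- qq != "-" & qpos >= loop[1L] & qpos <= loop[2L]
    data.frame(ref = nm, mismatches = sum(mm),
               loop_mismatches = sum(mm & inLoop))
  })
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$mismatches, tab$ref), ]
  rownames(tab) <- NULL
  list(best = tab$ref[1L], mismatches = tab$mismatches[1L],
       loopMismatches = tab$loop_mismatches[1L], table = tab)
}

#' Full handle analysis of a detected array
#'
#' Orients the array consensus, predicts the maturation cut, folds the
#' handle and classifies it against the reference set.
#'
#' @param array a [CrisprArray-class].
#' @param handleLen handle length (default 19).
#' @param refs reference handles (default [handleReferences()]).
#' @return list with `orientation`, `repeatOriented`, `handle` (a
#'   [RepeatHandle-class]) and `classification`.
#' @export
analyzeArrayHandle <- function(array, handleLen = 19L,
                               refs = handleReferences()) {
  cons <- consensusRepeat(array)
  ori <- orientArray(cons, handleLen = handleLen)
  oriented <- if (ori == "reverse") revComp(cons) else cons
  rh <- predictMaturationSite(oriented, handleLen = handleLen)
  cls <- classifyHandle(rh, refs = refs)
  list(orientation = as.character(ori), repeatOriented = oriented,
       handle = rh, classification = cls)
}
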