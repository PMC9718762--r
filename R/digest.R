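#' @importFrom Biostrings matchPattern IUPAC_CODE_MAP
NULL

#' Find PAM sites on both strands
#'
#' Matches an IUPAC pattern (default `TTTV`, the Cas12a PAM; `V` =
#' A/C/G) against both strands. Positions are reported on the forward
#' axis as 1-based closed intervals; overlapping matches are all
#' reported.
#'
#' @param dna target sequence (character or [Biostrings::DNAString]).
#' @param pam IUPAC pattern (default `"TTTV"`).
#' @return data.frame with `start`, `end` (forward axis) and `strand`.
#' @examples
#' findPamSites("TTTAGG")          # one + site
#' findPamSites("TTTT", "TTTV")    # empty: V excludes T
#' @export
findPamSites <- function(dna, pam = "TTTV") {
  pam <- toupper(pam)
  if (!all(.seq_chars(pam) %in% names(IUPAC_CODE_MAP)))
    stop("invalid IUPAC letter in PAM pattern: ", pam)
  s <- toupper(as.character(dna))
  n <- nchar(s)
  subj <- DNAString(s)
  hit <- function(x, strand) {
    m <- matchPattern(pam, x, fixed = FALSE)
    if (!length(m)) {
      return(data.frame(start = integer(), end = integer(),
                        strand = character()))
    }
    st <- IRanges::start(m); en <- IRanges::end(m)
    if (strand == "-") {  # map minus-strand coords to the forward axis
      tmp <- st
      st <- n - en + 1L
      en <- n - tmp + 1L
    }
    data.frame(start = st, end = en, strand = strand)
  }
  out <- rbind(hit(subj, "+"), hit(reverseComplement(subj), "-"))
  # matches containing N in the subject are rejected
  if (nrow(out)) {
    win <- substring(s, out$start, out$end)
    out <- out[!grepl("N", win, fixed = TRUE), , drop = FALSE]
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.no_cut_result <- function(n) {
  new("DigestResult", targetLen = n, pamStart = 0L, pamEnd = 0L,
      strand = "*", protoStart = 0L, protoEnd = 0L,
      cutNonTarget = NA_integer_, cutTarget = NA_integer_,
      overhang = 0L, fragments = n)
}

#' In-silico Cas12a digestion
#'
#' Scans the target for PAM sites (both strands), requires the spacer to
#' match the sequence immediately 3' of the PAM (exact by default), and
#' predicts the staggered cut. Cas12a cuts the non-target
#' (protospacer-bearing) strand `ntsCut` nt and the target strand
#' `tsCut` nt 3' of the PAM (defaults 18 and 23: the canonical 5-nt
#' 5'-overhang geometry; the enzyme's stagger is documented but the exact
#' offsets are configuration values). Fragment lengths are computed at
#' the non-target-strand (PAM-proximal) cut; both cut coordinates are
#' retained on the result.
#'
#' @param target target DNA (character or [Biostrings::DNAString]).
#' @param spacer crRNA spacer written as DNA (18--25 nt).
#' @param pam IUPAC PAM pattern (default `"TTTV"`).
#' @param ntsCut,tsCut cut offsets in nt 3' of the PAM on the non-target
#'   and target strands.
#' @param maxMismatch protospacer mismatches tolerated (default 0).
#' @param circular treat the target as circular (a single site then
#'   yields one linear fragment).
#' @return a list of [DigestResult-class] objects, one per cut site; a
#'   single no-cut result (fragments = target length) when no
#'   PAM-adjacent match exists.
#' @examples
#' t <- paste0(strrep("G", 40), "TTTA", strrep("A", 23), strrep("G", 33))
#' inSilicoDigest(t, strrep("A", 23))[[1]]
#' @export
inSilicoDigest <- function(target, spacer, pam = "TTTV", ntsCut = 18L,
                           tsCut = 23L, maxMismatch = 0L,
                           circular = FALSE) {
  s <- toupper(as.character(target))
  n <- nchar(s)
  sp <- toupper(as.character(spacer))
  sp <- chartr("U", "T", sp)
  if (!grepl("^[ACGT]+$", sp)) stop("spacer must be DNA over {A,C,G,T}")
  L <- nchar(sp)
  if (L < 18L || L > 25L) stop("spacer length must be 18-25 nt")
  ntsCut <- as.integer(ntsCut); tsCut <- as.integer(tsCut)
  sites <- findPamSites(s, pam)
  spc <- .seq_chars(sp)
  rc <- revComp(s)
  hits <- list()
  for (r in seq_len(nrow(sites))) {
    st <- sites$start[r]; en <- sites$end[r]; str <- sites$strand[r]
    if (str == "+") {
      q <- en + 1L                       # protospacer start, fwd axis
      if (q + L - 1L > n) next
      win <- substring(s, q, q + L - 1L)
    } else {
      qr <- (n - st + 1L) + 1L           # start on the reverse strand
      if (qr + L - 1L > n) next
      win <- substring(rc, qr, qr + L - 1L)
    }
    if (grepl("N", win, fixed = TRUE)) next
    if (sum(.seq_chars(win) != spc) > maxMismatch) next
    if (str == "+") {
      protoStart <- q; protoEnd <- q + L - 1L
      cutNts <- (q - 1L) + ntsCut        # nt 5' of the cut, fwd axis
      cutTs <- (q - 1L) + tsCut
    } else {
      protoEnd <- n - qr + 1L
      protoStart <- protoEnd - L + 1L
      cutNts <- n - ((qr - 1L) + ntsCut) # reverse-strand cut mapped back
      cutTs <- n - ((qr - 1L) + tsCut)
    }
    if (!circular && (cutNts < 1L || cutNts >= n)) next
    hits[[length(hits) + 1L]] <- list(
      pamStart = st, pamEnd = en, strand = str,
      protoStart = protoStart, protoEnd = protoEnd,
      cutNts = cutNts, cutTs = cutTs)
  }
  if (!length(hits)) return(list(.no_cut_result(n)))
  cuts <- vapply(hits, `[[`, integer(1), "cutNts")
  lapply(hits, function(h) {
    frags <- if (circular) {
      if (length(cuts) == 1L) n else {
        cs <- sort(unique(cuts))
        diff(c(cs, cs[1L] + n))
      }
    } else {
      c(h$cutNts, n - h$cutNts)
    }
    new("DigestResult", targetLen = n,
        pamStart = h$pamStart, pamEnd = h$pamEnd, strand = h$strand,
        protoStart = h$protoStart, protoEnd = h$protoEnd,
        cutNonTarget = h$cutNts, cutTarget = h$cutTs,
        overhang = abs(h$cutTs - h$cutNts),
        fragments = as.integer(frags))
  })
}

#' Cleavage efficiency from band intensities
#'
#' The gel-densitometry rule: cleaved fraction of total lane signal,
#' `100 * sum(cut) / (uncut + sum(cut))`.
#'
#' @param uncut intensity of the undigested band (>= 0).
#' @param cut numeric vector of cleaved-band intensities (possibly
#'   empty).
#' @return efficiency in percent.
#' @examples
#' cleavageEfficiency(20, c(48, 32))  # 80
#' @export
cleavageEfficiency <- function(uncut, cut = numeric()) {
  if (any(c(uncut, cut) < 0)) stop("intensities must be nonnegative")
  tot <- uncut + sum(cut)
  if (tot <= 0) stop("all band intensities are zero")
  100 * sum(cut) / tot
}

#' Editing efficiency from a T7E1 (or substrate-depletion) readout
#'
#' `correction = "none"` reads editing off the disappearance of the
#' substrate band: `100 * (1 - treated / control)`. The
#' `"indel_formula"` mode applies the standard mismatch-cleavage indel
#' estimate `100 * (1 - sqrt(uncut_fraction))`, requiring the cleaved
#' band intensities.
#'
#' @param treated substrate-band intensity after treatment.
#' @param control substrate-band intensity in the untreated control
#'   (> 0; required for `"none"`).
#' @param correction `"none"` (default) or `"indel_formula"`.
#' @param cutIntensities cleaved-band intensities (for
#'   `"indel_formula"`).
#' @return efficiency in percent; a treated intensity above the control
#'   clamps to 0 with a warning.
#' @examples
#' editingEfficiencyT7E1(8, 100)  # 92
#' @export
editingEfficiencyT7E1 <- function(treated, control = NULL,
                                  correction = c("none", "indel_formula"),
                                  cutIntensities = NULL) {
  correction <- match.arg(correction)
  if (correction == "none") {
    if (is.null(control) || control <= 0)
      stop("control intensity must be positive")
    if (treated > control) {
      warning("treated intensity exceeds control; clamping to 0%")
      return(0)
    }
    return(100 * (1 - treated / control))
  }
  if (is.null(cutIntensities) || !length(cutIntensities))
    stop("indel_formula mode requires cut band intensities")
  tot <- treated + sum(cutIntensities)
  if (tot <= 0) stop("all band intensities are zero")
  100 * (1 - sqrt(treated / tot))
}
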