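#' @importFrom Biostrings pairwiseAlignment score pattern subject
#'   alignedPattern alignedSubject AAString
#' @importFrom utils data
NULL

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.check_protein <- function(x, what = "sequence") {
  s <- toupper(as.character(x))
  if (nchar(s) == 0L) stop(what, " must be non-empty")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", s))
    stop("illegal residue in ", what,
         " (allowed: 20 standard letters plus X)")
  s
}

# columns of a pairwiseAlignment as two aligned character vectors
.aln_columns <- function(aln) {
  list(a = .seq_chars(as.character(alignedPattern(aln))),
       b = .seq_chars(as.character(alignedSubject(aln))))
}

# (query, ref) index pairs of aligned (non-gap/non-gap) columns
.aligned_pairs <- function(cols, offsetA = 0L, offsetB = 0L) {
  ia <- cumsum(cols$a != "-") + offsetA
  ib <- cumsum(cols$b != "-") + offsetB
  keep <- cols$a != "-" & cols$b != "-"
  cbind(query = ia[keep], ref = ib[keep])
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under BLOSUM62 with affine gap costs, the
#' BLASTp defaults (a gap of length L costs `gapOpen + L * gapExtend`,
#' i.e. 11 + L). Serves as the homology screen's scoring core.
#'
#' @param a,b protein sequences (character or [Biostrings::AAString]).
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings).
#' @param gapOpen,gapExtend affine gap parameters (defaults 11 and 1).
#' @return a list with `score` (raw alignment score), `alignedPairs`
#'   (two-column matrix of 1-based (query, ref) indices of aligned
#'   residues, strictly increasing in both), and `identity`
#'   (matches / aligned columns, gap columns included).
#' @examples
#' smithWaterman("HEAGAWGHEE", "PAWHEAE")$score
#' @export
smithWaterman <- function(a, b, matrix = NULL, gapOpen = 11,
                          gapExtend = 1) {
  a <- .check_protein(a, "query"); b <- .check_protein(b, "subject")
  if (is.null(matrix)) matrix <- .blosum62()
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = "local",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
  sc <- max(0, score(aln))
  cols <- .aln_columns(aln)
  offA <- IRanges::start(pattern(aln)@range) - 1L
  offB <- IRanges::start(subject(aln)@range) - 1L
  ncols <- length(cols$a)
  ident <- if (ncols && sc > 0) sum(cols$a == cols$b) / ncols else 0
  pairs <- if (sc > 0) .aligned_pairs(cols, offA, offB) else
    cbind(query = integer(), ref = integer())
  list(score = sc, alignedPairs = pairs, identity = ident)
}

#' Global alignment identity
#'
#' Needleman-Wunsch global alignment under the same matrix and gap costs
#' as [smithWaterman()]; identity is matches divided by total alignment
#' columns, gap columns included (conventions differ between tools, so
#' the denominator is stated explicitly).
#'
#' @inheritParams smithWaterman
#' @return identity fraction in `[0, 1]`.
#' @examples
#' globalIdentity("AAAA", "AAAT")  # 0.75
#' @export
globalIdentity <- function(a, b, matrix = NULL, gapOpen = 11,
                           gapExtend = 1) {
  a <- .check_protein(a); b <- .check_protein(b)
  if (is.null(matrix)) matrix <- .blosum62()
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = "global",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
  cols <- .aln_columns(aln)
  sum(cols$a == cols$b & cols$a != "-") / length(cols$a)
}

#' Raw alignment score
#'
#' Convenience accessor for the raw local or global alignment score under
#' the same scoring scheme as [smithWaterman()] / [globalIdentity()].
#'
#' @inheritParams smithWaterman
#' @param type `"local"` or `"global"`.
#' @return the raw score (local scores are floored at 0).
#' @export
alignmentScore <- function(a, b, type = c("local", "global"),
                           matrix = NULL, gapOpen = 11, gapExtend = 1) {
  type <- match.arg(type)
  a <- .check_protein(a); b <- .check_protein(b)
  if (is.null(matrix)) matrix <- .blosum62()
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = type,
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
  if (type == "local") max(0, score(aln)) else score(aln)
}

#' k-mer prefilter for bait panels
#'
#' BLAST-like seeding used to keep full local alignment affordable on
#' large panels: retain the baits sharing at least `minShared` exact
#' k-mer occurrences with the query (counted over query positions). The
#' prefilter is advisory --- it is not guaranteed to be a superset of the
#' alignment hits and can be disabled wherever it is used.
#'
#' @param query protein sequence.
#' @param baits named [Biostrings::AAStringSet] or named character.
#' @param k k-mer length (default 4).
#' @param minShared minimum shared k-mer count.
#' @return the retained subset of `baits` (same class as input).
#' @export
kmerPrefilter <- function(query, baits, k = 4L, minShared = 10L) {
  q <- .check_protein(query, "query")
  if (k > nchar(q)) stop("k exceeds query length")
  qk <- substring(q, seq_len(nchar(q) - k + 1L),
                  seq_len(nchar(q) - k + 1L) + k - 1L)
  keep <- vapply(as.character(baits), function(b) {
    if (k > nchar(b)) return(FALSE)
    bk <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                           seq_len(nchar(b) - k + 1L) + k - 1L))
    sum(qk %in% bk) >= minShared
  }, logical(1))
  baits[keep]
}

#' Screen ORFs against the Cas12a bait panel
#'
#' Applies the effector filters --- protein length within
#' `[minAa, maxAa]` residues and a methionine start --- then scores each
#' passing ORF against every bait by local alignment and keeps those
#' whose best raw score reaches `minScore`. With
#' `keepExcluded = TRUE`, ORFs failing only the methionine filter are
#' retained in the output flagged `excluded (no Met start)` rather than
#' silently dropped.
#'
#' @param orfs [GenomicRanges::GRanges] from [callOrfs()].
#' @param baits named [Biostrings::AAStringSet] or named character of
#'   Cas12a bait proteins.
#' @param minScore minimum best local alignment raw score.
#' @param minAa,maxAa protein length bounds in residues (800/1500).
#' @param usePrefilter apply [kmerPrefilter()] before alignment.
#' @param keepExcluded keep Met-filter failures, flagged.
#' @return an [S4Vectors::DataFrame], one row per candidate, sorted by
#'   score descending: `orf_index`, `contig`, `start`, `end`, `strand`,
#'   `aa_len`, `best_bait`, `sw_score`, `identity_to_best`,
#'   `passes_length`, `passes_start_met`, `passed`, `note`.
#' @export
screenCandidates <- function(orfs, baits, minScore = 200,
                             minAa = 800L, maxAa = 1500L,
                             usePrefilter = FALSE,
                             keepExcluded = FALSE) {
  if (length(baits) == 0L) stop("empty bait panel")
  baitSeq <- as.character(baits)
  names(baitSeq) <- names(baits)
  if (is.null(names(baitSeq)))
    names(baitSeq) <- paste0("bait_", seq_along(baitSeq))
  rows <- list()
  for (i in seq_along(orfs)) {
    prot <- mcols(orfs)$protein[i]
    aaLen <- mcols(orfs)$aa_len[i]
    passesLength <- aaLen >= minAa && aaLen <= maxAa
    passesMet <- substring(prot, 1L, 1L) == "M"
    if (!passesLength) next
    if (!passesMet && !keepExcluded) next
    panel <- baitSeq
    if (usePrefilter) {
      panel <- kmerPrefilter(prot, baitSeq)
      if (!length(panel)) panel <- baitSeq  # advisory only
    }
    scores <- vapply(panel, function(b) smithWaterman(prot, b)$score,
                     numeric(1))
    best <- which.max(scores)
    if (scores[best] < minScore) next
    rows[[length(rows) + 1L]] <- DataFrame(
      orf_index = i,
      contig = as.character(seqnames(orfs))[i],
      start = GenomicRanges::start(orfs)[i],
      end = GenomicRanges::end(orfs)[i],
      strand = as.character(strand(orfs))[i],
      aa_len = aaLen,
      best_bait = names(panel)[best],
      sw_score = unname(scores[best]),
      identity_to_best = globalIdentity(prot, panel[[best]]),
      passes_length = passesLength,
      passes_start_met = passesMet,
      passed = passesLength && passesMet,
      note = if (passesMet) "" else "excluded (no Met start)")
  }
  if (!length(rows)) {
    return(DataFrame(orf_index = integer(), contig = character(),
                     start = integer(), end = integer(),
                     strand = character(), aa_len = integer(),
                     best_bait = character(), sw_score = numeric(),
                     identity_to_best = numeric(),
                     passes_length = logical(),
                     passes_start_met = logical(), passed = logical(),
                     note = character()))
  }
  out <- do.call(rbind, rows)
  out[order(-out$sw_score), ]
}

#' Map reference residue positions onto a query protein
#'
#' Aligns `query` and `ref` globally and reports, for each requested
#' 1-based reference position, the query residue index aligned to it, or
#' `NA` when the reference residue faces a gap. Used to transfer known
#' catalytic residues (e.g. the RuvC aspartate/glutamate of
#' characterized Cas12a proteins) onto new candidates.
#'
#' @param query,ref protein sequences.
#' @param refPositions integer vector of 1-based residue indices in
#'   `ref`.
#' @inheritParams smithWaterman
#' @return named integer vector (names = reference positions), `NA` for
#'   gapped positions.
#' @export
mapResidues <- function(query, ref, refPositions, matrix = NULL,
                        gapOpen = 11, gapExtend = 1) {
  q <- .check_protein(query, "query"); r <- .check_protein(ref, "ref")
  refPositions <- as.integer(refPositions)
  if (any(refPositions < 1L | refPositions > nchar(r)))
    stop("refPositions out of range 1..", nchar(r))
  if (is.null(matrix)) matrix <- .blosum62()
  aln <- pairwiseAlignment(AAString(q), AAString(r), type = "global",
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend)
  cols <- .aln_columns(aln)
  qi <- cumsum(cols$a != "-")
  ri <- cumsum(cols$b != "-")
  out <- vapply(refPositions, function(p) {
    col <- match(p, ri)
    if (is.na(col) || cols$a[col] == "-") NA_integer_ else qi[col]
  }, integer(1))
  names(out) <- refPositions
  out
}

# ---- isoelectric point -----------------------------------------------------

# Bjellqvist pKa set (as used by the ExPASy pI tool): side chains,
# C-terminus (with Asp/Glu-specific values) and residue-specific
# N-terminal pKa.
.PK_BJELLQVIST <- list(
  side = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
           R = 12.00, Y = 10.00),
  cterm = 3.55,
  cterm_special = c(D = 4.55, E = 4.75),
  nterm_default = 7.50,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
            V = 7.44, E = 7.70)
)

# EMBOSS (iep) pKa set.
.PK_EMBOSS <- list(
  side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
           Y = 10.1),
  cterm = 3.6, cterm_special = c(),
  nterm_default = 8.6, nterm = c()
)

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the D, E, C, Y, H, K, R
#' side chains. `X` residues contribute no charge.
#'
#' @param p protein sequence.
#' @param pH pH value(s).
#' @param pkSet `"bjellqvist"` (default) or `"emboss"`.
#' @return numeric vector of net charges, one per pH.
#' @export
netCharge <- function(p, pH, pkSet = c("bjellqvist", "emboss")) {
  pkSet <- match.arg(pkSet)
  pk <- if (pkSet == "bjellqvist") .PK_BJELLQVIST else .PK_EMBOSS
  s <- .check_protein(p)
  aa <- .seq_chars(s)
  first <- aa[1L]; last <- aa[length(aa)]
  ntermPk <- if (first %in% names(pk$nterm)) pk$nterm[[first]] else
    pk$nterm_default
  ctermPk <- if (last %in% names(pk$cterm_special))
    pk$cterm_special[[last]] else pk$cterm
  counts <- table(aa)
  cnt <- function(r) if (r %in% names(counts)) counts[[r]] else 0L
  vapply(pH, function(ph) {
    pos <- 1 / (1 + 10^(ph - ntermPk)) +
      cnt("K") / (1 + 10^(ph - pk$side[["K"]])) +
      cnt("R") / (1 + 10^(ph - pk$side[["R"]])) +
      cnt("H") / (1 + 10^(ph - pk$side[["H"]]))
    neg <- 1 / (1 + 10^(ctermPk - ph)) +
      cnt("D") / (1 + 10^(pk$side[["D"]] - ph)) +
      cnt("E") / (1 + 10^(pk$side[["E"]] - ph)) +
      cnt("C") / (1 + 10^(pk$side[["C"]] - ph)) +
      cnt("Y") / (1 + 10^(pk$side[["Y"]] - ph))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' Bisection on [netCharge()] over pH 0--14 until the net charge is
#' within `tol` of zero.
#'
#' @inheritParams netCharge
#' @param tol convergence tolerance on the net charge (default 1e-4).
#' @return the pI (pH at zero net charge).
#' @examples
#' isoelectricPoint("GG")  # midpoint of the terminal pKa pair: 5.525
#' @export
isoelectricPoint <- function(p, pkSet = c("bjellqvist", "emboss"),
                             tol = 1e-4) {
  pkSet <- match.arg(pkSet)
  lo <- 0; hi <- 14
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    ch <- netCharge(p, mid, pkSet)
    if (abs(ch) < tol) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}
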