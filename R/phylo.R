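#' @importFrom ape read.tree write.tree prop.clades
#' @importFrom stats setNames
NULL

#' Pairwise distance matrix from protein sequences
#'
#' `d[i, j] = 1 - globalIdentity(i, j)` (p-distance on the global
#' alignment). A Poisson correction `-ln(1 - p)` is available for
#' multiple substitutions; the default is the uncorrected p-distance
#' since candidate screening only needs relative placement.
#'
#' @param seqs named [Biostrings::AAStringSet] or named character vector
#'   (>= 3 sequences, unique labels).
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal, labelled.
#' @export
distanceMatrix <- function(seqs, model = c("p", "poisson")) {
  model <- match.arg(model)
  s <- as.character(seqs)
  names(s) <- names(seqs)
  labels <- names(s)
  if (is.null(labels)) stop("sequences must be named")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(s) < 3L) stop("need at least 3 sequences")
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- 1 - globalIdentity(s[[i]], s[[j]])
      if (model == "poisson") p <- -log(max(1 - p, .Machine$double.eps))
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion `(n-2) d_ij - r_i - r_j`, with branch lengths
#' `v_i = d_ij/2 + (r_i - r_j)/(2(n-2))` and distances to the new node
#' `d_uk = (d_ik + d_jk - d_ij)/2`. Negative branch lengths are clamped
#' to zero with the deficit moved to the sibling branch; ties on the
#' Q-criterion are broken by the smallest (i, j) index pair in the
#' current matrix order. On additive matrices NJ recovers the generating
#' tree exactly.
#'
#' @param D symmetric distance matrix with labels (e.g. from
#'   [distanceMatrix()]).
#' @return an unrooted `phylo` object (class from \pkg{ape}).
#' @export
njTree <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  n0 <- nrow(D)
  if (n0 < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("distances must be finite")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  # each active node carries a Newick fragment (label or subtree)
  frag <- labels
  d <- D
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest (i, j) pair among ties: scan in lexicographic order
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (q[i, j] < bestQ - 1e-12) { bestQ <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi),
                       frag[j], fmt(vj))
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    frag <- c(frag[keep], newFrag)
    d <- d2
  }
  # final three-way join
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(v1),
                 frag[2], fmt(v2), frag[3], fmt(v3))
  read.tree(text = nwk)
}

# pairwise-deletion p-distance on an alignment matrix (rows = taxa,
# single characters; "-" and "." are gaps)
.pdist_pairwise_deletion <- function(aln) {
  n <- nrow(aln)
  labels <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- aln == "-" | aln == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      p <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 0
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Coerce aligned sequences to a character matrix
#'
#' @param aln named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = taxa).
#' @return character matrix with rownames.
#' @export
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop("alignment matrix must have rownames")
    return(aln)
  }
  if (is.null(names(aln))) stop("aligned sequences must be named")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Bootstrap support for NJ splits
#'
#' Resamples alignment columns with replacement `nReps` times, rebuilds
#' the NJ tree from pairwise-deletion p-distances for each replicate, and
#' reports the fraction of replicates containing each internal split of
#' the original tree. Reproducible under a fixed seed.
#'
#' @param aln user-supplied multiple sequence alignment (named character
#'   vector of equal-length strings, or character matrix).
#' @param nReps number of bootstrap replicates (> 0).
#' @param seed integer RNG seed.
#' @return the original NJ `phylo` with `node.label` set to support
#'   fractions; attribute `degenerate` flags an all-identical-column
#'   alignment (supports are then arbitrary).
#' @export
bootstrapSupport <- function(aln, nReps = 100L, seed = 1L) {
  nReps <- as.integer(nReps)
  if (nReps <= 0L) stop("nReps must be positive")
  m <- alignmentMatrix(aln)
  degenerate <- all(apply(m, 2L, function(col)
    length(unique(col)) == 1L))
  tree <- njTree(.pdist_pairwise_deletion(m))
  set.seed(as.integer(seed))
  reps <- vector("list", nReps)
  for (b in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- njTree(.pdist_pairwise_deletion(m[, cols,
                                                   drop = FALSE]))
  }
  counts <- prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- nReps  # the (trivial) root split
  tree$node.label <- counts / nReps
  attr(tree, "degenerate") <- degenerate
  if (degenerate)
    warning("alignment columns are all constant; ",
            "bootstrap supports are arbitrary")
  tree
}

#' Write / read Newick
#'
#' Thin wrappers over [ape::write.tree] and [ape::read.tree] so tree
#' serialization goes through one audited door. Support values (if any)
#' are serialized as internal node labels after the closing parenthesis.
#'
#' @param tree a `phylo` object.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeNewick
#' @param text Newick string (alternative to `path`).
#' @export
readNewick <- function(path = NULL, text = NULL) {
  if (is.null(text)) read.tree(path) else read.tree(text = text)
}
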