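# Independent reference implementations used as test oracles. These are
# deliberately written with different algorithms/data layouts than the
# package code paths they check.

.oracle_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Gotoh affine-gap DP; a gap of length L costs open + L * ext.
# type = "local" returns the best cell; "global" the corner.
oracleAlignScore <- function(a, b, open = 11, ext = 1,
                             type = c("local", "global")) {
  type <- match.arg(type)
  mat <- .oracle_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # A against gap
  Y <- matrix(NEG, n + 1, m + 1)  # B against gap
  local <- type == "local"
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
    for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- if (local) max(prev + s, s) else prev + s
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1],
                           Y[n + 1, m + 1])
}

# range of identity (matches / columns) over ALL optimal global
# alignments, by DFS over optimal tracebacks of the Gotoh matrices
oracleGlobalIdentityRange <- function(a, b, open = 11, ext = 1,
                                      maxPaths = 20000) {
  mat <- .oracle_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
    }
  }
  idents <- c()
  paths <- 0L
  eq <- function(u, v) abs(u - v) < 1e-9
  walk <- function(i, j, state, matches, cols) {
    if (paths > maxPaths) return()
    if (i == 1 && j == 1 && state == "M") {
      idents <<- c(idents, matches / cols)
      paths <<- paths + 1L
      return()
    }
    if (state == "M") {
      if (i > 1 && j > 1) {
        s <- mat[A[i - 1], B[j - 1]]
        mm <- matches + (A[i - 1] == B[j - 1])
        for (st in c("M", "X", "Y")) {
          val <- switch(st, M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                        Y = Y[i - 1, j - 1])
          if (eq(M[i, j], val + s)) walk(i - 1, j - 1, st, mm, cols + 1)
        }
      }
    } else if (state == "X") {
      if (i > 1) {
        if (eq(X[i, j], M[i - 1, j] - (open + ext)))
          walk(i - 1, j, "M", matches, cols + 1)
        if (eq(X[i, j], X[i - 1, j] - ext))
          walk(i - 1, j, "X", matches, cols + 1)
        if (i == 2 && j == 1) {  # boundary column of X
          idents <<- c(idents, matches / (cols + 1))
          paths <<- paths + 1L
        }
      }
    } else {
      if (j > 1) {
        if (eq(Y[i, j], M[i, j - 1] - (open + ext)))
          walk(i, j - 1, "M", matches, cols + 1)
        if (eq(Y[i, j], Y[i, j - 1] - ext))
          walk(i, j - 1, "Y", matches, cols + 1)
        if (j == 2 && i == 1) {
          idents <<- c(idents, matches / (cols + 1))
          paths <<- paths + 1L
        }
      }
    }
  }
  final <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  for (st in c("M", "X", "Y")) {
    val <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                  Y = Y[n + 1, m + 1])
    if (eq(val, final)) walk(n + 1, m + 1, st, 0, 0)
  }
  range(idents)
}

# exhaustive single-hairpin enumerator: outer contiguous run, optional
# one-sided bulge of 1-2 nt, inner contiguous run; returns max pair count
oracleHairpinPairs <- function(rna, allowGU = TRUE) {
  ch <- strsplit(chartr("T", "U", toupper(rna)), "")[[1]]
  n <- length(ch)
  pairOK <- function(x, y) {
    ok <- paste0(x, y) %in% c("AU", "UA", "GC", "CG")
    if (allowGU) ok <- ok || paste0(x, y) %in% c("GU", "UG")
    ok
  }
  runLen <- function(i, j) {
    # longest contiguous helix starting at pair (i, j), keeping loop >= 3
    L <- 0L
    while (i + L <= n && j - L >= 1 && (j - L) - (i + L) - 1 >= 3 &&
           pairOK(ch[i + L], ch[j - L])) L <- L + 1L
    L
  }
  best <- 0L
  for (i in 1:(n - 4)) {
    for (j in n:(i + 4)) {
      # no-bulge helices (every prefix of the maximal run is a structure)
      L1max <- runLen(i, j)
      best <- max(best, L1max)
      if (L1max == 0L) next
      # one bulge after L1 pairs (L1 >= 1), gap g on one side
      for (L1 in 1:L1max) {
        for (g in 1:2) {
          # bulge on the 5' side
          i2 <- i + L1 + g; j2 <- j - L1
          if (i2 <= n && j2 >= 1 && j2 - i2 - 1 >= 3)
            best <- max(best, L1 + runLen(i2, j2))
          # bulge on the 3' side
          i3 <- i + L1; j3 <- j - L1 - g
          if (i3 <= n && j3 >= 1 && j3 - i3 - 1 >= 3)
            best <- max(best, L1 + runLen(i3, j3))
        }
      }
    }
  }
  best
}

# position-by-position IUPAC matcher (forward and reverse strand)
oraclePamSites <- function(dna, pam) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s <- strsplit(toupper(dna), "")[[1]]
  p <- strsplit(toupper(pam), "")[[1]]
  k <- length(p); n <- length(s)
  out <- data.frame(start = integer(), end = integer(),
                    strand = character())
  if (n < k) return(out)
  for (st in 1:(n - k + 1)) {
    win <- s[st:(st + k - 1)]
    if (any(win == "N")) next
    if (all(mapply(function(x, pp) x %in% iupac[[pp]], win, p)))
      out <- rbind(out, data.frame(start = st, end = st + k - 1,
                                   strand = "+"))
    rcwin <- rev(comp[win])
    if (all(mapply(function(x, pp) x %in% iupac[[pp]], rcwin, p)))
      out <- rbind(out, data.frame(start = st, end = st + k - 1,
                                   strand = "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# independent codon-by-codon translation via the Biostrings code table
oracleTranslate <- function(dna, table = "11") {
  gc <- Biostrings::getGeneticCode(table)
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(vapply(codons, function(cd) {
    if (grepl("N", cd)) "X" else unname(gc[cd])
  }, character(1)), collapse = "")
}
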