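#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readBStringSet writeXStringSet reverseComplement translate
#'   getGeneticCode
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

# locate the first line of `path` containing a character outside `allowed`
# (sequence lines only); used to make parse errors name a line number.
.offending_line <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  bad <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    if (grepl(bad, toupper(lines[i]))) return(i)
  }
  NA_integer_
}

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet]
#' (`alphabet = "dna"`) or [Biostrings::AAStringSet]
#' (`alphabet = "protein"`). Sequences are uppercased; for DNA, `U` is
#' mapped to `T`. DNA records are restricted to `{A,C,G,T,N}`, protein
#' records to the 20 standard residues plus `X` and `*`; any other
#' character is a parse error naming the offending line. Record ids
#' (first whitespace-delimited token of the header) must be unique.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `DNAStringSet` or `AAStringSet`, empty for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 a toy contig", "acgtACGT"), tf)
#' readFasta(tf, "dna")
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(if (alphabet == "dna") DNAStringSet() else AAStringSet())
  }
  raw <- tryCatch(readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e)))
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (alphabet == "dna") {
    seqs <- chartr("U", "T", seqs)
    ok <- grepl("^[ACGTN]*$", seqs)
    if (!all(ok)) {
      line <- .offending_line(path, c(.DNA_ALPHABET, "U"))
      stop("illegal DNA character in ", path, " (record '",
           ids[which(!ok)[1]], "', line ", line, ")")
    }
    out <- DNAStringSet(seqs)
  } else {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seqs)
    if (!all(ok)) {
      line <- .offending_line(path, .AA_ALPHABET)
      stop("illegal amino-acid character in ", path, " (record '",
           ids[which(!ok)[1]], "', line ", line, ")")
    }
    out <- AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `DNAStringSet`/`AAStringSet` or named character
#'   vector of sequences.
#' @param path output file path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- if (all(grepl("^[ACGTNU]*$", toupper(x))))
      DNAStringSet(toupper(x)) else AAStringSet(x)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all records must have an id")
  writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`. Characters outside `{A,C,G,T,N}` are an error (IUPAC
#' ambiguity codes other than N are deliberately rejected; see
#' [findPamSites()] for IUPAC pattern matching on the pattern side).
#'
#' @param seq a DNA character string or [Biostrings::DNAString].
#' @return a character string (or `DNAString` if that was the input).
#' @examples
#' revComp("TTTA")  # "TAAA"
#' @export
revComp <- function(seq) {
  asString <- is(seq, "DNAString")
  s <- toupper(as.character(seq))
  if (!grepl("^[ACGTN]*$", s))
    stop("non-DNA character in sequence (allowed: A,C,G,T,N)")
  out <- as.character(reverseComplement(DNAString(s)))
  if (asString) DNAString(out) else out
}

#' Translate a DNA sequence
#'
#' Translates under the bacterial/archaeal genetic code (NCBI table 11)
#' by default; stops are rendered as `*`, codons containing `N` as `X`.
#' The length must be divisible by 3.
#'
#' @param seq DNA character string or [Biostrings::DNAString].
#' @param table genetic code id as understood by
#'   [Biostrings::getGeneticCode] (default `"11"`).
#' @return protein sequence as a character string.
#' @examples
#' translateDna("ATGAAATAG")  # "MK*"
#' @export
translateDna <- function(seq, table = "11") {
  s <- toupper(as.character(seq))
  if (nchar(s) %% 3L != 0L)
    stop("sequence length (", nchar(s), ") not divisible by 3")
  if (!grepl("^[ACGTN]*$", s))
    stop("non-DNA character in sequence")
  if (nchar(s) == 0L) return("")
  as.character(translate(DNAString(s),
    genetic.code = getGeneticCode(table),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

#' Transcribe DNA to RNA notation
#'
#' @param seq DNA character string.
#' @return the same sequence with `T` replaced by `U`.
#' @export
dnaToRna <- function(seq) chartr("T", "U", toupper(as.character(seq)))

#' Write features to GFF3
#'
#' Minimal GFF3 writer used for array and ORF annotations. Coordinates in
#' `df` must already be 1-based closed (the IRanges convention used
#' throughout the package), matching the GFF3 standard.
#'
#' @param df a data.frame with columns `seqid`, `source`, `type`,
#'   `start`, `end`, `score`, `strand`, `phase`, `attributes`. Missing
#'   optional columns are filled with `"."`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(df, path) {
  required <- c("seqid", "type", "start", "end")
  if (!all(required %in% names(df)))
    stop("df must have columns: ", paste(required, collapse = ", "))
  fill <- function(col, default = ".")
    if (col %in% names(df)) as.character(df[[col]]) else
      rep(default, nrow(df))
  lines <- paste(
    fill("seqid"), fill("source", "casProspector"), fill("type"),
    df$start, df$end, fill("score"), fill("strand"), fill("phase"),
    fill("attributes"),
    sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
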