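#' @importFrom Biostrings GENETIC_CODE
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# codons per amino acid under the standard nuclear/bacterial codon table
.codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

#' Random protein sequence
#'
#' Uniform over the 20 standard residues, starting with methionine.
#' Consumes the current RNG stream (seed it upstream).
#'
#' @param len protein length in residues.
#' @return a character string.
#' @export
randomProtein <- function(len) {
  paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE),
                    collapse = ""))
}

#' Mutate a protein by random substitutions
#'
#' Each position after the initial methionine is substituted with
#' probability `rate`, drawing uniformly from the 19 other residues.
#'
#' @param protein protein sequence.
#' @param rate per-residue substitution probability.
#' @return the mutated sequence.
#' @export
mutateProtein <- function(protein, rate) {
  aa <- .seq_chars(protein)
  if (length(aa) < 2L || rate <= 0) return(protein)
  idx <- which(stats::runif(length(aa) - 1L) < rate) + 1L
  for (i in idx) aa[i] <- sample(setdiff(.AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' Reverse-translate a protein
#'
#' Synonymous codons are drawn uniformly at random (codon bias is
#' irrelevant to the logic under test); the stop codon is `TAA`.
#'
#' @param protein protein sequence (no stops).
#' @param addStop append a stop codon (default TRUE).
#' @return a DNA string of length `3 * (nchar(protein) + addStop)`.
#' @export
reverseTranslate <- function(protein, addStop = TRUE) {
  tab <- .codon_table()
  aa <- .seq_chars(protein)
  codons <- vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue: ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), if (addStop) "TAA" else "")
}

#' Random DNA with a given GC content
#'
#' @param len length in nt.
#' @param gc GC fraction.
#' @return a character string.
#' @export
randomDna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Plant specification for the synthetic metagenome
#'
#' The defaults mirror the locus geometry reported for gut-metagenome
#' Cas12a systems: arrays of 7 repeats (36 nt, the FnCas12a-family
#' repeat) and 6 spacers (30 nt), an effector-length ORF 3 kb from the
#' array inside the 15-kb harvesting window, Cas2 and Cas4 adaptor genes
#' upstream with Cas1 absent, plus decoys: tandem repeats violating the
#' spacer-length bounds and a bait-like ORF outside the 15-kb window.
#'
#' @param nLoci number of contigs carrying a planted locus.
#' @param repeatSeq the planted direct repeat (36-nt FnCas12a-family
#'   repeat by default).
#' @param nRepeats repeat copies per array.
#' @param spacerLen spacer length in nt.
#' @param repeatMutRate per-base substitution rate applied to repeat
#'   copies (default 0).
#' @param casOffset distance from array end to the effector gene (nt).
#' @param casLen effector protein length (residues).
#' @param orfSubRate substitution rate turning a bait into a planted
#'   effector.
#' @param adaptors adaptor genes planted at each locus.
#' @param adaptorLens named lengths (residues) for Cas1/Cas2/Cas4.
#' @param nBaits bait panel size (default 16).
#' @param decoyTandem plant tandem-repeat decoys.
#' @param decoyFarOrf plant bait-like ORFs outside the window.
#' @return a list of class `plantSpec`.
#' @export
plantSpec <- function(nLoci = 5L,
                      repeatSeq = "GTCTAAGAACTTTAAATAATTTCTACTGTTGTAGAT",
                      nRepeats = 7L, spacerLen = 30L,
                      repeatMutRate = 0, casOffset = 3000L,
                      casLen = 900L, orfSubRate = 0.05,
                      adaptors = c("Cas2", "Cas4"),
                      adaptorLens = c(Cas1 = 300L, Cas2 = 105L,
                                      Cas4 = 200L),
                      nBaits = 16L, decoyTandem = TRUE,
                      decoyFarOrf = TRUE) {
  structure(list(
    nLoci = as.integer(nLoci), repeatSeq = toupper(repeatSeq),
    nRepeats = as.integer(nRepeats), spacerLen = as.integer(spacerLen),
    repeatMutRate = repeatMutRate, casOffset = as.integer(casOffset),
    casLen = as.integer(casLen), orfSubRate = orfSubRate,
    adaptors = adaptors, adaptorLens = adaptorLens,
    nBaits = as.integer(nBaits), decoyTandem = decoyTandem,
    decoyFarOrf = decoyFarOrf), class = "plantSpec")
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- .seq_chars(seq)
  idx <- which(stats::runif(length(ch)) < rate)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# a gene construct: in-frame stop guard + ATG gene + stop, oriented
.gene_construct <- function(protein, strand) {
  gene <- reverseTranslate(protein)          # starts ATG..., ends TAA
  construct <- paste0("TAA", gene)
  if (strand == "-") construct <- revComp(construct)
  construct
}

# forward-axis gene interval within a planted construct
.gene_interval <- function(constructStart, geneLen, constructLen,
                           strand) {
  if (strand == "+") {
    c(constructStart + 3L, constructStart + 2L + geneLen)
  } else {
    c(constructStart, constructStart + geneLen - 1L)
  }
}

#' Generate a synthetic metagenome with planted ground truth
#'
#' Builds `nContigs` contigs of i.i.d. background bases at the stated GC
#' content; the first `plant$nLoci` contigs carry a planted CRISPR locus
#' (array + effector gene + adaptor genes), and decoy features are
#' scattered per `plant`. All randomness is driven by `seed`; plant
#' layout and planted sequences are drawn before the background, so plant
#' positions are independent of background content. Planted effectors are
#' reverse-translated, lightly mutated copies of the generated bait
#' proteins, so the screening stage has a nontrivial but known answer.
#'
#' @param seed integer RNG seed.
#' @param nContigs number of contigs (default 20).
#' @param contigLen contig length in bp (default 50000).
#' @param gc background GC fraction (default 0.5).
#' @param plant a [plantSpec()].
#' @return a list: `contigs` (named [Biostrings::DNAStringSet]), `truth`
#'   (list of data.frames `arrays`, `orfs`, `decoys`), `baits` (named
#'   character, the Cas12a-like bait panel), `adaptorBaits` (named
#'   character: Cas1, Cas2, Cas4), and `plant`.
#' @examples
#' mg <- makeMetagenome(1, nContigs = 2, contigLen = 50000,
#'                      plant = plantSpec(nLoci = 1))
#' mg$truth$arrays
#' @export
makeMetagenome <- function(seed, nContigs = 20L, contigLen = 50000L,
                           gc = 0.5, plant = plantSpec()) {
  set.seed(as.integer(seed))
  nContigs <- as.integer(nContigs); contigLen <- as.integer(contigLen)
  if (plant$nLoci > nContigs)
    stop("infeasible plant spec: nLoci (", plant$nLoci,
         ") exceeds nContigs (", nContigs, ")")
  rlen <- nchar(plant$repeatSeq)
  arrayLen <- plant$nRepeats * rlen +
    (plant$nRepeats - 1L) * plant$spacerLen
  ids <- sprintf("synth_contig_%02d", seq_len(nContigs))

  # ---- phase A: plants (independent of background) ----
  baits <- setNames(
    vapply(seq_len(plant$nBaits), function(i) randomProtein(plant$casLen),
           character(1)),
    sprintf("Cas12a_bait_%02d", seq_len(plant$nBaits)))
  adaptorBaits <- setNames(
    vapply(c("Cas1", "Cas2", "Cas4"), function(a)
      randomProtein(plant$adaptorLens[[a]]), character(1)),
    c("Cas1", "Cas2", "Cas4"))

  plants <- lapply(ids, function(id) list(features = list()))
  names(plants) <- ids
  truthArrays <- list(); truthOrfs <- list(); truthDecoys <- list()

  addFeature <- function(contig, start, seq, kind, meta = NULL) {
    f <- list(start = as.integer(start), seq = seq, kind = kind,
              meta = meta)
    plants[[contig]]$features[[length(plants[[contig]]$features) + 1L]] <<- f
  }

  for (li in seq_len(plant$nLoci)) {
    id <- ids[li]
    jit <- function() sample(-300:300, 1L)
    arrayStart <- as.integer(round(contigLen * 0.36)) + jit()
    spacers <- vapply(seq_len(plant$nRepeats - 1L), function(i)
      randomDna(plant$spacerLen, 0.5), character(1))
    copies <- vapply(seq_len(plant$nRepeats), function(i)
      .mutate_dna(plant$repeatSeq, plant$repeatMutRate), character(1))
    arraySeq <- copies[1L]
    for (i in seq_len(plant$nRepeats - 1L))
      arraySeq <- paste0(arraySeq, spacers[i], copies[i + 1L])
    addFeature(id, arrayStart, arraySeq, "array")
    arrayEnd <- arrayStart + arrayLen - 1L
    truthArrays[[length(truthArrays) + 1L]] <- data.frame(
      contig = id, start = arrayStart, end = arrayEnd,
      n_repeats = plant$nRepeats, repeat_len = rlen,
      spacer_len = plant$spacerLen,
      repeat_seq = plant$repeatSeq)

    # effector: mutated bait, strand alternating for coverage
    baitIdx <- ((li - 1L) %% plant$nBaits) + 1L
    effProt <- mutateProtein(baits[[baitIdx]], plant$orfSubRate)
    effStrand <- if (li %% 2L == 1L) "+" else "-"
    effConstruct <- .gene_construct(effProt, effStrand)
    effStart <- arrayEnd + plant$casOffset
    geneLen <- 3L * (nchar(effProt) + 1L)
    gi <- .gene_interval(effStart, geneLen, nchar(effConstruct),
                         effStrand)
    addFeature(id, effStart, effConstruct, "gene")
    truthOrfs[[length(truthOrfs) + 1L]] <- data.frame(
      contig = id, start = gi[1L], end = gi[2L], strand = effStrand,
      id = sprintf("effector_%02d", li), class = "cas12a_like",
      source_bait = names(baits)[baitIdx], protein = effProt)

    # adaptor genes upstream of the array (Cas1 deliberately absent)
    offset <- 2000L
    for (ad in plant$adaptors) {
      prot <- mutateProtein(adaptorBaits[[ad]], plant$orfSubRate)
      str <- "+"
      cons <- .gene_construct(prot, str)
      cstart <- arrayStart - offset - nchar(cons)
      gi <- .gene_interval(cstart, 3L * (nchar(prot) + 1L),
                           nchar(cons), str)
      addFeature(id, cstart, cons, "gene")
      truthOrfs[[length(truthOrfs) + 1L]] <- data.frame(
        contig = id, start = gi[1L], end = gi[2L], strand = str,
        id = sprintf("%s_%02d", tolower(ad), li),
        class = paste0("adaptor_", tolower(ad)),
        source_bait = ad, protein = prot)
      offset <- offset + 2000L
    }

    # decoys in the locus contig
    if (plant$decoyTandem) {
      unit <- randomDna(28L, 0.5)
      tand <- strrep(unit, 6L)
      tstart <- arrayEnd + plant$casOffset + geneLen + 4000L + jit()
      addFeature(id, tstart, tand, "decoy_tandem")
      truthDecoys[[length(truthDecoys) + 1L]] <- data.frame(
        contig = id, start = tstart, end = tstart + nchar(tand) - 1L,
        kind = "tandem_repeat")
    }
    if (plant$decoyFarOrf && li == 1L) {
      prot <- mutateProtein(baits[[plant$nBaits]], plant$orfSubRate)
      cons <- .gene_construct(prot, "+")
      dstart <- arrayEnd + 15000L + 1500L
      gi <- .gene_interval(dstart, 3L * (nchar(prot) + 1L),
                           nchar(cons), "+")
      addFeature(id, dstart, cons, "gene")
      truthOrfs[[length(truthOrfs) + 1L]] <- data.frame(
        contig = id, start = gi[1L], end = gi[2L], strand = "+",
        id = "far_decoy_01", class = "decoy",
        source_bait = names(baits)[plant$nBaits], protein = prot)
    }
  }

  # decoys in contigs without arrays
  if (plant$decoyFarOrf && nContigs > plant$nLoci) {
    extra <- seq(plant$nLoci + 1L,
                 min(nContigs, plant$nLoci + 2L))
    for (ci in extra) {
      prot <- mutateProtein(baits[[1L]], plant$orfSubRate)
      cons <- .gene_construct(prot, "-")
      dstart <- as.integer(round(contigLen * 0.4))
      gi <- .gene_interval(dstart, 3L * (nchar(prot) + 1L),
                           nchar(cons), "-")
      addFeature(ids[ci], dstart, cons, "gene")
      truthOrfs[[length(truthOrfs) + 1L]] <- data.frame(
        contig = ids[ci], start = gi[1L], end = gi[2L], strand = "-",
        id = sprintf("orphan_decoy_%02d", ci), class = "decoy",
        source_bait = names(baits)[1L], protein = prot)
    }
  }
  if (plant$decoyTandem && nContigs > plant$nLoci + 2L) {
    for (ci in seq(plant$nLoci + 3L, nContigs)) {
      unit <- randomDna(24L, 0.5)
      tand <- strrep(unit, 7L)
      tstart <- as.integer(round(contigLen * 0.6))
      addFeature(ids[ci], tstart, tand, "decoy_tandem")
      truthDecoys[[length(truthDecoys) + 1L]] <- data.frame(
        contig = ids[ci], start = tstart,
        end = tstart + nchar(tand) - 1L, kind = "tandem_repeat")
    }
  }

  # feasibility: features within bounds and non-overlapping
  for (id in ids) {
    fs <- plants[[id]]$features
    if (!length(fs)) next
    iv <- do.call(rbind, lapply(fs, function(f)
      c(f$start, f$start + nchar(f$seq) - 1L)))
    if (any(iv[, 1L] < 1L) || any(iv[, 2L] > contigLen))
      stop("infeasible plant spec: feature outside contig bounds on ",
           id, " (", paste(apply(iv, 1, paste, collapse = "-"),
                           collapse = ", "), "; contigLen ", contigLen,
           ")")
    o <- order(iv[, 1L])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("infeasible plant spec: overlapping planted features on ", id)
  }

  # ---- phase B: background, then overwrite with plants ----
  contigs <- character(nContigs)
  for (ci in seq_len(nContigs)) {
    bg <- randomDna(contigLen, gc)
    for (f in plants[[ids[ci]]]$features) {
      substr(bg, f$start, f$start + nchar(f$seq) - 1L) <- f$seq
    }
    contigs[ci] <- bg
  }
  contigSet <- DNAStringSet(contigs)
  names(contigSet) <- ids

  bindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst)
    else proto
  list(
    contigs = contigSet,
    truth = list(
      arrays = bindOr(truthArrays, data.frame()),
      orfs = bindOr(truthOrfs, data.frame()),
      decoys = bindOr(truthDecoys, data.frame())),
    baits = baits,
    adaptorBaits = adaptorBaits,
    plant = plant)
}

#' Write a synthetic metagenome to disk
#'
#' FASTA plus tab-separated truth tables and a JSON sidecar recording the
#' generating configuration.
#'
#' @param mg result of [makeMetagenome()].
#' @param dir output directory (created if needed).
#' @param seed the seed used (recorded in the sidecar).
#' @return `dir`, invisibly.
#' @export
writeMetagenome <- function(mg, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(mg$contigs, file.path(dir, "contigs.fa"))
  writeFasta(mg$baits, file.path(dir, "baits.fa"))
  writeFasta(mg$adaptorBaits, file.path(dir, "adaptor_baits.fa"))
  for (nm in names(mg$truth)) {
    utils::write.table(mg$truth[[nm]],
      file.path(dir, paste0("truth_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(mg$plant)
  cfg$seed <- seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
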