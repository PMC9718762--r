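---
title: "Mining metagenome assemblies for Cas12a effectors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenome assemblies for Cas12a effectors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casProspector)
```

# The problem

Class 2 type V-A CRISPR effectors (Cas12a, formerly Cpf1) are single-protein
RNA-guided nucleases: they recognize a T-rich PAM (5'-TTTV-3'), use a single
short crRNA that they mature themselves, and cleave double-stranded DNA with
a staggered cut that leaves 5' overhangs. New orthologs are routinely mined
from environmental and host-associated metagenome assemblies by exploiting
the genomic signature of the system: a CRISPR repeat-spacer array with a
large (~1,300 aa) effector gene nearby, often accompanied by the
Cas4/Cas1/Cas2 adaptation module.

`casProspector` implements that mining cascade as a tested, reusable R
toolkit. Every stage is exposed as an exported function on standard
Bioconductor containers (`DNAStringSet`, `AAStringSet`, `IRanges`,
`GRanges`, `phylo`), and `runDiscovery()` chains them:

1. **Array detection** — `findArrays()`, a CRT-style seed-and-extend
   scanner.
2. **ORF harvesting** — `callOrfs()` (six-frame, code 11) and
   `crisprNeighborhood()`, keeping ORFs within 15 kb of an array.
3. **Homology screen** — `screenCandidates()`: local protein alignment
   against a bait panel of characterized Cas12a proteins, after the
   800–1500 residue and methionine-start filters.
4. **Repeat and handle analysis** — `orientArray()`,
   `predictMaturationSite()`, `foldHairpin()`, `classifyHandle()`.
5. **Phylogeny** — `distanceMatrix()` + `njTree()` (+
   `bootstrapSupport()`).
6. **Functional prediction** — `findPamSites()`, `inSilicoDigest()`,
   `cleavageEfficiency()`, `editingEfficiencyT7E1()`,
   `isoelectricPoint()`, `mapResidues()`.

A deterministic synthetic-metagenome generator (`makeMetagenome()`) with a
planted, machine-readable truth table makes the whole cascade testable at
desk scale.

# Coordinate conventions

All intervals in R objects are 1-based closed (`IRanges`/`GRanges`
convention), which coincides with GFF3. Two derived quantities need a
convention of their own:

* the **maturation cut** of a direct repeat is stored as the number of
  nucleotides removed from the repeat 5' end, so
  `handle == rna(substring(repeat, cut + 1))`;
* a **digestion cut site** of value *k* separates positions *k* and
  *k + 1* on the forward axis, so fragment lengths are `c(k, len - k)`.

# Array detection

`findArrays()` follows the CRT lineage of repeat finders. Exact `seedK`-mers
(default 8) recurring at a spacing compatible with one repeat plus one
spacer anchor candidate arrays; seeds are chained, extended outward
column-by-column into equal-length repeat copies, and additional copies are
then searched at valid spacings against the running consensus, allowing up
to `maxMismatches` (default 2) substitutions per copy. Defaults
(`detectorParams()`): at least 3 copies, repeat 19–38 nt, spacer 19–48 nt.
Those bounds are the detector's only notion of biological plausibility and
every reported array is checked against them.

Three design choices deserve a note:

* **Equal-length copies, no indels.** Repeat copies are modeled as
  substitution-only variants of a common consensus. This matches how array
  figures align repeats, keeps the consensus a per-column majority vote
  (ties go to the earliest copy), and makes boundary arithmetic exact.
* **Strict and tolerant extension.** Boundary extension is run twice per
  seed chain: once demanding unanimous columns, once allowing one
  dissenting copy per column within the mismatch budget. Both variants
  enter the candidate pool, and overlap resolution ranks candidates by
  repeat count, then by a CRT-like quality score (matched characters minus
  a penalty that makes a one-dissent column a net loss), then by position.
  The strict variant pins exact boundaries of clean arrays; the tolerant
  one recovers the full width of arrays with mutated copies. A column where
  every copy disagrees can never be attributed to the repeat, which is why
  the majority-vote tie-break is only exercised on interior columns.
* **Spacer dissimilarity.** A perfect tandem repeat read at period 2 is
  geometrically a legal array whose "spacers" equal the repeat unit, so
  candidates are rejected when a spacer is ≥ 80% identical to the repeat
  consensus or to its neighboring spacer. True spacers are acquired from
  mobile elements and are effectively random, so this filter costs nothing
  on real arrays; it is what keeps tandem/satellite decoys out.

Detection is strand-agnostic and reports `orientation = "unknown"`;
orientation is resolved later from the biology (below).

# ORF calling

`callOrfs()` is a deterministic six-frame caller: an ORF is an `ATG`-to-stop
run under the bacterial code (NCBI table 11), the longest ORF is reported
per stop, and reverse-strand hits are mapped to forward-axis coordinates.
This deliberately replaces a trained metagenome gene finder: the cascade
only needs candidate proteins near arrays, determinism makes planted-truth
testing exact, and the methionine filter downstream mirrors how non-Met
starts were excluded in the screening protocol this package reproduces.
`GTG`/`TTG` starts can be enabled (`altStarts = TRUE`), in which case such
ORFs are translated by plain codon lookup and flagged by the Met filter
rather than silently rewritten. The default `minAa = 100` for the
neighborhood scan keeps the smallest adaptor gene (Cas2, ~100 aa) visible
while the effector screen enforces 800–1500 aa separately.

# Homology screen

The screen scores each surviving ORF against every bait with
Smith–Waterman local alignment under BLOSUM62, gap open 11 / extend 1 —
the BLASTp defaults, since BLASTp is the tool this stage stands in for. The
alignment engine is `Biostrings::pairwiseAlignment()`; the test suite pins
its behavior (including the exact gap-cost convention, `11 + L` for a gap
of length L) against an independently written brute-force dynamic program
on hundreds of random pairs. Pairwise identity is reported from the global
(Needleman–Wunsch) alignment as matches divided by **all** alignment
columns, gap columns included — conventions differ between tools, so the
denominator is stated explicitly and tested. `kmerPrefilter()` offers
BLAST-like seeding to keep large panels affordable; it is advisory,
disabled by default, and the pipeline's candidate set is proven invariant
to it in the tests. A full-length screen replaces the original protocol's
conserved-motif query step, since the motif set itself is not published as
text; `mapResidues()` covers the residue-level use of such motifs
(transferring the RuvC catalytic D/E positions of characterized orthologs
onto candidates through the global alignment).

The default score threshold (`minScore = 200`) sits far above the empirical
null for unrelated ~1,000-aa proteins under this scoring (tests place the
null below 100) and far below any true ortholog signal (a 5%-diverged
effector scores in the thousands), so the screen's verdicts are not
sensitive to it.

# Direct repeats and the crRNA 5' handle

Cas12a matures its own pre-crRNA: cleavage inside the repeat leaves a
fixed-length repeat suffix — the 5' handle — on the mature crRNA, and that
handle folds into a short stem-loop (in reality a pseudoknot). The package
models the handle fold as the **best single hairpin**: one helix, an
optional internal bulge of at most 2 nt on one side, loop of at least 3 nt,
Watson-Crick or G·U pairs, most pairs wins, ties to the smaller loop and
then the 5'-most helix. Handles are ~20 nt, so exhaustive search is exact
and instant, and the suite verifies it against an independent enumerator.
No thermodynamic energy model is used — for these lengths the pair-count
criterion reproduces the canonical handle stems, but the folds should be
read as diagrams, not ΔG predictions.

The fold is then used three ways:

* **Orientation** (`orientArray()`): the mature handle comes from the
  repeat 3' end, so the strand whose terminal 19 nt fold with more pairs is
  called the sense strand; ties default to forward with a warning.
* **Maturation site** (`predictMaturationSite()`): the cut is placed
  `handleLen` nt from the repeat 3' end. The default of 19 nt (configurable
  18–20) matches the canonical FnCas12a-family handle; published locus
  figures mark the cut graphically but print no offset, so this is a
  package default, not a measured constant.
* **Classification** (`classifyHandle()`): references are right-justified
  (handles are anchored at the 3' end, next to the spacer), Hamming
  mismatches counted (pad-versus-base counts as a mismatch), and loop-region
  mismatches reported separately because known orthologs differ mostly at
  the loop. The shipped references (`inst/extdata/handle_references.fa`)
  are the canonical AsCas12a/FnCas12a/LbCas12a handle sequences from the
  literature and are deliberately a plain editable FASTA: pass your own set
  to extend it.

# Phylogeny

Distances are `1 − identity` on the global alignment (p-distances); a
Poisson correction `−ln(1 − p)` is available but off by default since the
tree's role here is candidate placement, not divergence dating. `njTree()`
is a from-scratch Saitou–Nei implementation with documented determinism:
Q-criterion ties break to the smallest index pair, negative branch lengths
are clamped to zero with the deficit moved to the sibling. On additive
matrices NJ is exact, and the suite verifies exact recovery (topology and
branch lengths, via the tree metric) on random additive trees, plus
topological agreement with `ape::nj` on noisy matrices. Maximum-likelihood
trees are out of scope. `bootstrapSupport()` resamples columns of a
user-supplied alignment (pairwise-deletion p-distances, so columns gapped
in either member of a pair are ignored for that pair), rebuilds NJ trees,
and reports per-split support through `ape::prop.clades`; the replicate
count is a parameter, not a constant, since both 100× and 1000× are common
in practice.

# In-silico digestion and efficiencies

`findPamSites()` matches any IUPAC pattern (default `TTTV`) on both
strands; `inSilicoDigest()` requires the spacer to match exactly
(configurable) immediately 3' of a PAM and predicts the staggered cut. The
cut offsets — 18 nt on the non-target (protospacer) strand and 23 nt on the
target strand, 3' of the PAM — encode the canonical Cas12a 5-nt 5'-overhang
geometry; the stagger itself is documented biology, the exact offsets are
configuration values, and the fragment report states that lengths are
computed at the PAM-proximal (non-target-strand) cut. Fragment lengths
always sum to the target length (asserted on every digest), and digesting
the reverse-complemented target mirrors the fragment multiset. Circular
targets are supported behind a flag (one cut linearizes).

Band-intensity quantification follows the densitometry rules used with
in-tube cleavage assays: cleavage efficiency is
`100 · cut / (uncut + cut)` summed over cleaved bands, and editing
efficiency from a substrate-depletion (T7E1-style) readout is
`100 · (1 − treated/control)`, with the standard indel estimate
`100 · (1 − sqrt(uncut fraction))` available when the cleaved bands are
quantified. A treated intensity above the control clamps to 0% with a
warning rather than reporting negative editing.

`isoelectricPoint()` solves the Henderson–Hasselbalch charge balance by
bisection over pH 0–14 (tolerance 1e-4 on the net charge). The default pKa
set is Bjellqvist's (with residue-specific N-terminal and Asp/Glu
C-terminal values, as in the ExPASy tool); an EMBOSS-style set is
selectable because published pI values rarely state which table produced
them, and the two sets differ by up to ~0.3 pH units on real proteins.

# The synthetic metagenome

`makeMetagenome(seed)` is first-class, tested code, not a fixture dump. It
emulates — at desk scale — the situation the cascade faces on a real
assembly database: mostly featureless contigs, a few true loci, and decoys
that defeat naive detectors. Defaults (20 contigs × 50 kb, GC 0.5):

* **5 locus contigs**, each carrying an array of **7 repeats × 36 nt**
  (the FnCas12a-family repeat) with **6 random 30-nt spacers**, an
  effector gene (a bait protein mutated at 5% substitutions,
  reverse-translated with uniform synonymous codons) **3 kb** from the
  array, and **Cas2 + Cas4** adaptor genes upstream with **Cas1 absent** —
  the adaptor configuration reported for gut-metagenome Cas12a loci.
* **Decoys**: perfect tandem repeats (unit length inside the repeat
  bounds, spacing outside them) in locus and non-locus contigs, plus
  bait-like ORFs placed beyond the 15-kb window or on array-less contigs.
* A **16-protein bait panel** (the panel size used in published Cas12a
  screens) and Cas1/Cas2/Cas4 adaptor baits, generated per seed.

Plant layout and planted sequences are drawn before any background base,
so positions are independent of background composition; the whole object
is byte-deterministic in the seed. The effector length default (900 aa)
sits inside the 800–1500 aa screening window, and planted genes carry an
in-frame stop guard immediately 5' of their start codon so the six-frame
caller recovers exactly the planted interval.

What the generator does **not** emulate: codon bias, assembly errors and
chimeras, repeat arrays with indels, degenerate repeats, partial genes at
contig edges, and real inter-protein homology structure (baits are random
sequences, so the bait panel is an idealized, well-separated panel).
Passing the planted-truth tests therefore demonstrates the correctness of
the machinery — coordinates, filters, scores, orientation, classification —
not field performance on real assemblies, where array degeneracy and gene
fragmentation dominate the error budget.

# Problem sizes used in the checks

The shipped acceptance checks run the full cascade on the default
20 × 50 kb fixture (detection alone and end-to-end), compare the alignment
scores against a brute-force dynamic program on 100 random ≤ 12-residue
pairs, rebuild 20 random 8-leaf additive trees, verify fragment-length
conservation on 1,000 random digests, and check the hairpin fold against
exhaustive enumeration on 50 random 20-mers. These sizes were chosen so the
whole suite exercises every stage in a few minutes on one core while
keeping every comparison exact rather than sampled.

# Validation against published locus numbers

Two further checks reproduce numbers reported for the two characterized
gut-metagenome Cas12a loci (mutual protein identity ≈ 37%, calculated pI
6.91/6.15, RuvC catalytic residues at 877/962 and 873/967 mapped from
FnCas12a D917/E1006, seven repeats and six spacers per array, handles
identical to FnCas12a, and amplicon digests of 1,662 → 978 + 684 bp and
721 → 378 + 343 bp). The required accession contigs and amplicon/crRNA
sequences must be downloaded by the user (they are not redistributed with
the package); the corresponding tests state exactly which files to place
under `tests/testthat/validation/` and fail with that message until the
files are present. Tolerances there follow the published precision: ±3
percentage points on the identity (alignment parameters and the identity
denominator are not stated alongside the published value) and ±0.3 pH
units on the pI (the pKa table behind the published values is not named).

# Known limitations

* Arrays split across contig ends, or with large indels between repeat
  copies, are out of scope by design.
* The single-hairpin handle model cannot represent the real handle
  pseudoknot; classification against reference handles does not depend on
  it, but stem annotations are approximate.
* The ORF caller does not model ribosome-binding sites or refine start
  sites; on real data a Prodigal-derived protein may begin a few codons
  away from the ATG this caller picks, which matters for residue-number
  comparisons at single-residue precision.
* E-value statistics are not computed; the screen uses raw scores with an
  empirically safe threshold, which is appropriate for a bait panel of
  known orthologs but not for open-ended database search.
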