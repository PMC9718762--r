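# casProspector

Mining metagenome assemblies for CRISPR–Cas12a effectors.

## What this is for

Cas12a (Cpf1) is a class 2 type V-A CRISPR effector: a single RNA-guided
nuclease that recognizes a T-rich PAM (5′-TTTV-3′), processes its own
crRNA, and cuts double-stranded DNA with a staggered cut leaving 5′
overhangs. New orthologs are mined from metagenome assemblies by their
genomic signature — a CRISPR repeat–spacer array with a large effector ORF
nearby, sometimes with the Cas4/Cas1/Cas2 adaptation module.

`casProspector` implements that discovery cascade for R users working on
assembled contigs:

1. **Detect arrays** (`findArrays`): CRT-style seed-and-extend repeat
   finding (≥ 3 copies, repeat 19–38 nt, spacer 19–48 nt, ≤ 2 mismatches
   per copy), with a spacer-dissimilarity filter that rejects
   tandem/satellite decoys.
2. **Harvest ORFs** (`callOrfs`, `crisprNeighborhood`): six-frame ATG→stop
   calls under genetic code 11, restricted to ±15 kb around each array.
3. **Screen candidates** (`screenCandidates`): Smith–Waterman local
   alignment (BLOSUM62, gap open 11 / extend 1) against a panel of known
   Cas12a bait proteins, after the 800–1500 aa and Met-start filters.
4. **Analyse repeats** (`orientArray`, `predictMaturationSite`,
   `foldHairpin`, `classifyHandle`): strand from handle foldability,
   crRNA maturation cut, mature 5′ handle stem–loop, classification
   against the As/Fn/LbCas12a reference handles.
5. **Place on a tree** (`distanceMatrix`, `njTree`, `bootstrapSupport`):
   neighbor joining on 1 − identity distances, with column-bootstrap
   support on a supplied alignment.
6. **Predict function** (`findPamSites`, `inSilicoDigest`,
   `cleavageEfficiency`, `editingEfficiencyT7E1`, `isoelectricPoint`,
   `mapResidues`): TTTV PAM scanning, staggered-cut fragment prediction
   (cuts 18/23 nt 3′ of the PAM → 5-nt 5′ overhang), band-intensity
   efficiency rules, pI by Henderson–Hasselbalch bisection, and catalytic
   residue transfer (e.g. FnCas12a RuvC D917/E1006) via global alignment.

`makeMetagenome` generates deterministic synthetic metagenomes with a
planted truth table (arrays, effector/adaptor genes, decoys), so the whole
pipeline is testable without downloads, and `runDiscovery` chains all
stages into one report.

## Worked example

```r
library(casProspector)

# a 2-contig synthetic metagenome, one planted Cas12a locus
mg <- makeMetagenome(11, nContigs = 2, contigLen = 50000,
                     plant = plantSpec(nLoci = 1))
report <- runDiscovery(mg$contigs, mg$baits,
                       adaptorBaits = mg$adaptorBaits)
report
#> DiscoveryReport: 1 array(s), 1 candidate(s) passing all filters (1 rows incl. flagged exclusions)
#>   tree: 17 tips

as.data.frame(reportCandidates(report))[, c("contig", "start", "end",
  "strand", "aa_len", "best_bait", "sw_score", "identity_to_best", "pI")]
#>            contig start   end strand aa_len      best_bait sw_score
#> 1 synth_contig_01 21585 24287      +    900 Cas12a_bait_01     4898
#>   identity_to_best       pI
#> 1        0.9511111 8.477757
```

The single candidate is the planted effector: a 900-aa ORF on the plus
strand, 3 kb from the detected array, whose best bait is the protein it was
derived from (95% global identity — it was planted with 5% substitutions),
with its isoelectric point computed from the Bjellqvist pKa set. The array
analysis recovers the repeat biology:

```r
as.data.frame(reportHandles(report))[, c("orientation",
  "maturation_cut", "handle", "best_reference", "mismatches")]
#>   orientation maturation_cut              handle best_reference mismatches
#> 1     forward             17 AAUUUCUACUGUUGUAGAU       FnCas12a          0
```

i.e. the 36-nt direct repeat is in forward orientation, maturation removes
its first 17 nt, and the retained 19-nt 5′ handle is identical to the
FnCas12a handle. The adaptor scan labels Cas4 and Cas2 near the array (and
no Cas1 — the planted locus configuration). In-silico digestion predicts
staggered cuts:

```r
t <- paste0(strrep("G", 40), "TTTA", strrep("A", 23), strrep("G", 33))
inSilicoDigest(t, strrep("A", 23))[[1]]
#> DigestResult: 100 bp target, PAM 41-44 (+), cuts 62/67 (5-nt 5' overhang)
#>   fragments: 62 + 38 bp

cleavageEfficiency(20, c(48, 32))   # gel densitometry rule
#> [1] 80
```

A thin command-line front end over the same functions is installed at
`inst/scripts/casprospector.R` (subcommands `simulate`, `detect`, `run`,
`digest`, `quantify`).

## Scope notes

The package operates on assembled contigs (FASTA in, GFF3/TSV/Newick/JSON
out). It does not align reads, assemble, call genes with a trained model,
compute alignment E-values, fold RNA thermodynamically, or model collateral
(trans) nuclease activity. See the methods vignette
(`vignettes/casProspector-methods.Rmd`) for the model assumptions, defaults
and their rationale, and known limitations.
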