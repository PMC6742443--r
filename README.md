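# mitoforms

Structural isoform analysis of recombining plant mitochondrial genomes.

## The problem

Plant mitochondrial genomes are routinely drawn as single circles, but in
vivo they are a dynamic mixture of linear, branched and subgenomic circular
molecules. A small set of **primary structural units** (polished contigs,
here named K..Z) is joined in several alternative orders — **isoforms** —
because multi-kilobase repeats present at 2x stoichiometry act as hinges for
frequent, symmetric homologous recombination, while dispersed repeats of a
few hundred bp recombine rarely and generate minor isoforms at the
percent level.

`mitoforms` implements the full inference chain that resolves this isoform
repertoire from sequencing data:

1. **Reverse read mapping** — primary units are cut into 2 kb tiling
   fragments (1 kb step) and aligned *onto* long reads, so each read reports
   the ordered, oriented sequence of units it traverses (its *unit path*).
   Reads covering ≥ 10 distinct fragments form the maximally informative set.
2. **Stoichiometry** — unit copy numbers from per-fragment coverage (2 kb
   windows, 0.5 kb step, alignments ≥ 1.8 kb at ≥ 80% identity), and
   junction abundances from the breakpoint between complete (≥ 1.8 kb) and
   fragmented alignments of 2 kb junction-spanning fragments.
3. **Secondary building blocks** — repeat-phased windows of unit paths
   (e.g. `P-T-Q`: repeat T with its two flanks read through in one
   molecule) with read-support counts.
4. **Isoform enumeration** — backtracking search for circular arrangements
   that use every unit exactly its copy number of times, traverse only
   observed junctions, and honour the block constraints; frequencies are
   estimated by simplex-constrained least squares on block support
   fractions.
5. **Junction consensus & polishing** — draft-anchored majority-vote
   consensus of 4–6 kb junction-centred read windows, plus short-read
   column/indel polishing.
6. **Minor isoforms** — 2D distance matrices (1 kb bins) of mate-pair and
   Hi-C (GATC-GATC split-read) distances; crossover at a dispersed repeat
   leaves double short diagonals off the main diagonal, and the
   recombination frequency is the mask density over the matched-geometry
   diagonal density.
7. **Repeat scan** — exact 50-mer seeds extended ungapped under +1/−20
   scoring, which reports only nearly identical (recently recombining)
   repeats.

A **simulator** generates multi-isoform circular genomes (including the
built-in *Lactuca sativa* / *L. saligna* unit tables), long reads with
configurable substitution/indel error, mate pairs and Hi-C ligation
chimeras, with complete ground truth, so every stage is testable without
external data.

## Worked example

Simulate the two major *L. sativa* isoforms (which differ by the exchange of
units P and U between the repeat hinges R and T) and re-infer them:

```r
library(mitoforms)

iso   <- majorIsoforms("sativa")          # alpha and beta, 363,324 bp each
cfg   <- simulationConfig(iso, seed = 21, coverage = 250)
truth <- generateGenome(cfg)
reads <- simulateLongReads(truth)

tiling <- makeTiling(unitSequences(truth))          # 2 kb / 1 kb fragments
hits   <- mapTilingToReads(tiling, reads)
keep   <- selectInformativeReads(hits, 10)
paths  <- unitPaths(hits[hits$readId %in% keep, ], tiling)

blocks <- buildingBlocks(paths, trueCopyNumbers(truth))
g      <- buildJunctionGraph(blocks, trueCopyNumbers(truth),
                             unitLengths = unitLengths(loadFixture("sativa")))
isos   <- enumerateIsoforms(g)
scoreIsoforms(isos, blocks)$frequencies
```

Representative output from this run:

```
> length(isos)
[1] 2
> isos[[1]]
IsoformModel iso1 (circular)
  K+ M+ N+ W+ Z+ R+ P+ T+ L+ R+ U+ T+ Q+ M+ N+
 363324bp
> scoreIsoforms(isos, blocks)$frequencies
 iso1  iso2
0.499 0.501
```

Exactly two genome-length circular arrangements survive the junction and
block constraints — the planted alpha and beta — and their estimated
frequencies recover the planted 50/50 mixture. The same machinery on the
*L. saligna* models recovers the four T-centred blocks (P-T-Q, P-T-L,
K-T-L, K-T-Q) and four R-centred blocks (Z-R-P, Z-R-U, L-R-U, L-R-P).

`runPipeline()` chains these stages and writes TSV/FASTA/BED/GFF3 artifacts
plus a JSON run report; `inst/cli/mitoforms.R` is a thin command-line
wrapper (`simulate`, `run`, `repeats` subcommands).

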