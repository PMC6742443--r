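---
title: "Resolving the isoform repertoire of recombining mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving the isoform repertoire of recombining mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoforms)
```

## The model

Plant mitochondrial DNA is not one circular molecule. A small set of
*primary structural units* — maximal unambiguous segments of the genome —
is present in the molecule population in several alternative circular (or
linear) arrangements, the *isoforms*. Units present at twice the coverage
of the rest (copy number 2) are large repeats; frequent, symmetric
homologous recombination between their two copies interconverts isoforms,
so the repeats behave as hinges and the major isoforms coexist at roughly
equal stoichiometry. Dispersed repeats of tens to hundreds of bp recombine
far more rarely and generate minor isoforms at frequencies of roughly 1-10%
(for repeats of 100-500 bp) down to below 1% (shorter than 100 bp).

`mitoforms` treats isoform inference as a constrained combinatorial
problem over a junction multigraph:

* each unit contributes one edge type with multiplicity equal to its copy
  number;
* adjacency edges are the junctions observed in long reads;
* *secondary building blocks* — repeat-phased windows such as `P-T-Q`,
  read through a repeat within a single molecule — act as path
  constraints: a walk entering a repeat from one flank must leave it
  according to some observed block.

Every closed walk that uses each unit exactly its copy number of times,
traverses only observed junctions and satisfies the block constraints is a
candidate isoform. Around a 2x hinge the *pairwise* junction multiset is
typically identical across isoforms (both exits of both copies are present
in every isoform), which is why blocks of length three or more — not bare
junctions — carry the phasing information, and why the frequency estimator
fits block support fractions rather than pairwise junction fractions.

## Coordinate and naming conventions

Internally every interval is 0-based, half-open. Exported BED files are
0-based half-open; exported GFF3 is 1-based inclusive (stated in the file
header). Oriented units are written `K+` / `K-`; circular arrangements are
stored in canonical form: the lexicographically minimal token string over
all rotations of the arrangement and of its reverse-complement traversal,
with ties broken on the `name+strand` token text in the C locale. This
removes the arbitrariness of linearising a circularly permuted map.

Contour lengths measured by fluorescence microscopy convert at a fixed
3.0 kb per micrometre (10 um corresponding to about 30 kb of uncompacted
B-form DNA; equivalently 121 um for a ~363 kb genome). The slightly
smaller textbook value of 2.94 kb/um was rejected in favour of the factor
that reproduces the published arithmetic exactly.

## Built-in fixtures

`loadFixture()` provides the *Lactuca sativa* (11 units, 314,646 bp
non-redundant, repeats M, N, R, T) and *L. saligna* (10 units, 323,254 bp,
repeats M, R, T) unit tables. In sativa, M and N are adjacent in all major
arrangements and behave as one long repeat (MN); recording N at copy
number 2 is required to reproduce the published 363,324 bp genome length.
The composite saligna unit UV can be split into U (38,613 bp) and V
(51,410 bp) for cross-species comparison; the split point is a convention
of this package, not a deposited coordinate.

`majorIsoforms()` returns two circular arrangements per species. The full
unit orders were never published; the built-in arrangements are
constructed to satisfy every stated structural constraint — for sativa the
partial order M-N-K-M-N-W-Z and the exchange of P and U between R and T
distinguishing alpha from beta; for saligna the four T-centred blocks
(P-T-Q, P-T-L, K-T-L, K-T-Q), the four R-centred blocks (Z-R-P, Z-R-U,
L-R-U, L-R-P) and the integrated linear-plasmid unit S flanked by M on
both sides. They should be read as representative models, not deposited
sequences.

## The simulator and what it does (not) emulate

`simulationConfig()` fixes the study conditions. Defaults:

| parameter | default | rationale |
|---|---|---|
| coverage | 250x | the depth the assembly design targets |
| read length | lognormal, mean 15 kb, SD 5 kb | long-read length scale; no published distribution exists, so this is a modelling choice |
| long-read error | 1% sub / 1% ins / 1% del | deliberately below real single-pass error so the built-in seeded aligner suffices; a documented knob |
| short reads | 100 nt, 0.1% substitutions | polishing-grade accuracy |
| mate-pair inserts | 2.5 and 10 kb, SD 10% of the mean | the library designs the method expects |
| Hi-C decay exponent | 3 | contacts concentrate within ~10 kb |

Molecules are sampled proportional to frequency times length; circular
genomes use the doubled-sequence trick and reads never exceed one genome
length. All randomness derives from one seed through named substreams
(genome, long reads, mate pairs, Hi-C, subsampling), so stages are
independently reproducible.

Not emulated: quality scores, chimeric long reads, mate-pair duplicates
and nuclear contamination (a plastid decoy spike-in is supported through
`filterPlastid()`'s inputs). Passing tests therefore demonstrate
correctness of the inference logic under a clean error model, not
robustness to every artefact of real libraries.

## Alignment engine

The BLAST-based mapping of the original workflow is replaced by a built-in
seeded, banded aligner (Rcpp): exact k-mer seeds (k = 15, sampled every
40 bp of the query) are clustered by diagonal and each cluster is verified
by a banded Smith-Waterman (match +1, mismatch −2, gap −2; band half-width
30 by default — drift over a 2 kb fragment at 2% indel error has SD ≈ 6 bp,
so the band is generous while keeping verification cheap). Hits report
identity, aligned length and the longest internal gap; "uninterrupted"
junction alignments require ≥ 1.8 kb with no internal gap over 50 bp, the
1.8 kb threshold being the one magic number retained from the method's
design. The aligner is checked against full dynamic-programming local
alignment on small instances (interval within ±2 bp, identity within
0.02). An adapter is unnecessary for tabular external hit files: the hit
table is a plain data frame and can be constructed from any source that
provides the same columns.

Short reads are placed by exact seeds plus substitution-only Hamming
verification (matching the simulator's short-read error model); a read is
*unique* if no second placement lies within 5 mismatches of the best.

## Parameter choices that matter

* **Tiling** 2 kb / 1 kb for unit paths, 2 kb / 0.5 kb for coverage; a
  tail window [L−2000, L) is always added so unit termini — where junction
  evidence lives — are covered. Units shorter than one window yield a
  single whole-unit fragment.
* **Informative reads**: ≥ 10 distinct fragments (default); 12 is the
  appropriate setting for shorter-read data sets.
* **Unit-path runs**: a run needs ≥ 2 fragments unless the unit is too
  short to yield them; runs split by one discarded stray hit are rejoined;
  reads where two units claim over half of the same span are flagged
  ambiguous and excluded.
* **Copy numbers**: per-unit interior mean (dropping two fragments at each
  end, where coverage dips) divided by an iteratively re-estimated
  single-copy median; ratios more than 0.25 from the nearest integer are
  flagged rather than silently rounded, surfacing sub-stoichiometric
  repeats. The 0.25 band is this package's construction — no numeric
  criterion was published.
* **Blocks**: minimum support 2, suppressing chimera- and error-induced
  phantom paths.
* **Recombination detection**: for repeat copies at p1 < p2, crossover
  pairs satisfy (p1 − x) + (y − p2 − rep) ≈ insert − readLength, a short
  diagonal displaced from the main diagonal by (p2 − p1) ± (insert − rep).
  The frequency estimate is mask count / (mask + matched-geometry diagonal
  count at both parental junctions), pooled over libraries; both counts
  share acceptance geometry (window ±3 SD of the insert plus one bin), so
  read-loss effects cancel to first order. Copies closer than about one
  insert length leave the mask overlapping the diagonal and are flagged
  unestimable. The exact mask geometry is a documented construction
  calibrated by simulation.
* **Repeat scan**: word 50, +1/−20, X-drop 40, minimum score 50. The
  published e-value cutoff is replaced by this raw-score threshold because
  the statistical parameters for that scoring are not available; with
  −20 per mismatch the scan reports only nearly identical repeats, which
  is the intent (recently duplicated or gene-converted copies).

## Numerical and degenerate-input behaviour

Consensus and polishing are draft-anchored column votes: ties keep the
draft base (stability over novelty), columns below the depth threshold are
left untouched, and indels need a strict majority of covering reads.
Polishing is idempotent. Frequency fitting uses a softmax parameterisation
on the simplex; for two isoforms the 1-D profile is optimised on a bounded
interval (the surface is flat toward the boundary, where quasi-Newton
steps are unreliable). Isoform sets indistinguishable by the supplied
blocks are flagged and returned tied rather than fitted. Enumeration from
a graph with an unconnected terminus returns an empty set with a
diagnostic naming the terminus.

## Problem sizes used by the test suite

The suite regenerates all data in code. The main conditions: saligna block
recovery at 100x coverage with 15 kb reads; sativa frequency recovery at
the default 250x; copy-number recovery on a 102 kb genome (six single-copy
units of 10-13 kb and one 15 kb 2x hinge) at 100x with 4 kb reads over 20
seeds — shorter reads at fixed depth decorrelate the per-fragment counts
and give the coverage-ratio estimator the precision that the 2.0 ± 0.25
band requires; minor-isoform detection on a 120 kb genome with a 500 bp
repeat, 100,000 pairs per mate-pair library. Oracle comparisons (brute
force enumeration, quadratic repeat scan, full-DP alignment) run on
reduced instances: up to 6 unit instances, sequences of a few kb, queries
up to 300 bp.

## Known limitations

* The aligner expects the low single-digit error rates of the simulator's
  defaults; raw single-pass long reads at 10-15% error would need a larger
  band, denser seeds, or external mapping.
* Enumeration is exponential in the worst case; it is practical because
  block constraints prune the walk space, and a result cap with a
  truncation flag guards pathological graphs.
* Frequency estimates assume block detectability depends only on the
  repeat-run geometry (cancelling within groups); strong read-length
  structure violating this would bias the fit.
* Whether isoforms coexist on one physical molecule (branched concatemers)
  is outside the method's reach; only population-level stoichiometry is
  inferred.
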