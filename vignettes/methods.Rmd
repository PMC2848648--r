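---
title: "How genetiler learns and calls genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How genetiler learns and calls genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(genetiler)
```

`genetiler` is an unsupervised prokaryotic gene caller: it trains its entire
model — coding statistics and translation-initiation-site signals — on the
input sequence itself, then tiles the genome with genes by dynamic
programming. This vignette explains the model, the constants that shape it,
the choices made where the design was genuinely open, what the synthetic
benchmark genomes do and do not emulate, and the known limitations.

## The candidate-gene universe

A candidate gene is a start codon (ATG, GTG or TTG only; nonstandard starts
such as ATA or CTG are not considered) paired with its next in-frame stop
codon (per the NCBI translation table, default 11; table 4 treats TGA as
tryptophan). Genes shorter than 90 bp, measured from the first base of the
start codon through the last base of the stop codon inclusive, are excluded
— shorter ORFs contribute more false positives than true genes. Synthetic
*edge nodes* in each frame at both contig boundaries represent genes
truncated by the ends of draft contigs; their lengths are trimmed to codon
multiples anchored at the intact end. Codons containing N are never valid
starts or stops, but genes may span runs of N (their hexamers score 0).

Internally all coordinates are 0-based with minus-strand codons stored at
the forward coordinate of their own first base; all output is 1-based
inclusive, GFF3-style.

## GC frame bias and the training tiling

In GC-skewed genomes, coding sequence concentrates G+C in a preferred codon
position. Every stop-to-stop ORF of at least 90 bp (both strands, stop
codon excluded) votes for the codon position with the highest total G+C
over the ORF. Votes are weighted by the ORF's codon count, so the tallies
measure the fraction of *codons in ORFs* preferring each position; with
unit votes the far more numerous short wrong-frame ORFs dominate and can
invert the signal. The winner fractions are normalized around 1,
B(i) = 3·f(i), so a position preferred by two-thirds of the codons scores
2.0. The bias is kept linear: a log transform was considered and rejected
as it blurs the contrast between frames that the preliminary tiling needs.

A per-base profile then labels each base with the residue class (index mod
3) whose G+C content is maximal in the 120 bp window centered there (the
conventional frame-plot window width; windows are truncated at contig
edges, and ties resolve to the lowest class). The preliminary score of a
candidate gene is S = Σᵢ B(i)·l(i), where l(i) counts its bases labeled
with the class corresponding to codon position i of the gene's own frame.
These scores drive a first dynamic-programming pass whose maximal tiling —
forced to choose between heavily overlapping ORFs — becomes the training
gene set.

## The hexamer coding model

In-frame hexamers are windows of six bases starting at each codon boundary
(dicodons, stepping by 3), equivalent to a 5th-order Markov emission; the
stop codon is excluded from the windows. Their frequencies G(w) over the
training tiling are compared with the background frequency B(w) of each
word over the entire input, both strands, irrespective of frame:
C(w) = log(G(w)/B(w)), natural log, clamped to [−4, +4]. The clamp handles
words with insufficient data: a word absent from the training genes takes
the floor, a word absent from the background (but observed in genes) the
ceiling, and a word absent from both scores 0. Natural log is fixed
project-wide because the 4.25/0.4 start-weight constants assume that scale.

A gene's coding score C is the sum of C(w) over its in-frame hexamers. Two
adjustments follow, per ORF:

* **Truncation penalty.** Among starts sharing a stop, ordered outermost
  (longest) inward, a start whose best longer alternative scores higher is
  penalized by the difference: adjusted = own − (best_longer − own), where
  the comparator is the running maximum of adjusted scores. Choosing the
  500-scoring long form over a 400-scoring truncation prices the
  truncation at 300. This discourages erasing a gene's 5' region with an
  opposite-strand call.
* **Long-gene boost.** A gene longer than a GC-dependent threshold —
  700 bp at GC ≤ 0.35 rising linearly to 1200 bp at GC ≥ 0.70, since
  high-GC genomes have longer spurious ORFs — with a negative coding score
  is lifted to a minimal positive 0.1: such long ORFs are rarely spurious.

## The start model

Start training begins from the *coding peaks*: the highest-C start of each
ORF, kept when C ≥ 35.0 (long-gene territory; fewer than 10 peaks triggers
a warning and degraded training). Three signal families are learned as
log-likelihood ratios S = log(R/B) of peak frequency over the background of
all enumerated start nodes, zero counts replaced by a single
pseudo-occurrence, clamped to ±4:

* start-codon type (ATG/GTG/TTG);
* Shine-Dalgarno RBS bins — 28 classes pairing motif sets (3–6 bp cores of
  AGGAGG, with `x` wildcards at the center of 5–6 bp motifs) with spacer
  ranges (3–4, 5–10, 11–12, 13–15 bp between the motif's 3' end and the
  start codon), searched in a 21 bp window ending one base before the
  start;
* after the loop settles, a generic upstream position-weight matrix over
  the offsets the RBS scorer does not cover (1–2 and 15–45 bp upstream),
  against the symmetrized genome base composition.

The loop alternates tabulating weights from the current peaks and
re-picking each ORF's peak to maximize C + 4.25·(type + RBS), until fewer
than 1 % of peaks move or 20 iterations. Two details stabilize it:

* In the first iteration a start's bin is the highest-numbered matching bin
  (the default priority order); afterwards the *re-picking* and the final
  scoring use the admissible bin with the highest current weight.
* The weight tabulation itself uses the fixed priority assignment on both
  sides of the ratio. Letting the tabulation assignment follow the weights
  makes strongly correlated bins (AGGAGG and its GGAGG/AGGAG subwords)
  saturate the clamp and the peak set cycle indefinitely; with the
  symmetric rule the ratios are honest enrichments and the loop reaches a
  fixed point in a handful of iterations.

**SD usage decision.** The organism is judged not to use the Shine-Dalgarno
motif strongly when the no-motif bin weight is positive, or above −0.5
while none of the 4-mer bins (3, 11, 12) reaches 1.0. In that case an
exhaustive secondary finder runs: all 3-mers present upstream (spacer
3–15 bp) of at least 20 % of the peaks seed a word set of every 3–6 bp
string containing a seed; words present in fewer than 20 % of peaks (the
same frequency bar as the seeds) merge into the no-motif bin, and the same
iterative training runs over word-by-spacer-class bins. The final RBS score
uses the SD system when SD is detected, the secondary system when its top
word weight reaches 1.0 with a negative no-motif weight, and otherwise the
per-start maximum of the two systems.

## Final scoring and the second dynamic-programming pass

Each start's total is C + 4.25·(R + T + 0.4·U) with the start-signal term
first passed through the length penalty: below the 250 bp equilibrium
length a positive term is scaled by l/250 and a negative term by 250/l,
and any gene with negative C loses a flat 0.5 from its start term. Edge
(partial) starts carry neutral signals (R = T = U = 0).

The DP runs over coordinate-sorted nodes with the nine legal connection
types: gene (5'→3' on either strand); intergenic (3'F→5'F, 3'F→3'R,
5'R→3'R, 5'R→5'F), scored by the distance modifier — +0.5 below 60 bp,
−0.5 above 180 bp in the final pass (±0.2 in the training pass); and
overlap connections scoring the implied second gene only: same-strand 3'→3'
up to 60 bp, and opposite-strand 3'F→5'R up to 200 bp with 5' ends never
overlapping. Intergenic connections are limited to 5 kb (with a
nearest-node fallback so a node desert cannot sever the path), so the
program must choose a gene in every populated region even at a negative
score; a final sweep removes all genes with non-positive totals. When two
genes overlap by exactly 1 or 4 bp on the same strand (operon junctions
such as ATGA) and the downstream gene lacks an RBS with a negative RBS
score, the RBS requirement is waived and that component is raised to 0.
After the traceback, when two starts of the same ORF lie within 15 bp,
coding is treated as equal and the start with the better start weight wins
(ties to the outermost start), provided the swap keeps the neighbors
legal.

The engine keeps one DP state per incoming gene at forward-stop nodes so
the no-5'-overlap rule of the opposite-strand connection is enforced
exactly; the brute-force enumeration oracle in the test suite reproduces
the whole grammar, including its corner cases (paths may begin or end on a
bare node, and overlap connections may originate at a stop that carries no
gene on the path). One asymmetry is inherent to the connection table and
shared with other implementations of it: a forward gene can overlap
neighbors at both of its ends, whereas a reverse gene that 3'-overlaps a
forward gene cannot also 5'-overlap the next reverse gene. Strand-mirrored
inputs therefore yield mirrored calls except in such double-overlap
chains.

Multi-contig input is processed as independent DP problems concatenated in
input order; connections never cross contig boundaries.

## The synthetic benchmark genomes

`genome_spec()`/`generate_genome()` produce genomes with exactly the
statistical structure the trainer assumes, plus a truth table: coding
emitted from a GC-parameterized codon-usage profile (an order-5 Markov
emission that factorizes over codons) with a controllable third-position
GC bias (default GC3 = GC + 0.25); start usage ATG/GTG/TTG =
0.75/0.15/0.10; gamma-distributed gene lengths (mean 900 bp, minimum
150 bp); operon-like gaps (60 % short gaps of 3–25 bp) with injectable 1
and 4 bp same-strand overlaps and 4 bp convergent overlaps built on
consistent shared codons (ATGA, TTAA junctions); and three RBS regimes —
AGGAGG at spacer 5–10 bp ("sd"), a GGTG motif over moderately AT-rich
upstreams ("secondary", A. pernix-like), or strongly AT-rich upstreams with
no motif ("none", cyanobacteria-like). Intergenic composition is solved so
the realized genome GC lands within about two points of the request.
Planted genes are kept free of in-frame stops by construction and repair.

What the generator does **not** emulate: real codon-usage correlations
beyond position-wise composition, laterally transferred or atypical genes,
leaderless transcription, sequencing error, assembly gaps, and genome-scale
heterogeneity. Passing recovery tests on these fixtures shows the
algorithm recovers the signals it models when those signals are present —
not that its accuracy on real genomes matches any published benchmark.

Default test problem sizes, chosen to exercise the statistics at
comfortable margins: 100 kb for unit-level recovery and the 20-genome
stress suite (high density, injected overlaps), 500 kb for regime
detection, hexamer sign recovery, and end-to-end sensitivity, 60 kb for
cheap mechanical checks (with the deliberate under-100 kb training
warning), and ≤ 600 bp for the exhaustive DP-oracle equivalence.

## Numerical choices and degenerate inputs

* Ties in GC-window winners and ORF winners resolve to the lowest codon
  position; DP score ties resolve by a fixed connection-processing order.
* The hexamer clamp (±4), the start-weight clamp (±4), the secondary
  clear-cut gate (1.0), the no-motif pseudo-counts, and the distance
  modifiers are all named constants in `gt_params()`; the test suite
  includes sensitivity checks showing the call set is stable (≥ 90 %
  3'-end agreement) under unit changes of the clamp and modifier choices.
* Training needs at least 20 kb of sequence (hard error) and warns below
  100 kb; an input with no qualifying ORF errors out with advice.
* Upstream windows truncated by a contig edge match what they can; bin 0
  remains admissible. A contig with no candidate gene yields no calls, not
  an error.
* Profiles serialize to versioned JSON at 17 significant digits, so the
  two-step mode (train to file, predict later) reproduces the one-step
  predictions exactly; training and prediction contain no randomness.

## Known limitations

* Accuracy targets here are defined on the package's own synthetic
  benchmarks; no claim is made of reproducing published accuracy numbers
  on real genomes, which require curated references.
* In non-SD regimes the secondary motif system, like the approach it
  implements, can latch onto AT-rich words and admit more marginal calls
  (higher predicted/planted count ratios) than in SD genomes.
* Short genes (< 150 bp planted, < 90 bp in principle) and genes whose
  start signal contradicts the planted regime are the dominant error
  classes on fixtures.
* The metagenomic use case (many short anonymous contigs from mixed
  organisms) is out of scope: training assumes a single organism.
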