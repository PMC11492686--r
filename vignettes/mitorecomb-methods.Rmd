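---
title: "Quantifying repeat-mediated mitogenome recombination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat-mediated mitogenome recombination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitorecomb)
```

## The problem

Angiosperm mitochondrial genomes typically carry a handful of long repeats
(hundreds of bp to >10 kb) present in exactly two copies. Homologous
recombination across such a repeat pair interconverts two alternative
genome arrangements, so the "genome" is really a population of isoforms.
An assembly graph records the contigs and their adjacencies but cannot by
itself say which arrangements dominate; long reads can, because a read
long enough to traverse a repeat copy *plus* unique sequence on both sides
witnesses one specific arrangement.

`mitorecomb` models this situation and estimates isoform proportions from
spanning reads. It also provides the supporting structural analyses that
accompany an organelle genome report: SSR and dispersed-repeat detection,
RSCU codon-usage summaries, and detection of chloroplast-derived segments
(MTPTs).

## The structural model

A `mito_graph` holds single-copy **contigs**, two-copy **repeat
elements**, and adjacencies. Each repeat copy is a *placement*
`(left neighbor, right neighbor)` in the orientation of a master
traversal. A repeat with copies `(L1, R1)` and `(L2, R2)` admits exactly
two conformations:

* **reference** — each copy keeps its own neighbors:
  `L1-LR-R1` / `L2-LR-R2`;
* **crossover** — for a *direct* repeat pair (copies co-oriented),
  recombination exchanges the right neighbors: `L1-LR-R2` / `L2-LR-R1`;
  for an *inverted* pair it joins like flanks, `L1-LR-L2` / `R1-LR-R2`,
  reversing the intervening segment.

Path strings do not record strand, so copy orientation is declared
explicitly (the `copy2_orient` column of the packaged fixture; the
`inverted` argument of `mito_graph_from_paths()`). In the packaged study
data the printed recombinant path labels force this choice: for
*C. carlesii* LR9 and *Ca. henryi* LR7 the minor conformation pairs
left flank with left flank, which is only possible for inverted copies;
the remaining repeats behave as direct pairs.

`resolve_major()` selects one pairing per repeat (the one with the larger
spanning-read proportion; ties keep the reference pairing and are logged)
and walks all adjacencies into molecules. Circular molecules are rotated
to start at the lexicographically smallest contig id; linear molecules
start from their dangling end. Crossover resolution across an *inverted*
repeat would require signed (reversed) contig traversals; the walker
refuses it with an informative error rather than emitting a path whose
orientations it cannot represent. This costs nothing in practice: resolved
molecules follow major conformations, which are the reference pairings
here, and molecule lengths are orientation-independent.

Molecule length is the plain sum of element lengths along the path, a
repeat contributing once per traversal; no overlap subtraction is applied
because contigs and repeat copies are modelled as non-overlapping
segments. Total genome length is therefore invariant under pairing
choices — recombination rearranges sequence, never gains or loses it —
and the test suite asserts this over all direct pairing combinations.

## Spanning-read support

For each repeat and each conformation, `build_windows()` extracts the
repeat copy with up to `flank` bp (default 5000) of sequence on either
side — exactly 5000 where available, truncated (and recorded) at linear
molecule ends, wrapping on circular molecules. Reads are aligned to all
four windows; `classify_support()` accepts a read for a path only if a
*single contiguous* alignment covers the whole repeat interval plus at
least `min_flank` bp (default 50) on both sides. Disjoint fragment pairs
are not accepted: the flank rule is meaningless for split hits. The rule
is the pair of inequalities

```
window_cover.start <= repeat_start - min_flank
window_cover.end   >= repeat_end   + min_flank
```

and the tests check it exhaustively against a position-counting oracle
over all integer cover intervals of a toy window; it is monotone in the
cover interval by construction.

Reads aligning to several windows of the same repeat are resolved by
score; strict ties are discarded as ambiguous and counted. A read is
counted at most once per repeat but may support different repeats
independently (a long read can span two repeat regions).

`tally_support()` sums each conformation's two path counts into its
total; proportions divide by the grand total. Averaging the two paths
instead of summing rescales numerator and denominator identically, so the
proportions are the same under either convention — which is why the
package reports path counts, summed totals and proportions side by side.
For repeats whose two copies are close enough that single reads traverse
copy1–interior–copy2 (e.g. the 481 bp repeat of *Ca. henryi* chromosome
2), *multi-copy mode* fuses the two traversals into one window per
conformation and counts directly. Reported percentages carry exactly two
decimals, rounded half-up, matching the conventional table rendering;
coordinates everywhere are 1-based inclusive.

`estimate_ratio()` attaches Wilson score intervals to the point
estimates; at zero successes the interval is nondegenerate, which matters
for repeats with very skewed mixtures.

## The alignment engine

The default engine indexes window k-mers (k = 15), anchors shared k-mers
(read k-mers sampled every `stride` = 3 positions), keeps the densest
diagonal band (half-width 100 bp), chains anchors by increasing read
position, and scores the chain: equal-length inter-anchor gaps by direct
character comparison, unequal ones by Levenshtein counts, unanchored
tails by ungapped projection clipped at window edges. Identity is
matches over alignment length, with a 0.70 floor in the long-read error
regime. For substitution-only reads the projected coordinates are exact;
under indels they are approximate, which is sufficient for the
flanking-coverage rule (50 bp resolution). Any external local aligner
producing window/read intervals, strand and identity could be plugged in
behind the same record shape; the engine is deliberately contract-first.

## Synthetic data: what it emulates, what it does not

`make_toy_genome()` builds the canonical four-contig geometry: a single
circular master `c1-R-c2-c3-R-c4` whose repeat copies pair four distinct
flanking contigs. The crossover conformation splits it into two circles —
the same combinatorics as the published assembly graphs, at desk scale.
Each undirected adjacency is written once to GFA, giving 5 segments and
6 links.

`simulate_reads()` draws, per read: an isoform (by mixture weight), a
molecule within it (uniform per molecule by default, matching the
interpretation of conformation proportions as molecule-mixture fractions;
length-weighted available), a start (uniform; circular molecules wrap),
and a truncated log-normal length — natural-scale mean 12 kb, sd 6 kb,
minimum 1 kb, capped at the molecule length. The cap is a physical
constraint added here: a read cannot be longer than its source molecule.
Default error rates (substitution 0.05, insertion 0.03, deletion 0.03)
mimic a CLR-like profile; tests that need exactness use zero error.
Reverse-complementing happens with probability 0.5 and provenance is
recorded per read.

Because the toy geometry is symmetric (both conformations expose the same
number of repeat copies per unit length), the crossover fraction among
*valid spanning* reads is an unbiased estimate of the mixture proportion,
and zero-error recovery error is purely binomial. What the generator does
**not** emulate: realistic PacBio error kinetics, chimeric reads, nuclear
contamination, coverage biases. A green end-to-end test therefore
establishes the correctness of windowing, classification and tallying —
not robustness to every real-world artefact.

`plant_mtpt()` overwrites random disjoint mitogenome intervals with
chloroplast intervals mutated to a target identity (point mutations only,
Bernoulli per base), returning exact truth intervals. `make_cds_set()`
draws internal codons from configurable weights between an ATG start and
a uniform stop.

## Repeat detection choices

SSRs follow the MISA convention: maximal perfect tandem runs of 1–6 bp
motifs at minimum copy numbers 10, 5, 4, 3, 3, 3. A run is reported once,
under its shortest primitive motif at its leftmost start; trailing
partial copies are not counted, so interval length equals motif length ×
copy number. Composite/compound SSR merging is not reproduced — the
downstream summaries only need counts by motif class.

Dispersed repeats are maximal interval pairs matching under one of four
orientation transforms with Hamming distance ≤ 3 and length ≥ 30 bp
(REPuter-style classes; indels are not modelled, matching the
Hamming-distance parameterisation). Candidate diagonals come from shared
exact seeds; the pigeonhole bound says a qualifying repeat contains an
exact run of ⌈(min_len − k)/(k + 1)⌉ = 7 bp, and the seed is capped at
32 bp for large `min_len` so sensitivity is never lost. Each candidate
diagonal is scanned exactly: maximal windows are delimited by the
(k+1)-th mismatch on each side or the diagonal ends. Self-overlapping
pairs are excluded (tandem territory), unordered pairs are counted once,
and output is capped (default 5000) by descending length. Length bins
follow the conventional 30–39 / 40–49 / 50–99 / 100–399 / ≥400 bp, the
last bin closed on the left.

## Codon usage

Counts are frame-0 triplets; trailing incomplete codons are trimmed with
a warning (annotation edge cases must not abort a pipeline), codons
containing N are skipped and tallied, stops are counted separately and
excluded from RSCU. The genetic code defaults to the standard table,
which plant mitochondria use; single-codon families (ATG, TGG) have RSCU
identically 1 when observed, zero-observation families report NA, and
family sums equal family sizes by construction — all asserted as
invariants.

## MTPT detection

Seeded (word 11) ungapped extension on both strands, scored +1/−2, with
significance from the ungapped Karlin–Altschul formula using λ ≈ 1.28 and
K ≈ 0.46 for these scores and the two genome lengths as m·n; hits above
the E-value threshold (default 1e−5) are dropped. Bit-for-bit BLASTN
equivalence is a non-goal — correctness is established by planted-truth
recovery. Chloroplast genomes carry a large inverted repeat, so a single
transferred segment can produce two chloroplast-side hits; hits whose
chloroplast intervals fall in distinct copies of a chloroplast repeat
(found by self-comparison at ≥1 kb) but cover >90% of the same mitogenome
interval are deduplicated keeping the best E-value rather than discarded —
transfers of repeat-resident genes (e.g. rrn16) must survive the filter.
Totals are computed on the union of mitogenome intervals, making "total
MTPT length" a genome-coverage quantity that is invariant under splitting
hits into abutting pieces.

## Numerical and degenerate-input conventions

* Percentages: two decimals, round half-up (not banker's rounding).
* Zero valid reads: proportions are NA, printed as NA.
* Tied conformation support: the reference pairing is kept and a message
  is emitted.
* Ambiguous multi-mapping: strict score ties are discarded and reported,
  with a configurable margin.
* Windows: flank truncation is recorded; a circular molecule smaller than
  one window is an error rather than a silently wrapped double-count.
* All generators are bit-reproducible under a fixed seed; pipeline
  outputs embed the seed in their provenance headers.

## Known limitations

* Crossover resolution across inverted repeat pairs is recognised but not
  walked (no signed paths); pairing enumeration, labels and proportion
  estimates fully support inverted pairs.
* The dispersed-repeat engine is exact but quadratic per candidate
  diagonal; it is sized for organelle genomes (≤ a few hundred kb), not
  nuclear chromosomes.
* The alignment engine reports one best alignment per read×window; true
  split/supplementary alignment handling is out of scope, consistent with
  the contiguous-alignment validity rule.
* Simulated coverage is uniform; depth-based checks
  (`depth_consistency()`, default ±10% relative tolerance) are validated
  on simulated data and are advisory on real tables.
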