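---
title: "Methods: structural heteroplasmy and repeat-mediated recombination in circular mitogenomes"
author: "mitostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural heteroplasmy and repeat-mediated recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostruct)
```

## The problem

Plant mitochondrial genomes are recombinationally dynamic. Homologous
recombination between the two copies of a *direct* repeat on one circular
molecule excises it into two subgenomic circles; recombination between
copies on two different circles fuses them back together. Composing these
two events at two different repeat pairs can interconvert alternative
arrangements of the same genome — two structural "types" that coexist
within an individual as *structural heteroplasmy*, often with one type at
a few percent frequency. Short-read data can quantify this: a read that
fully spans a repeat motif *and* both of its flanks witnesses which flank
pairing — and therefore which genome structure — it came from.

`mitostruct` implements this analysis chain on circular genomes:

1. **genome model** — circular sequences, 0-based half-open intervals with
   origin wrapping, signed block arrangements, canonical rotation;
2. **repeat finder** — direct/inverted repeat pairs under a minimum-length
   and maximum-mismatch-fraction contract;
3. **recombination** — deterministic intra-/inter-molecular crossover
   operators and the two-step rearrangement;
4. **heteroplasmy** — diagnostic junction construction and
   junction-spanning read classification with a frequency table;
5. **pseudogene** — frameshift / premature-stop / truncation diagnosis of
   a locus against an intact reference CDS;
6. **intron configuration** — cis/trans classification of a
   matR-containing group-II intron (nad1i728-like), with wheat/petunia
   subtypes and breakpoint-deletion measurement;
7. **synthetic data** — generators for all of the above with recorded
   ground truth.

## Circular coordinates and structure equality

All coordinates are 0-based half-open. An interval on a circle of length
$n$ has `start` in $[0, n)$ and `end` in $(\mathrm{start}, \mathrm{start} + n]$;
`end > n` means the feature crosses the sequence origin. This makes
interval arithmetic on circles unambiguous (width is always
`end - start`) at the cost of one convention to remember.

Circular DNA has no intrinsic origin or strand, so two circular molecules
are *structure-equal* iff one is a rotation of the other or of its reverse
complement. `canonical_rotation()` picks the lexicographically smallest
rotation over both strand readings as a unique representative — an
artifact convention, not a biological origin. The same idea applies to
block arrangements: `same_structure()` compares signed label cycles up to
rotation and reversal-with-sign-flip.

## Repeat detection

`find_repeats()` reports pairs of equal-length, non-overlapping intervals
whose aligned reading (reverse-complemented for inverted pairs) differs at
$m$ substitutions with $m/L \le f$ (default $f = 0.10$) and
$L \ge \texttt{min\_len}$ (default 30 bp). Comparison is ungapped and `N`
never matches anything, including `N`.

**Semantics.** A reported window is *one-step maximal*: extending the
aligned window by one base on either side either violates the mismatch
bound or would make the two copies overlap. Because the budget is a
fraction, one physical repeat typically supports many staggered maximal
windows, each absorbing a different set of flanking mismatches; windows
that overlap on one alignment diagonal are therefore collapsed to a single
reported pair per locus (longest, then fewest mismatches, then smallest
start). Pairs fully contained in a longer reported pair are suppressed.

**Algorithm.** Every candidate pair lies on a diagonal: the offset
$d = (b - a) \bmod n$ for direct pairs, the anti-diagonal
$u = (a + b + L - 1) \bmod n$ for inverted pairs. Any window of length
$\ge \texttt{min\_len}$ and density $\le f$ contains an aligned
`min_len`-sub-window of density $\le f$ (averaging over sub-window
positions), so screening each diagonal for its best `min_len` window is a
*complete* filter — no seeding heuristic, no missed repeats, and exact
agreement with a definitional brute force is testable. On surviving
diagonals, maximal windows are enumerated analytically: a
mismatch-bounded maximal window must start right after a mismatch, end
right before one, and satisfy $m \le fL$, $m + 1 > f(L+1)$;
geometry-capped windows (extension blocked by copy overlap) are
enumerated from the diagonal arithmetic separately. A k-mer seeding stage
was considered and rejected: a feasible 30 bp window with 3 mismatches is
only guaranteed an exact run of 7 bp, so any practical seed length can
miss valid windows, which would break the finder's exact equivalence with
brute force.

**Behaviour to know about.** Under a 10% budget, a planted exact repeat of
length $M$ in random sequence is reported as a window up to roughly
$1.18M$ long: the maximal window keeps absorbing flanking mismatches until
their density pushes the window to the bound (a 3.5 kb exact repeat can
report as ~4.1 kb at 90% identity). The reported locus always *contains*
the true repeat. The scan is quadratic in genome length
(all $1.5n$ diagonals at $O(n)$ each) and is intended for the
kilobase-to-tens-of-kilobase toy circles used throughout; hundreds of
kilobases are feasible but take minutes.

## Recombination operators

`intramolecular_recombine()` places the crossover at the motif's 5'
boundary: product 1 is the arc from the start of `copy_a` to the start of
`copy_b` (carrying one full motif copy), product 2 the complementary arc
with the other copy. For copies identical up to the allowed mismatches,
all crossover placements yield structure-equal products, so one canonical
placement keeps outputs deterministic; where copies differ, each product's
motif sequence is the copy 5' of its crossover. Gene conversion is not
modelled. Lengths are conserved exactly; re-integration
(`intermolecular_recombine()`) at the same pair restores a structure-equal
molecule, and `two_step_rearrangement()` (short-pair excision, then
long-pair re-integration) is an involution on structures when the
short-repeat copies separate the long-repeat copies — its precondition,
checked and reported as an error otherwise.

## Junction classification

`build_junctions()` extracts, for each motif copy in each genome, the
window *flank + motif + flank* (default flank 30 bp; window
$61 + 2\times30 = 121$ bp for the default motif). After a flank-swapping
recombination the B-type windows carry the cross-combinations of the
A-type flank pairings, which is what makes them diagnostic.

`classify_reads()` compares each read (both orientations) against the four
junctions by banded, gapless sliding (Hamming distance at every offset
where the junction fits inside the read). A read is:

* **uninformative** — no placement covers motif + both flanks within
  `max_mismatches` (default 3 over the window);
* **A** / **B** — placements match only one type's junctions;
* **ambiguous** — both types match; ties are *not* resolved, and
  ambiguous reads are excluded from the analyzed count, matching a hard
  count table rather than fractional assignment.

Mates of a pair are classified independently (a 121 bp window is rarely
spanned by both mates, and the count unit is the read). A Wilson 95%
interval for the minor-type fraction accompanies the counts:
low-frequency types at 1/114-scale counts need uncertainty attached.
Percentages are formatted at one decimal with half-up rounding
(`round_half_up()`), the convention of published count tables;
base R `round()` would round 0.05 down.

The `max_mismatches = 3` default is a transparent stand-in for the opaque
"medium-low sensitivity" of GUI mappers: with 30 bp flanks the A- and
B-junctions differ at many positions (random flanks differ at ~75% of
sites), so misclassification requires ~tens of coincident errors and in
simulation at a 0.002/bp error rate effectively never occurs; the
parameter is exposed for sensitivity analysis.

## Pseudogene scanning

`scan_pseudogene()` aligns the candidate to an intact reference CDS with
`Biostrings::pairwiseAlignment` (global on the candidate, local on the
reference so fragments align freely; match 2, mismatch −3, gap open 10,
gap extend 1). Indels are projected to reference coordinates; the
candidate is then translated *linearly* from the first in-frame aligned
codon, so frame changes propagate downstream exactly as they would for a
ribosome. Status:

* **absent** — no alignable region of ≥ 30 bp at ≥ 60% identity;
* **pseudogenized** — net reading-frame offset ≠ 0 over the aligned
  region, or any premature stop codon, or loss of more than 20%
  (configurable) of the reference 3' end;
* **intact** — otherwise.

The frame offset is cumulative, not per-event: a +1 insertion compensated
by a downstream −1 deletion with no stop codon in the shifted segment
leaves the gene intact, although both events are still listed in the
report. `shared_diagnostic_events()` intersects frameshift events across
reports (same indel sign, position within ±2 bp) to recover a single
ancestral pseudogenizing mutation — the shared early-5' "A" insertion
pattern — from a set of independently decayed copies. Stop codons use the
standard genetic code (appropriate for plant mitochondrial ribosomal
protein genes); C-to-U RNA editing, which can rescue apparent stops, is
deliberately not modelled — the diagnosis is DNA-level.

## Intron configuration

`classify_intron_configuration()` takes located exon4/matR/exon5 features.
The locus is **cis** when all three sit on one strand, in transcriptional
order, within `max_cis_span` (default 10 kb — plant mitochondrial cis
introns are kilobase-scale; the contiguity criterion is a convention the
data sources leave implicit). Otherwise the configuration is **trans**:
*petunia* type when exon4+matR remain collinear and exon5 is elsewhere
(breakpoint between matR and exon5), *wheat* type when exon4 stands alone
(breakpoint between exon4 and matR). The inter-locus distance is the
circular distance from the 3' end of the upstream locus to the 5' start of
the downstream locus; since a circle has two arcs and the convention in
published figures is not stated, both arcs are reported
(`locus_distance` is the shorter). Classification is invariant to
rotation and to a global strand flip, both tested.

`breakpoint_deletion()` measures reference sequence lost at the split: the
two trans locus sequences (contigs) are locally aligned to the contiguous
reference region of a cis relative, and the intron bases covered by
neither alignment are counted. On error-free synthetic splits this equals
the planted deletion exactly.

## The synthetic-data generator

`make_toy_genome_pair()` emulates the measurement conditions, not any real
genome: an i.i.d. uniform background (which makes planted repeats the only
expected ≥ 30 bp repeats and junction flanks diagnostic with overwhelming
probability), a 3.5 kb and a 61 bp direct repeat pair planted in
alternating order around the circle (the two-step precondition), four
random arcs at fixed proportions 28/22/31/19% of the non-repeat length,
and the B-type derived by `two_step_rearrangement()` itself. The default
repeat lengths are 3500/61 bp following the figure-caption values of the
motivating study (its running text also mentions 3000/62; both are plain
parameters). The default 30 kb circle is a deliberate scale-down from a
~420 kb mitogenome: junction classification sees only reads near the two
short-repeat copies, so the genome length only sets the uninformative-read
fraction, and 30 kb keeps a 20-replicate study in tens of seconds.

`simulate_reads()` draws read positions uniformly on the circle, picks
the source genome per read as Bernoulli(`weight_b`), and applies i.i.d.
substitution errors (default 0.002/bp). Indels, quality-dependent error
profiles, GC bias, and instrument-specific artifacts are *not* modelled.
Passing tests therefore demonstrate the classifier's arithmetic and its
robustness to substitution noise, not performance on real libraries —
with real reads, indel errors near the junction simply push reads into
the uninformative class by the span rule. Expected spanning reads per
junction window of width $w$: about
$2 \cdot \text{coverage} \cdot (\text{read\_len} - w + 1)/\text{read\_len}$;
at 80× with 150 bp reads and a 121 bp window, ≈ 32 analyzed reads, the
same order as published per-individual counts (70–121).

`make_pseudogene_set()` gives every copy the same +1 "A" insertion within
the first 60 bp ("early 5' site") and decays copies privately:
substitutions Poisson(4), a private 1–3 bp indel with probability 0.3
placed ≥ 80 bp downstream of the shared event (so positional intersection
at ±2 bp slop stays unambiguous), and a 10–40% 3' truncation with
probability 0.3.

All generators are pure functions of their parameters and seed
(byte-identical reruns); seeds are ordinary integers.

## Numerical and design choices

* Feasibility comparisons use `m <= f*L + 1e-9`: with $f$ not
  representable in binary, the epsilon keeps integer budgets like
  $0.1 \times 30 = 3$ on the intended side.
* Junction labels A1/B1 go to the motif copy nearest the origin of the
  given genome record — deterministic, though not biologically meaningful.
* A read matching A- and B-junctions at equal distance is ambiguous; there
  is no evidence either way.
* `arrangement_of()` lists blocks from the block containing position 0;
  reconstruction concatenates block sequences in listed order and
  orientation.
* Error handling favours loud failure: wrong repeat orientation, overlap
  geometry, motif occurrence ≠ 2, missing intron features, cis input to
  `breakpoint_deletion()`, and invalid reference CDSs are all distinct
  errors.

## Problem sizes used by the test suite

Oracle-equality tests for the repeat finder run on 50 circles of
0.4–1.2 kb against an independent definitional brute force; mixture
recovery runs 20 replicates per weight (0.9%, 5%, 95%) at 80× on 30 kb
pairs and checks the planted weight against each replicate's Wilson 95%
interval; the two-step involution, pseudogene battery (six mutation
classes), and intron constructions (cis / petunia at an 84,430 bp
separation / wheat / 0, 100 and 449 bp planted breakpoint deletions) run
on kilobase-scale fixtures. These sizes were chosen so the whole suite
exercises every claim in a few minutes while keeping every expected value
either derived from planted truth or computed by an independent oracle.

## Known limitations

* The repeat finder is ungapped; diverged repeats containing indels are
  reported as separate loci or not at all. Tandem repeats (overlapping
  copies) are out of scope.
* Reported repeat windows over-extend exact repeats by up to ~18% under
  the default 10% budget (see above); consumers needing exact motif
  boundaries should intersect with high-identity sub-windows.
* The heteroplasmy estimator is a hard classifier; no mixture model or EM
  over read likelihoods is attempted, and the Wilson interval quantifies
  only counting noise, not mapping bias.
* Pseudogene calls ignore RNA editing and alternative start codons.
* Recombination operators model single deterministic events, not
  recombination dynamics, rates, or substoichiometric shifting across
  generations.

## A worked end-to-end run

```{r demo, eval = FALSE}
res <- run_demo(seed = 1, out_dir = "mitostruct-demo")
res$table
#>        label analyzed n_A pct_A n_B pct_B
#> 1 demo-seed1       35   2   5.7  33  94.3
```

The demo writes the genome pair (FASTA), the repeat table (TSV), the
simulated reads (FASTQ), the structure-frequency table, the pseudogene
report, and the intron report into `out_dir`, each regenerable from the
seed alone.
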