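---
title: "Detecting and modelling integrase-driven chromosomal inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling integrase-driven chromosomal inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoflip)
```

## The problem

Hyperthermophilic archaea of the genus *Thermococcus* shuffle their
chromosomes by large (tens to hundreds of kb) inversions so frequently
that closely related genomes are hard to align. These inversions are not
the work of the host's homologous-recombination machinery: their
endpoints fall inside pairs of paralogous sequences — tRNA genes,
chemotaxis genes, transposase and dehydrogenase paralogs — that share a
perfectly conserved core of roughly 100–620 bp in inverted orientation,
and the causal agent is a mobile-element tyrosine integrase that, besides
the canonical site-specific reactions (integration, excision, inversion
between attachment sites), catalyses *low-sequence-specificity*
recombination between any pair of identical segments down to about
100 bp, with the same outcome as homologous recombination.

`chromoflip` implements the complete computational side of studying this
phenomenon as five analysis stages over a bundled synthetic-data
generator:

1. **anchor/synteny stage** — exact-match anchoring of two genomes,
   chaining into signed synteny blocks, and extraction of the block
   permutation, breakpoints and inversion segments;
2. **breakpoint forensics** — the maximal perfectly conserved (direct or
   inverted) segment shared by the flanks of each breakpoint, global
   flank identity, and crossover localization between informative
   mismatches;
3. **inversion-history reconstruction** — exhaustive search for minimal
   sequential inversion scenarios whose endpoints are restricted to the
   recovered repeat pairs, with per-pair orientation tracked along a
   scenario;
4. **recombination engine** — an in-silico model of the integrase's
   reactions on annotated DNA maps, with restriction-digest and PCR
   readouts;
5. **population genotyping** — a two-pass read mapper, diagnostic-position
   read classification for inversion-allele fractions, and depth-ratio
   plasmid copy-number estimates.

All coordinates in the package are **0-based, half-open**; reports and
documentation state this. Intervals on circular molecules may wrap.

## Stage 1: anchors, blocks, permutations

`find_anchors()` reports every maximal exact match of length ≥ `min_len`
(default 24) between the two genomes, in both orientations, seeded by
shared k-mers (`k = 16`) with k-mers occurring more than 10 times masked
from seeding. Exact matching (MUM-style) rather than alignment is
appropriate because the compared genomes are conspecific: diverged
regions simply fall into breakpoint gaps. Circularity is handled by
doubling the second genome and de-duplicating wrapped hits modulo its
length; copies truncated at the doubling boundary are removed by a
containment test on the diagonal class.

Two repeat-specific artefacts require care, and both are handled before
chaining:

* an anchor whose footprint is **contained** in a ≥ 2× longer anchor's
  footprint on either genome is a repeat-induced cross-match (a
  paralogous core matching its partner copy), not collinear backbone;
  it is discarded — the repeats themselves are recovered, deliberately,
  by stage 2;
* the two mirror cross-matches of an inverted repeat pair lie on a
  common anti-diagonal and would chain into a phantom inverted block
  across unrelated sequence; blocks must therefore have at least
  `min_anchor_frac` (default 25%) of their span covered by exact
  matches.

`chain_to_blocks()` is greedy single-linkage over q-sorted anchors
(`max_gap` 20 kb both on q and s, `slack` 1 kb of tolerated overlap —
anchors at inversion borders legitimately overlap by up to the repeat
core length, because the junction regenerates a full core). Chains
spanning < `min_block` (5 kb) are discarded: the inversions of interest
are 10–150 kb, so blocks an order of magnitude smaller suffice.

`blocks_to_permutation()` lists blocks in genome-2 order with signs. A
breakpoint is every genome-2 adjacency that is not
adjacent-and-co-oriented on genome 1. A breakpoint junction joins two
genome-1 locations that may be tens of kb apart — one copy of the
recombination substrate sits at each — so both junction-facing endpoints
are reported rather than a single "gap" interval. Inversion segments are
maximal runs of minus-oriented blocks; their sizes are reported as both
the genome-1 and genome-2 span, since the two differ whenever repeats of
unequal flank length recombine.

## Stage 2: repeat substrates at breakpoints

"Sequence identity" is used in two senses, and the package reports both:
the **core** is the maximal *perfectly* identical shared segment
(`longest_shared_segment()`, exact, `N` never matches, ties broken by
smallest position), while `percent_identity()` is a global
Needleman–Wunsch alignment statistic (match +1, mismatch −1, gap open
−2, gap extend −1 — fixed and documented because no standard exists)
over the whole extracted flanks.

`longest_shared_segment()` runs a seeded maximal-match search (exact for
any shared segment ≥ 20 bp) and falls back to an exhaustive
per-diagonal scan when nothing that long is shared, so it is exact at
all lengths; the test suite checks it against an independent
binary-search-over-substring-sets oracle on hundreds of random
instances.

`characterize_breakpoints()` windows ±2000 bp (the window used when
extracting breakpoint regions from real sequencing data) around each
*clustered junction endpoint* and matches **all pairs** of endpoint
windows in both orientations, pairing endpoints greedily by descending
core length. The all-pairs generalization matters: under nested or
overlapping histories the left and right junctions of one minus-run need
not be copies of the same repeat pair, so the naive "two flanks per
inversion" pairing would compare the wrong windows. Cores from different
pairs are checked for any shared segment ≥ 20 bp — an exact-match
criterion replacing tool-dependent BLAST E-value thresholds.

`localize_crossover()` takes two gap-free aligned parents and a
recombinant and reports the maximal interval `(l, r]` between informative
positions (columns where the parents differ) such that the recombinant
matches parent A at informative positions ≤ l and parent B at ≥ r.
Within a perfectly conserved core there are no informative positions, so
crossovers are localizable only to an interval — as in real data, where
sequencing a recombinant junction places the crossover downstream of the
last discriminating mismatches. Chimeric patterns requiring more than
one crossover raise an error; a recombinant identical to one parent
returns a `no_crossover` status.

## Stage 3: scenario reconstruction

Scenarios are searched exhaustively (breadth-first over permutation
states) rather than via Hannenhalli–Pevzner theory: realistic instances
have 4–12 blocks, and the deliverable is the *set of minimal scenarios*
under substrate constraints, which distance theory alone does not give.
The search is guarded at `max_n = 12` blocks.

The constrained search tracks repeat copies as **markers** interleaved
with the blocks. An inversion bounded by a pair reverses (and
sign-flips) everything strictly between its two markers and leaves the
markers in place: because the crossover falls at the core midpoint and
the two copies share the core exactly, both junctions retain a full core
in its original orientation — so a pair remains a substrate after firing
(inversion is an involution), and a pair whose *one* copy lies inside
another event's span flips between direct and inverted orientation.
This single rule reproduces the observation that some pairs sit in
direct orientation in an ancestral genome and only become inversion
substrates after an earlier overlapping inversion. A pair is a legal
endpoint only while its copies are in inverted orientation and only if
its conserved core is at least 100 bp (the smallest substrate the
integrase uses efficiently); incompatible or direct-orientation pairs
are simply not in the move set, which is how the engine also represents
the observed *failure* of recombination between non-identical tRNA
pairs. "Unreachable" is a legitimate answer, reported as `Inf`.

Minimal scenarios are enumerated by depth-first search to the BFS depth,
each verified by re-application, canonically ordered, and capped
(default 1000) with an explicit truncation flag. Sequence-level
application (`invert_between_pair()`) reverse-complements the half-open
interval between the two core midpoints; for odd core lengths the
junction cores regenerate to length `core − 1`, so the bundled generator
defaults to even cores (the naturally observed ones are even).

## Stage 4: the recombination engine

`site_recombine()` implements the classical reactions on annotated
molecules. Recombination is legal only between sites whose **cores are
identical** in the oriented frame (reverse-complement for inverted
geometry); the crossover sits at a configurable offset within the core,
defaulting to the midpoint since real crossovers are only localizable to
an interval. Geometry chooses the reaction: two circles give a
co-integrate; co-oriented sites on one molecule give excision (two
circles from a circular substrate, a deletion from a linear one);
inverted sites give an in-place inversion.

Hybrid product sites are composed as *upstream partner's prefix up to
the crossover + downstream partner's suffix*. This single convention
fixes the product sizes: a circular substrate carrying an 87-bp site, a
762-bp spacer and a 43-bp minimal site in direct orientation excises a
circle of 762 + 87 = **849 bp** (spacer plus one full-length hybrid
site), not 762 + 43 = 805 — regardless of the crossover offset, because
what the circle gains on one side of the crossover it loses on the
other. Features overlapping a reaction junction are split and suffixed
`:5p`/`:3p`; hybrid att sites are renamed (attP × attB → attL/attR).
Nucleotide conservation (sum of product lengths = sum of substrate
lengths) is asserted across the test suite, and excision∘integration is
verified to be the identity on sequences-as-circles.

`homologous_recombine()` models the integrase's low-sequence-specificity
mode: every maximal perfectly shared segment ≥ `min_core` (default
100 bp, the smallest active substrate observed in vitro) is treated as a
generic att-site pair and recombined. Reaction kinetics are *not*
modelled; the core length is reported as a qualitative proxy for the
observed efficiency gradient (site-specific reactions equilibrate in
minutes, low-specificity ones take hours).

`digest()` scans both strands for exact recognition sites (cut placed at
the site start — fragment sizes are invariant to the within-site offset)
and understands topology: s sites cut a circle into s fragments, a
linear molecule into s + 1; an uncut circle is reported as such.
`pcr_predict()` uses exact primer matching (v1) and reports convergent
products within `max_len`, including across the origin of circular
molecules, which is what makes outward-facing primers on an integrated
element diagnostic for excision: they yield a product only from the
excised circle.

Since the true sequences of the in vitro constructs are unpublished,
`build_construct_map()` builds *reconstructions*: random filler scrubbed
of stray recognition sites, with enzyme positions solved by exact
integer search against the printed pre- and post-reaction fragment
sizes. For the inverted-site plasmid the solver finds enzyme placements
(e.g. one site inside the spacer at offset 289 or 727) such that the
intact plasmid digests to {2796, 1777} and the inversion product to
{2358, 2215}; these maps validate the engine against the printed gel
readouts without claiming to be the true plasmids.

## Stage 5: population genotyping

The mapper is a bespoke seed-and-extend (ungapped) aligner so that the
pipeline is fully self-contained and desk-testable: exact k-mer seeds
(k = 21) at `max_mismatch + 1` disjoint offsets per strand — by
pigeonhole, a read with ≤ `max_mismatch` substitutions always has one
clean seed — with candidates scored by Hamming distance and a read
placed only at a *unique* best position with ≤ `max_mismatch`
mismatches. Reads inside two-copy exact repeats tie and are `ambiguous`;
ambiguous reads never contribute to diagnostics. `two_pass_assign()`
maps everything to the ancestral reference, then maps the unmapped pool
to the derived reference, mirroring the metagenome procedure. The
mismatch allowance should scale with read length × error rate (3 for
100-bp reads at 1%, 8 for 250-bp reads).

A point that shapes the whole design: **recombination between perfect
repeat copies creates no locally novel sequence.** Around each junction
the derived genome reads, through the entire conserved core, exactly
like the ancestral genome near one copy or the other; derived-origin
reads that do not span the whole core map *perfectly* to the ancestral
reference (possibly at the mirrored locus). Only reads spanning the full
core **plus discriminating flank bases on both sides** carry any
information about the junction allele. `make_site_diagnostics()`
therefore anchors each junction at a coordinate just outside the core on
the non-inverted side and picks diagnostic positions just beyond the
core's far edge where the two references differ;
`classify_breakpoint_reads()` counts a read only if its alignment covers
the anchor, at least one diagnostic position, *and* reproduces the
shared reference bases at a 4-bp flank-identity window at the anchor.
The anchor-coverage rule excludes derived-interior reads exactly (their
mirrored alignments lie wholly inside the inverted span); the
flank-identity check removes the residual contamination from reads that
overhang the *partner* junction by a few bases and mirror-map within the
mismatch allowance while carrying foreign flank sequence. Consequently
mixture simulations use MiSeq-like 250-bp reads and ~104-bp cores (the
shortest natural substrate), so that reads can span core + flanks; with
100-bp reads, junctions with cores ≥ ~92 bp are strictly
non-genotypeable at the read level — a real limitation of short-read
genotyping of repeat-mediated inversions, not of the implementation.

Reads are classified ancestral/derived/other (bases matching neither
expectation, i.e. sequencing errors, are reported but excluded from the
denominator). The derived-allele fraction comes with a 95% Wilson score
interval computed on the number of *distinct informative reads*: the two
diagnostic positions of a junction lie within one read length of each
other, so pooled base counts would double-count reads and the nominal
interval would under-cover. Per-position base counts are still reported.

`depth_ratio()` averages per-base depth over a target region and over
the chromosome excluding masked regions, reporting the ratio as copies
per chromosome; for a target that is an integrated locus also resident
once on the chromosome, `target_baseline_copies = 1` subtracts the
resident copy.

## The synthetic-data generator

`make_genome_with_repeats()` plants repeat pairs in i.i.d. background at
a chosen GC content. Two details make downstream truth checks exact:
cores of different pairs are rejection-sampled to share no 20-mer
(mirroring the absence of inter-pair similarity in the natural pairs),
and the bases immediately flanking each copy are forced to differ
between the copies, so the maximal shared segment equals the planted
core length exactly rather than being extended by chance flank
agreement (which would otherwise happen to ~44% of pairs).

`apply_truth_history()` samples event sequences by randomized
backtracking over the legal-move tree (distinct pairs, each in inverted
orientation at its turn) and accepts a sequence only if the
endpoint-constrained minimal distance equals the event count and every
created junction is still a breakpoint of the final arrangement — the
study condition is "k genuinely independent inversions", not "k button
presses". Notably, many repeat geometries admit *no* valid k-event
history over exactly k pairs (each event flips the orientation of pairs
with one copy inside its span, and the flips can extinguish the move
set); simulations therefore plant a few more pairs than events.

`simulate_reads()` draws uniformly positioned (circular-aware),
random-strand, single-end reads with independent substitutions at a
constant rate and constant Phred-40 quality; read names carry the truth
(`src`, `pos`, `strand`) after a reserved `|` delimiter that all
consumers ignore. Indels, quality ramps, coverage biases and paired ends
are deliberately out of scope: the mapper is ungapped and the
classification uses base calls only, so none of these would exercise
tested behaviour. This also bounds what passing tests show about real
data — real Illumina errors are indel-containing and quality-dependent,
and real paralog flanks are ~90–97% similar rather than i.i.d.
background, so real informative-read yields will differ.

`simulate_passaging()` is a neutral Wright–Fisher sketch of the serial
50-fold-dilution culture design (bottleneck every ~6 generations ≈
log2(50)); the per-pair inversion rate is invented scaffolding, clearly
labelled, because no per-generation rate has been measured.

## Parameter summary

| parameter | default | unit | rationale |
|---|---|---|---|
| `k` (anchoring) | 16 | bp | unique in Mb-scale genomes; masked above 10 occurrences |
| `min_len` (anchor) | 24 | bp | suppresses chance matches (4^-24 per position) |
| `max_gap` / `min_block` | 20 000 / 5 000 | bp | inversions of interest are ≥ 10 kb |
| `min_anchor_frac` | 0.25 | — | rejects anti-diagonal phantom blocks |
| forensics `window` | 2 000 | bp | the breakpoint-region window used on real data |
| `min_core` (endpoints) | 100 | bp | smallest substrate active in vitro/in vivo |
| inter-pair check | 20 | bp | exact-match replacement for E-value screens |
| mapper `seed_k` / `max_mismatch` | 21 / 3 | bp / count | pigeonhole seeding; scale allowance with read length × error |
| diagnostics per junction | 2 | — | the number used on the real populations; pooling generalizes to n ≥ 1 |
| `anchor_margin` / `check_len` | 12 / 4 | bp | excludes mirror-mapped partner-junction reads |
| reads | 250 bp, 1% subst., Phred 40 | — | MiSeq-like; reads must span core + flanks |

## Numerical and degenerate-input choices

Ties in `longest_shared_segment()` break to the smallest position in A,
then B. Chaining is leftmost-first greedy and RNG-free; scenario output
is sorted lexicographically. Empty anchor lists, zero breakpoints, zero
planted pairs, uncovered diagnostic positions (explicit `NA`), uncut
circular digests, and unreachable scenario targets all return typed
empty/flagged results rather than errors; genuinely contradictory inputs
(overlapping blocks, incompatible cores, chimeric recombinants,
crossover offsets outside the core) raise errors that name the problem.
Every generator is bit-reproducible from its seed.

## Problem sizes used in the tests

The bundled suites run at desk scale, chosen so the full suite completes
in a few minutes: 200-kb genomes with 2–5 planted inversions for the
recovery sweeps (20 seeded configurations), 30-kb genomes at 100×
coverage for mixture recovery (two mixtures × ten seeds), 500 random
instances (≤ 2 kb) for the shared-segment oracle, n ≤ 7 permutations
for the reversal-distance oracle, and 1000 reads for the mapper oracle.
The analysis scripts under `analysis/` re-run the same stages
narratively and write their tables under `results/`.

## Known limitations

* Gapped alignment is absent throughout (mapper, crossover
  localization); indel-bearing reads are simply unmapped.
* Translocations and transpositions are out of scope; only inversions
  are modelled, matching the observed rearrangement spectrum.
* The "identical core" legality rule for site-specific recombination is
  a deliberate simplification: the sequence determinants of why some
  non-identical site pairs fail are unknown.
* Scenario enumeration is exhaustive and exact but limited to ~12
  blocks; larger instances need a lower-bound backend rather than this
  package.
* Gene conversion between tandem conserved regions of one paralog pair
  (observed once in the natural data) is reported as two separate cores
  but not modelled as a process.
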