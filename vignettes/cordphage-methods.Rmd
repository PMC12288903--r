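---
title: "Methods: phage detection and dyad sharing in cell-free DNA"
author: "cordphage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage detection and dyad sharing in cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordphage)
```

## The problem

Cell-free DNA (cfDNA) in plasma is dominated by short human fragments
(typically 50–200 bp) with a small microbial component that includes
bacteriophage DNA. Detecting phage sequences in such data, and asking
whether the phages found in an umbilical-cord blood sample match those in
the mother's blood, requires care on three fronts:

1. a 75-bp read aligned against hundreds of thousands of partly redundant
   phage database sequences will often map to many of them
   (multimapping);
2. with fragments this short, a handful of spurious alignments can mimic
   a phage, so presence calls must demand both read support and breadth
   of genome coverage; and
3. "everything is everywhere" contamination must be separated from
   biological sharing before pairs of samples are compared.

`cordphage` implements the analysis stage of this problem: it consumes
per-sample alignment hit tables (the standard 12-column tabular output of
a nucleotide search, one table per sample and database), the database
FASTA/metadata, and a sample sheet with maternal/fetal dyad structure,
and produces presence/absence calls and sharing statistics.

## Multimapper resolution

Hits are first filtered to e-value strictly below `evalueMax`
(default 5e-4). Within each database, reads hitting exactly one phage are
fixed immediately and define each phage's *unique-mapping-read tally*.
Remaining (multimapping) reads are resolved greedily: among the phages
still holding unresolved reads, the one with the highest tally absorbs
all of its unresolved reads; those reads leave every other phage's pool;
repeat until the pool is empty.

Two points are deliberately pinned down because the verbal description of
such procedures leaves them open:

* **Tie-breaking.** Equal tallies are broken by the higher total
  mapping-read count, then by lexicographic phage ID. This makes the
  output deterministic and invariant to row order, which we verify by
  property tests.
* **Static vs dynamic tallies.** The default ranks phages by tallies
  computed once, before iteration. A `dynamicTally` switch recomputes
  tallies each round over the reads still in play. With unique-read
  tallies the two are provably identical — a phage that wins a round
  absorbs *every* contested read it holds and therefore never competes
  again — so the switch only changes behaviour together with
  `tally = "total"`, which ranks by total mapping reads instead. Both
  variants are exposed; the default follows the unique-read wording.

Resolution is per database: each database is searched separately
upstream, so a read may legitimately hold one assignment per database.

## Calling rule

For each (sample, database, phage) the package computes:

* `nUniqueReads` — reads after collapsing duplicate sequencing IDs and
  duplicate alignment start sites. The start site is the 5′-most subject
  coordinate, `min(start, end)`, so a reverse-strand duplicate collapses
  with a forward read at the same locus. Duplicate IDs are collapsed
  first (keeping the best e-value, ties to the longer alignment), then
  duplicate starts; the order is configurable in principle but this is
  the documented default.
* `coverageBp` — breadth of coverage: the size of the union of all
  assigned alignment intervals, equivalent to marking positions off a
  `1..L` genome vector. Production code uses sorted interval merging
  (`IRanges::reduce`); the naive boolean-vector method is retained as the
  independent test oracle.

A phage is **called** in a sample when `nUniqueReads >= 10` and
`coverageBp >= 500` (both inclusive, "at least"). A phage called in
strictly more than 75% of the cohort's non-excluded samples is flagged
**prevalent** — commonly circulating sequence or processing contamination
— and every downstream statistic can be run with or without the
prevalent set. Phages from different databases are never merged, even
when their call patterns, counts and coverage are identical across all
samples; such pairs are only *reported* as likely inter-database
duplicates.

## The dyad null model and exact test

The sharing question is asked through phages present in **exactly two
samples**. Each such phage defines an unordered pair of samples; under
the null hypothesis of no maternal-infant structure this pair is uniform
over all `choose(N, 2)` pairs, of which `D` are dyads. With `n`
two-sample phages the expected number of dyad pairs is

$$E = n \cdot \frac{D}{\binom{N}{2}},$$

and the primary significance computation is the one-sided exact binomial
tail `P(X >= observed)` with `X ~ Binomial(n, D / choose(N, 2))`. Each
phage contributes one trial even when two phages land on the same pair
of samples. Only the "more dyads than expected" direction is offered,
because that is the scientific question.

The choice of the uniform-over-all-pairs null (rather than restricting
to maternal×fetal pairs) is forced by the reported expectations: with
`n = 10, N = 20, D = 10` it gives `E = 0.526 ≈ 0.5`, and with
`n = 28, N = 124, D = 62` it gives `E = 0.228 ≈ 0.2`; the restricted
null reproduces neither. A Fisher-exact variant on the 2×2 table (pairs
defined by two-sample phages vs all other unordered pairs) × (dyad vs
non-dyad) is provided behind `method = "fisher"`; on the large-cohort
configuration (11 observed dyads of 28) both variants give p-values far
below 0.001. On the small configuration (3 observed of 10) the binomial
tail computed here is 0.0132 and the Fisher variant 0.0105; any claim
of non-significance for that configuration must therefore rest on a
different, unstated test construction, which we do not attempt to
reverse-engineer.

Descriptive statistics around the test — per-dyad overlap
decompositions, per-phage sample-count histograms with the singleton
tally, condition stratification (phages in more than 7 samples split
over term/preterm and chorioamnionitis classes) and cross-cohort set
overlap — are pure set algebra over the called sets and carry no
significance machinery, deliberately: presence counts at this scale do
not support abundance or diversity comparisons.

## Host habitat annotation

Database metadata (predicted host genus, morphology) is joined onto
called phages and classified with editable genus lists:
vagina-associated (Streptococcus, Megasphaera, Prevotella,
Bifidobacterium, Roseburia, Faecalibacterium, Clostridium, Ruminococcus,
Lactobacillus), gut-associated (Escherichia, Enterobacter,
Campylobacter, Listeria, Klebsiella), and no-known-human-habitat
(Acidithiobacillus, Dickeya). A genus on both the vagina and gut lists
is reported as vagina-associated with a dual-habitat flag. Phages
without any host prediction inherit the habitat of their source database
when it was mined from human gut samples (GPD, GVD, ELGV, MGV);
otherwise they are `unknown`. The same fallback applies to a known genus
absent from every list, which keeps the class total exhaustive while the
lists remain short; the lists are configuration, not code, precisely so
a user can re-draw these boundaries.

## What the simulator emulates — and what it does not

`simulateCohort()` generates the complete input side of the pipeline:
database record tables (with partial metadata), a dyad-structured sample
sheet with tri-state condition flags, and hit tables with the exact
column dialect of the readers. It emulates:

* 75-bp single-end reads from 50–200 bp cfDNA fragments (alignment
  length = min(read length, fragment length));
* dyad sharing: each dyad receives `phagesPerDyad` phages (default 6,
  drawn from a pool shared across dyads so phages recur), each planted
  in both members with probability `sharedFraction`, else in one;
* ubiquitous contaminants planted in every sample;
* below-threshold noise phages — alternately 9 spread reads (fails the
  read minimum) and 12 reads packed into a 450-bp window (fails the
  coverage minimum);
* controlled multimapping: a fraction of each phage's reads also hit a
  per-database "trap" phage that has no unique reads of its own, so a
  correct greedy resolution must leave every trap uncalled; and
* filter-failing junk hits with e-values at or above the threshold.

Planted read starts are evenly spaced (one read length apart), so the
planted breadth is achieved exactly and recorded in a truth manifest
along with planted unique-read counts and expected call flags; a
`jitterStarts` option perturbs the spacing to stress the interval-union
code. One master seed derives a named sub-seed per component (genomes,
membership, positions, e-values, decoys, FASTA content), so outputs are
byte-identical across runs.

The simulator does **not** emulate: sequencing error or quality scores,
human background reads and their depletion, alignment score physics
(e-values and bit scores are drawn from simple parametric ranges, not
from an alignment model), database redundancy beyond the trap construct,
or real phage genome composition. Passing the end-to-end recovery tests
therefore demonstrates that the pipeline computes its defined statistics
correctly on data of the declared shape — not that the thresholds are
well-calibrated for any particular sequencing protocol.

Default generator dimensions were fixed once at study-like values:
10 dyads (20 samples), 5 databases of 20 phages with 2–20 kb genomes,
10–25 reads per planted phage. The unit suite runs cohorts of 2–10
dyads; the acceptance script uses the 20-sample and 124-sample
configurations that the sharing analysis is defined on.

## Numerical and degenerate-input choices

* All threshold comparisons are exact integer/float comparisons matching
  the rule wording: e-value strictly below; unique reads and coverage
  inclusive ("at least"); prevalence strictly above 75% (15 of 20
  samples is *not* prevalent, 16 is).
* `expectedDyadPairs` is evaluated in closed form — no simulation — and
  is checked against a Monte-Carlo null in the tests.
* An empty hit table propagates to empty, well-formed outputs at every
  stage; the enrichment test with `n = 0` reports an NA p-value rather
  than inventing one.
* Reverse-strand subject coordinates are normalised on read
  (`start <= end` plus a strand flag) and restored on write, so
  read/write round trips are field-identical.
* Excluded samples are dropped before any statistic; incomplete dyads
  are skipped with a warning rather than an error.

## Known limitations

* The pipeline starts at hit tables: alignment itself (and its culling
  behaviour, which caps hits per read per database at 20 upstream) is
  out of scope; the `cullingLimit` configuration field documents the
  expectation but nothing enforces it.
* No identity filter is applied beyond the e-value rule; if the upstream
  search was run permissively, identity filtering must happen before the
  tables are read.
* Presence/absence only: no depth profiles, consensus sequences or
  strain-level analysis.
* The habitat classification is a lookup, not an inference; its genus
  lists are small and deliberately user-editable.
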