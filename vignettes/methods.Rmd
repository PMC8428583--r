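---
title: "Designing experiment-specific rRNA depletion oligos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing experiment-specific rRNA depletion oligos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodeplete)
```

## The problem

Ribosome profiling (Ribo-seq) sequences the ~19–32 nt mRNA fragments
protected by translating ribosomes. During nuclease footprinting, ribosomal
RNA is fragmented too, and those fragments co-purify with the
ribosome-protected fragments (RPFs); in unfavourable libraries they can
account for the large majority of reads. Which rRNA positions dominate is
protocol- and tissue-specific, so fixed commercial depletion panels remove
the wrong fragments for many experiments. The remedy implemented here is to
*learn* the contaminating positions from a small pilot library and design
biotinylated antisense oligos against exactly those positions, so the
fragments can be captured on streptavidin beads before reverse
transcription.

## The depleting-potential model

The central statistic is the per-oligo, per-sample **depleting potential**.
For an oligo of length $l$ tiled from the rRNA reference set:

1. **Depletion regions.** Every reference interval complementary to the
   oligo for a contiguous stretch of at least
   $s = \max(\lfloor 2l/3 \rfloor, 10)$ nucleotides is a depletion region.
   The oligo's own source interval always qualifies; so do near-identical
   regions on other rRNA copies, which is how multi-copy reference sets are
   handled.
2. **Depletable fragments.** A primary-aligned read is depletable by a
   region when it covers at least $\max(10, \lfloor 2l/3 \rfloor)$ nt inside
   the region and leaves at most $\min(10, \lfloor l/3 \rfloor)$ nt outside
   it. The coverage bound ensures a stable oligo–fragment duplex; the
   overhang bound limits unhybridized tails that would weaken capture.
3. **Potential.** The potential of the oligo in a sample is the fraction of
   that sample's primary alignments depletable in at least one of its
   regions, each read counted once (set semantics, so potentials never
   exceed 1 even with overlapping regions or multiple rRNA copies).

The sample total is the number of *primary* alignments: the depletable
numerator is defined on primary placements, so using the same set in the
denominator keeps the ratio interpretable as a fraction of fragments. Both
floors are applied with $\lfloor\cdot\rfloor$; the seed formula is stated
with an explicit floor and we extend the same convention to the overhang
bound.

Oligos with potential below 0.05 in strictly more than 75% of the pilot
samples are discarded before feature computation (both thresholds are
user-adjustable, and the inequalities are strict exactly as stated: a
potential of exactly 0.05 is not "below", and a below-threshold fraction of
exactly 0.75 does not discard). The **overall depletion score** is the
fraction of samples with potential strictly greater than the threshold.

## Thermodynamics

Duplex stability is scored with published nearest-neighbor RNA/RNA
parameters at 37 °C: Watson–Crick stack free energies from Xia et
al. (1998), G·U wobble stacks from Mathews et al. (1999) as revised in the
Turner 2004 set, duplex initiation $+4.09$ kcal/mol and a $+0.45$ kcal/mol
penalty per helix end closed by an AU or GU pair. The table ships inside
the package (`energy_model()`), so no external thermodynamics engine is
needed and results are reproducible from source alone. Absolute energies
from other engines will differ by their loop models; every energy-derived
threshold in the pipeline (the minimum binding energy $E_{\min}$ and the
off-target cutoff derived from it) is computed self-consistently from this
model, which preserves the pipeline's logic regardless of the absolute
scale.

`min_hybridization_energy()` is the energy of the oligo bound in full
perfect duplex with its target — the most stable binding achievable.
Self-folding (`self_fold()`) uses a nested-structure dynamic program over
the same stack table with a minimum hairpin loop of three unpaired bases;
the open chain is always feasible, so the reported MFE is never positive,
and ties are broken toward fewer pairs so zero-energy lone pairs are never
reported. An installed RNAfold binary can be substituted behind the same
contract (`engine = "rnafold"`) when full Turner loop energies are wanted.

**Wobble handling.** G·U pairs are accepted as complementary during
cross-species target search and off-target scanning (RNA–RNA duplexes do
form wobbles), but *not* when identifying depletion regions, where the
definition is a perfectly complementary stretch; the strict reading is the
default and a flag (`region_wobble`, `wobble`) switches either behaviour.

## Search semantics

The duplex search reports every *maximal* contiguous complementary run of
length ≥ s between oligo and reference in antisense orientation, scored
over the run — there is no extension beyond the perfectly paired stretch
(the "no suboptimal extension" convention). Equivalence of these intervals
with seed-and-extend engines that do extend is therefore not guaranteed;
within this package the run *is* the region. Ties for the lowest-energy hit
(cross-species mode) break by longest stretch, then lowest reference index
and start.

Without wobble a run is an exact substring match between the
reverse-complemented oligo and the reference, so the implementation prunes
search diagonals with exact block seeding (pigeonhole over
$\lfloor s/2 \rfloor$-mers); the tests assert byte-exact agreement with the
unpruned scan and with a brute-force oracle.

## Alignment of pilot reads

When alignments are not supplied as SAM, reads are placed with a
substitution-only end-to-end scan: at most 2 mismatches by default (the
conventional `-n 2` setting), no indels and no splicing — rRNA fragments
are contiguous reference substrings, and the restriction keeps the aligner
exactly checkable against an exhaustive-offset oracle, which the test suite
does. All equally-best placements are reported; one is flagged primary by
the deterministic rule (fewest mismatches, then lowest reference index,
then lowest coordinate). Reverse-complement placement is off by default
because Ribo-seq libraries are stranded; a flag enables it. Pigeonhole
seeding (default seed length 25) is an optimization only and provably
cannot change results.

## Cross-species optimization

For each source oligo the lowest-energy hit on the new organism's rRNAs is
its intended target; the optimized oligo is the perfect reverse complement
of that interval, extended by one base per unpaired source nucleotide at
each end. Antisense geometry maps the oligo's 5′ dangling end to the
high-coordinate side of the target interval and the 3′ end to the
low-coordinate side; extensions are clamped at reference bounds and the
*actual* added bases are recorded. A source oligo whose best stretch is
shorter than 10 nt is reported unoptimizable rather than silently dropped.
Optimization is idempotent: re-optimizing an optimized set returns every
oligo unchanged, which the acceptance tests verify.

## Off-target screening

With $E_{\min}$ the most negative perfect-duplex energy over all designed
oligos and $l_{\min}$ the shortest oligo length, transcripts are scanned
with seed $l'_{\min} = \lfloor 0.75\, l_{\min} \rfloor$ and energy cutoff
$E'_{\min} = \min(-25, 0.5\,E_{\min})$ kcal/mol. Only the sense strand is
scanned by default (only sense fragments become RPFs); each maximal run is
counted as one off-target, and the per-hit detail (transcript, interval,
energy, stretch) is written to a separate TSV while the count joins the
feature table.

## The synthetic pilot generator

`generate_fixture()` emulates the one structural feature of real pilot data
the method depends on: a handful of narrow rRNA intervals ("hotspots")
producing a disproportionate share of fragments, reproducibly across
replicates. References are uniform-random RNA (a GC-bias knob exists for
energy-model tests); reads draw an origin component by weight, a start
uniform inside the hotspot and a length uniform in 19–32 nt (the usual
size-selection window), with optional substitution errors; a truth table
records every origin. It deliberately does *not* model ligation or PCR
bias, structure-driven cleavage preference, or sequence similarity between
hotspots and the rest of the rRNA — so passing tests demonstrate that the
statistics and bookkeeping are correct, not that real libraries will show
hotspots this clean. Defaults for the end-to-end checks: two references
(400 and 150 nt), one hotspot of 40 nt at weight 0.9, three replicates of
400 reads — small enough that twenty seeded replicate runs complete in
about a minute, large enough that binomial noise on the top oligo's
potential is ~1%.

## Numerical and degenerate-case choices

- Coordinates are 0-based half-open everywhere internally; conversion
  happens only at format boundaries (BED stays 0-based half-open, GFF3 and
  the CSV report 1-based inclusive). Oligo ids are the deterministic
  `ref|start-end|length` scheme (1-based inclusive), so runs diff cleanly.
- Oligos are always antisense; the strand column in BED/GFF3 is fixed `-`.
- Ambiguity codes (N) in references are rejected with the offending record
  named, never skipped: silently dropping a record would change oligo
  enumeration counts.
- A single-pair "duplex" scores initiation only (no stacked helix, no end
  penalty); an empty pilot sample is an error rather than a potential of 0.
- A read depletable in regions on *different* rRNA copies still counts once
  per sample. Whether one should count per copy is genuinely ambiguous; set
  semantics keeps potentials in [0, 1].
- "Highly similar" in the selector is interval Jaccard ≥ 0.5 on the same
  reference (configurable). The greedy auto-selector breaks score ties by
  most negative hybridization energy, then position, so selections are
  deterministic.

## A worked micro-example

```{r example}
spec <- fixture_spec(c(400, 150),
                     hotspots = data.frame(reference = 1, start = 150,
                                           end = 190, weight = 0.9),
                     reads_per_sample = 400, n_samples = 3, seed = 1)
fx <- generate_fixture(spec)
samples <- lapply(fx$samples, align_reads, references = fx$references)
fit <- design_oligos(fx$references, samples, design_config(25, 25))
summary(fit)
greedy_autoselect(fit$features, k = 3)
```

## Known limitations

- The energy model has no dangling-end, coaxial-stacking or
  temperature-dependence corrections; 37 °C only.
- The aligner is substitution-only; reads spanning true indels (rare in
  rRNA fragments) are dropped.
- Pseudoknots are outside the self-folding structure space.
- The pipeline quantifies depleting *potential*, not realized depletion;
  bead chemistry, secondary structure of the fragment and oligo dosage are
  not modelled. It reports all high-potential oligos rather than one
  optimal set — selection remains a user decision, aided by
  `filter_table()`/`greedy_autoselect()`.
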