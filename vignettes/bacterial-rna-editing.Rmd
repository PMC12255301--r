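---
title: "Discovering TadA-mediated A-to-I mRNA editing from bacterial RNA-seq"
author: "bacedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering TadA-mediated A-to-I mRNA editing from bacterial RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacedit)
library(data.table)
```

## The biological problem

Adenosine deaminated to inosine in an mRNA is read as guanosine by both the
ribosome and the reverse transcriptase, so A-to-I editing surfaces in RNA-seq
as A>G mismatches between reads and the genomic reference. In bacteria the
editing enzyme is TadA, the tRNA-Arg2 anticodon deaminase, which also edits
mRNAs that present its sequence and structure preferences: a seven-base
`YTACGAA` consensus (Y = C or T, edited A third) displayed in the loop of a
stem-loop whose geometry matches the 17-nt tRNA-Arg2 anticodon arm.

The catch is that A>G mismatches also arise from strain-to-reference DNA
differences, sequencing error, misalignment, and PCR artifacts. `bacedit`
implements a discovery cascade that separates low-frequency, replicated,
strand-consistent editing signals from those confounders, and the downstream
characterization: motif enrichment against a genome-sampled null, codon
recoding annotation, secondary-structure profiling, differential editing
between strains, and conservation classification across species.

## The discovery model

Editing at a site is modeled as a per-read Bernoulli event: a read covering
an edited adenosine carries G with probability equal to the site's editing
level. The observed level is therefore a binomial proportion,
`level = 100 * k / n` with `k` edited reads out of `n` qualified reads, and
everything downstream (confidence intervals, replicate consistency,
differential tests) follows from that sampling model.

The cascade runs, per sample:

1. **Trimming** -- modified-Mott segments under an error-probability limit of
   0.05, at most 2 ambiguous bases, minimum retained length 50.
2. **Mapping** -- ungapped k-mer-seeded placement requiring 95% of the read
   aligned at 95% identity; reads with two or more equal-best placements are
   discarded outright, so repeats cannot manufacture mismatches. Externally
   aligned SAM is accepted as-is through the same interface.
   Samples with under 50% of reads mapped are excluded.
3. **Pileup** -- a base counts only if its own quality is >= Q30 and every
   base within 2 positions on the read is >= Q30 (truncated at read ends);
   coverage counts qualified bases only.
4. **Initial calling** -- coverage 20--1e6, at least 3 supporting reads,
   frequency >= 1%.

and then across samples:

5. **Post-call filters** -- >= 3 unique supporting start and end
   coordinates (PCR/positional artifacts), frequency within [5%, 98%]
   (the 98% ceiling removes strain-specific mutations riding at ~100%),
   at most two alleles at the position.
6. **Replicate intersection** -- present in 100% of biological replicates of
   an experiment (or at least k of n, e.g. 3 of 4 for the single-strain
   profile), unioned across experiments.
7. **Orientation** -- only sites inside annotated genes are kept, expressed
   on the coding strand so a forward T>C in a minus-strand gene is a coding
   A>G; every other substitution type is discarded. For stranded libraries,
   only reads on the transcribed strand support a variant and antisense
   reads never count toward the level.
8. **DNA-variant subtraction** -- sites matching a DNA-seq variant list are
   removed.
9. **Level rescue** -- for each final site, every sample's coverage and
   G-fraction is re-read straight from the pileup with no thresholds, so
   sub-1% levels in non-called samples are reported as observed rather than
   silently zeroed; uncovered samples are missing, not zero.

A site's single summary level is the unweighted mean over non-missing
samples; the per-sample table is always retained alongside, so a weighted
choice remains available to the user.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| trimming error-probability limit | 0.05 | probability | standard realization of quality-limit trimming |
| min read length after trim | 50 | nt | shorter reads map ambiguously |
| length / similarity fraction | 0.95 / 0.95 | fraction | discards partial and divergent placements |
| neighborhood radius / qualities | 2 / Q30, Q30 | nt, Phred | mismatches flanked by shaky calls are artifacts |
| min coverage / count / frequency | 20 / 3 / 1% | reads, % | floor below which a binomial signal is indistinguishable from error |
| frequency band after calling | 5--98% (or 1--98%) | % | lower bound suppresses noise, upper bound removes strain mutations |
| unique starts / ends | >= 3 each | count | independent fragments, not one amplified molecule |
| max alleles | 2 | count | hyper-allelic positions are systematic artifacts |
| folding window | 17 | nt | length of the tRNA-Arg2 anticodon arm |

All threshold comparisons are inclusive (`>=` / `<=`), matching the
"at least" semantics used throughout; the 50%-mapped bound is likewise
treated as inclusive, a convention recorded here because nothing forces
either reading.

## Characterization statistics

**Motif enrichment.** Each oriented site contributes one 4-mer
(offsets -1, A, +1, +2 on the coding strand). The null is the frequency of
each `XAYZ` 4-mer over *both strands* of each species' genome (genes lie on
either strand), combined across species weighted by per-species site counts
so expected and observed totals match. The test is a plain chi-square
goodness of fit, `sum((O - E)^2 / E)` on 64 categories, df = 63. Categories
with expected < 1 are pooled into a rest class with df reduced accordingly;
whole-genome nulls never trigger this, but tiny toy inputs can.

**7-mer classes and logo matrix.** Hamming distance to `YTACGAA` with Y
degenerate, binned 0 / 1 / >=2; the 21-base contexts also yield a
position frequency matrix with per-position information content
`IC = 2 - H - 3/(2 ln 2 n)` (small-sample corrected), the quantities a logo
renderer consumes.

**Codon recoding.** Codon and in-codon position are computed on the coding
strand from the gene's frame, the A>G substitution applied, and the effect
classified under the standard genetic code (mid-gene, so start-codon special
cases never arise). The expected codon-position and effect distributions
condition on the `TACG` context -- editing requires the motif, so sampling
all adenosines would answer a different question; conditioning on the motif
is one of several defensible nulls and the choice is flagged here. Note
`TTA`/`CTA` encode leucine under the standard code; synonymous
third-position events in those codons are classified strictly by the code.

**Structure.** 17-nt windows slide in 1-nt steps; at offset 0 the edited A
is the 8th base (`NNNNNYT[A]CGAANNNNN`). MFE comes from ViennaRNA's RNAfold
(nearest-neighbor model, 37 C) through a pluggable adapter; a built-in
Nussinov base-pair-maximization scorer (-1 per nested pair, minimum loop 3)
is available for engine-free testing and is explicitly non-thermodynamic.
All structure conclusions rest on *relative* comparisons (sites versus
controls, window versus shuffles), so the engine choice cannot flip them.
Controls are all other `YTACGAA` occurrences on either genome strand,
anchored at the would-be edited A, with real sites excluded -- the
full-length consensus is the only self-consistent 7-base control pattern.
Offsets default to -30..+30, wide enough to show the dip and cheap to
compute.

**Comparative statistics.** Per-site differential editing uses the classic
pooled-variance Student t on per-replicate levels with Benjamini--Hochberg
correction across sites; site-set comparisons (e.g. overexpression versus
control sites) use Welch's unequal-variance t on per-site means, the pooled test suits
replicate-level comparisons of a single site while the unequal-variance
test suits heterogeneous site sets. Relative change is
`(mean_b - mean_a) / mean_a`, a signed fraction of the baseline mean; an
absolute-difference variant is a one-line change and the per-sample table
needed for it is always retained. Conservation classes partition events by an externally
supplied protein key: `conserved` (>= 2 species recode the same position
with the same substitution), `partially_conserved` (shared protein only),
`unique` -- homology search itself is out of scope and consumed as a table.

## What the synthetic data emulates -- and what it does not

`sim_config()` describes the study conditions: a 50-kb genome at 40% GC
(Acinetobacter-like), 40 non-overlapping CDS of 300--900 nt on both strands
plus two tRNA genes, 30 editing sites rewritten into `YTACGAA` inside
5-bp-stem hairpins, per-site levels Uniform(10%, 60%), stranded 100-nt
single-end reads at 50x mean gene-body coverage with 1e-3 substitution
error at Q37, three replicates, and five strain SNPs planted as coding A>G
at 100% frequency specifically to exercise the 98% ceiling. Each read
overlapping a site is edited independently (binomial levels); errors are
applied after editing; replicates differ only by derived RNG streams from
one master seed.

Sites are planted at least one read length from gene termini: reads are
drawn entirely within gene bodies, so only there does the configured mean
coverage actually hold at the site. Hairpins are built by writing the
reverse complement of the window's 5' flank into its 3' flank, leaving the
7-mer in the loop -- the anticodon-arm geometry.

Deliberately not modeled: indels (the built-in mapper is ungapped; gapped
alignments enter via SAM), PCR duplicates, quality miscalibration,
paired-end inserts, expression heterogeneity (a per-gene multiplier hook
exists, but the statistics under test do not depend on it), and
transcription boundaries beyond annotated genes. Passing tests therefore
demonstrate correctness of the cascade's logic and calibration of its
statistics under the stated sampling model -- not robustness to alignment
artifacts around indels, biased error profiles, or coverage heterogeneity
in real libraries.

## Numerical choices and degenerate inputs

* Neighborhood quality at read ends: the window truncates rather than
  discarding edge bases outright.
* Alleles for the hyper-allelic filter are counted at the calling support
  threshold (>= min count reads); counting raw single-read alleles would
  declare nearly every deep position hyper-allelic.
* Equal-best mapper placements are detected as exact score ties only.
* Constant groups in t-tests: p = 1 when both groups are identical
  constants (no evidence), 0-variance-different-means yields p = 0.
* Zero-coverage samples at a site are missing, never zero.
* Sites within 10 bases of a contig end have no full 21-nt context and are
  excluded with a warning; windows running off a contig are skipped
  per offset.
* Ambiguous sites inside overlapping genes on both strands are dropped with
  a warning; counting them on either gene would double-assign strands.
* The chi-square pooling rule (expected < 1 into a rest class) keeps the
  statistic finite on toy inputs without affecting genome-scale nulls.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full cascade on the
default 50-kb / 30-site / 3-replicate configuration (about half a minute),
20 independent 30-kb genomes of 50 hairpin sites each for structure
discrimination, 200-seed calibration loops for the motif null and the
global-null FDR, and 100-seed power runs for differential editing. These
sizes were chosen so each statistic has enough replication to be a
meaningful check while the whole suite stays desk-scale; a full
cross-species survey over hundreds of RNA-seq experiments is orders of
magnitude larger and is not recomputable from scratch at a desk.

## Known limitations

* The built-in mapper is deliberately minimal (ungapped, exact-tie
  detection); real data should arrive as externally aligned SAM.
* The conservation classifier trusts the supplied protein keys; paralogy or
  inconsistent naming will misgroup events.
* The codon-effect null conditions on `TACG`; if the true targeting motif
  is longer, the expected distributions shift.
* Editing independence across reads is an assumption; clustered editing in
  single molecules would narrow the observed binomial spread.
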