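---
title: "Cross-mutant SNV analysis for EMS candidate-gene identification"
author: "emsHunter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-mutant SNV analysis for EMS candidate-gene identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsHunter)
```

## The problem and the model

Forward-genetics screens with the chemical mutagen EMS (ethyl
methanesulfonate) produce allelic series: several independently derived
mutant lines whose phenotype traces to lesions in the same gene.  When the
chromosome carrying the gene can be purified (for example by flow sorting)
and sequenced in the wild type and in each mutant, the causal gene can be
found without any fine mapping, by exploiting two properties of EMS:

1. **Spectrum.** The vast majority of EMS-induced point mutations are
   G/C-to-A/T transitions ("canonical" changes: G>A or, on the other
   strand, C>T).
2. **Independence.** EMS lesions are approximately uniformly and
   independently distributed over G/C sites, at densities on the order of
   one mutation per several hundred kilobases of (mappable) sequence.

Because each mutant was mutagenised independently, the only assembly contig
expected to carry an induced mutation in *every* line is the one containing
the target gene.  The analysis is therefore: call near-fixed SNVs per
mutant line against the repeat-masked wild-type assembly, discard artifact
positions, count for each contig the number of lines mutated on it, and
rank.  A handful of contigs will be hit in two or three lines by chance;
essentially none in five or six.

## Per-line SNV calling

The caller consumes samtools mpileup text (the mapping itself — BWA,
pair/duplicate filtering, `mpileup -BQ0` — is upstream of this package) and
applies three per-column predicates, all configurable via `FilterConfig()`:

* **Masking.** Only columns whose assembly base is upper-case A/C/G/T are
  considered.  Repeat-derived (soft-masked) and N positions are skipped
  both for calling and for the callable-base denominators, because
  repetitive sequence attracts mismapped reads.
* **Coverage** of at least `minCoverage` (default 15) reads.
* **Near-fixation.** The single most frequent non-reference base must reach
  `minAlleleFrequency` (default 99.99 %) of the substitution-supporting
  reads (A+C+G+T counts; deletions and reference-skip symbols are excluded
  from the denominator, since the filter targets substitutions and `*`
  columns reflect alignment artifacts).  At the default threshold and any
  realistic depth this means *zero* dissenting reads: the mutations sought
  are homozygous and the chromosome preparation is essentially clonal, so
  any mixed column is evidence of mismapping, not of a lesion.  Ties among
  non-reference bases never call.

Two denominators are tracked per line: `callableBases` (unmasked,
depth-passing positions) and its G/C subset.  Densities are reported
against callable bases rather than total assembly length so that they are
robust to coverage differences between lines.

## Cross-line integration

Positions called in more than `maxMutantsSharingPosition` (default 2)
distinct lines are removed from *all* lines before ranking.  Independent
EMS hits essentially never coincide at a base, so shared positions indicate
pre-existing variation between the mutagenised parent and the reference
cultivar, or systematic mapping error.  The published description of this
rule is one ambiguous sentence (three discard conditions joined in a single
clause); this package reads it as an OR of three independent filters, with
the sharing rule acting at position level and a separate contig-level
reporting threshold `minMutantsPerContig` (default 3) controlling which
contigs are reported as candidates.  Both are exposed as parameters, so
either reading of the sentence can be configured.

Integration produces one report per contig (zero-SNV contigs included, so
the histogram of "contigs mutated in k lines" is complete and its counts
always sum to the number of assembly contigs) ranked by number of mutated
lines, then total SNVs, then contig id — a total order, so reruns are
byte-identical.

## Quality control

* **Cultivar contaminants.** A line that is not actually derived from the
  mutagenised parent shows orders of magnitude more SNVs (observed:
  1 per ~1.6 kb against 1 per 380–741 kb for genuine lines) of mixed
  spectrum.  `flagContaminants()` flags a line whose callable-bases-per-SNV
  falls 20-fold below the cohort median.  The published contrast is ~240×,
  so the default threshold sits far from both sides; it is a configurable
  engineering choice, as the original analysis made this call by
  inspection.  Flagged lines are excluded and ranking is recomputed
  without them.
* **Assembly artifacts.** Mapping wild-type reads back to their own
  assembly exposes chimeric or misassembled contigs as clusters of fixed
  disagreements.  `wildtypeSelfCheck()` flags contigs exceeding 0.5 fixed
  disagreements per unmasked kb (again a stated engineering choice: a
  correctly assembled contig produces essentially none at the 99.99 %
  frequency filter, a diverged haplotype produces hundreds).  Flagged
  contigs are never reported as candidates, whatever their mutant count.

## The false-positive model

Under the canonical spectrum and independence assumptions, a line's
per-G/C-site mutation rate is estimated as
\(\hat\mu = n_{canonical} / callableGcBases\), and the probability that a
contig with \(n_{GC}\) unmasked G/C sites carries at least one background
mutation in one line is

\[ p \;=\; 1 - (1 - \mu)^{n_{GC}}, \]

which for \(\mu\,n_{GC} \ll 1\) is \(\approx \mu\,n_{GC}\).  The complement
form is kept because it is exact under the stated independence and costs
nothing.  Across \(m\) independently mutagenised lines the joint
false-positive probability is the product of the per-line values — for a
10-kb contig at the highest observed per-line probability of 0.11,
\(0.11^{12}\) corresponds to odds of 1 in 3 × 10¹¹, which is why overlap
across five or six lines is already decisive.  `formatOneIn()` renders such
probabilities at one significant figure with conventional half-up rounding.
(The analogous published barley figure, 1 in 4 × 10¹⁴ from \(0.05^{11}\),
is arithmetically inconsistent — \(0.05^{11}\) gives 1 in 2 × 10¹⁴ — and
presumably used unpublished per-line rates; this package reports the
arithmetic consequence of its inputs.)

\(\hat\mu\) is estimated from all canonical calls genome-wide, including
the causal contig: one call among hundreds biases the rate negligibly and
there is no principled reason to exclude it.

## The synthetic-experiment generator

`simulateExperiment()` emulates the whole data-generating process at the
level the pipeline consumes — pileup columns, not reads; read simulation
and mapping are out of scope by design.  Its defaults state one realistic
experiment, and were chosen once, from the observed regimes, not tuned to
tests:

| parameter | default | rationale |
|---|---|---|
| contigs | 600, log-normal (median 6 kb, σ = 0.8), floor 500 bp | short-read draft assembly shape; ~5 Mb total |
| GC content | 0.44 | Triticeae genomic GC |
| masked fraction | 0.10 in contiguous blocks | repeat-masked draft, after masking |
| causal contig | 10 kb | the published candidate contigs were 10–12 kb |
| mutants | 6 | the published cohort size |
| background density | 1/500,000 per bp | inside the observed 1/380–1/741 kb range |
| contaminant density | 1/1,580 per bp (optional line) | the observed contaminant density |
| coverage | Poisson, λ = 30 | observed 27–35× |
| error rate | 0 | filters are count-exact; error is opt-in |

Mechanics worth knowing:

* EMS mutagenesis hits each unmasked G/C site independently with
  probability `density / g` (`g` = unmasked G/C fraction), so the expected
  genome-wide count is `density × unmasked bases`.  This is implemented as
  one binomial draw of the count plus uniform placement without
  replacement — exactly equivalent to per-site Bernoulli trials, and fast
  at tens of millions of sites.  Contaminant variation hits every unmasked
  site at its density with a uniform choice among the three alternates.
* Each mutant receives exactly one causal lesion at a distinct G/C site of
  the causal contig; the contaminant line receives none.
* Determinism: all randomness derives from one master seed, with per-line
  streams at fixed offsets, so any single line is reproducible in
  isolation and rerunning a configuration reproduces every output file
  byte for byte.
* The chimeric-artifact scenario appends a 10-kb contig whose second half
  diverges 1 % from the genome the reads derive from.  Divergent columns
  are emitted as a 97/3 alternate/reference read mixture rather than as
  fixed differences: at 30× a column then passes the zero-dissent filter
  with probability ≈ 0.4 *independently per line*, which is what lets a
  real chimera rank as a candidate (different lines call different subsets
  of its positions, evading the shared-position filter) while the
  wild-type self-check still sees it glowing.  Fully fixed divergence
  would be silently removed by the shared-position filter and the
  scenario would test nothing.

What a green test on synthetic data does **not** establish: robustness to
mapping bias, amplification (MDA) bias, paralog collapse in the assembly,
residual wrong-chromosome reads after flow sorting, or base-quality
pathologies — none of which are modelled.  The simulator validates the
*analysis logic* under the method's own stated assumptions.

## Numerical and degenerate-input choices

* Allele-frequency comparison uses `count ≥ minAF × denominator − 10⁻⁹`
  so exact boundary fractions (9999/10000 at the default) are never lost
  to floating point.
* Zero SNVs give an *absent* (`NA`) density, never an infinite one, and
  such lines are excluded from the cohort median and never flagged.
* Cohort QC requires at least three lines; with fewer it warns and leaves
  flags unset rather than guessing.
* Zero-depth positions are omitted from written mpileup (as samtools
  does); absent positions are treated as zero depth.
* mpileup base-quality and mapping-quality strings are parsed but ignored:
  the upstream mapping disables BAQ, and every filter operates on counts.
* `p = 1 − (1−μ)^n` is computed via `expm1`/`log1p` to keep precision at
  small μ.

## Performance notes

The three per-position hot loops (mpileup read-base decoding, pileup
column synthesis, the SNV filter) are in C++; everything else is plain R.
A 5-Mb six-mutant experiment simulates and ranks in seconds; the 40-Mb
single-mutant density benchmark runs in about a minute.  The test suite
runs the seeded causal-recovery property over 30 replicate experiments of
the default world (the notional reference is 100 replicates; 30 keeps the
suite inside its time budget while leaving the ≥95 % recovery bar
unchanged).

## Limitations

* Indels, heterozygous variants and base-quality modelling are out of
  scope: the method targets homozygous point mutations in effectively
  clonal material.
* The shared-position and contaminant thresholds are engineering defaults
  standing in for decisions the original analysis made by manual
  inspection; they are exposed, not learned.
* The false-positive model assumes a single genome-wide μ; local GC or
  mutability context beyond the global G/C fraction is not modelled.
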