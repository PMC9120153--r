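---
title: "Measuring CRISPR spacer acquisition from amplicon sequencing: methods and design"
author: "spacerTracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CRISPR spacer acquisition from amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerTracer)
```

## The measurement problem

Type II-A CRISPR-Cas systems record immunity by inserting a short sequence
(a spacer, typically ~30 nt) between two copies of a direct repeat at the
leader-proximal end of a CRISPR array. In *Streptococcus thermophilus*,
adaptation against a resident plasmid can be followed without selection by
PCR-amplifying the leader end of the CR1 array from a passaged culture and
deep-sequencing the amplicons with overlapping 2 × 250 bp paired-end
reads. The quantity of interest is the fraction of reads whose array has
gained a new leader-proximal spacer, together with where those new spacers
came from (the plasmid, an anti-CRISPR gene carried on it, or the host
genome) and what protospacer-adjacent motif (PAM) flanks their source
sites — for CR1 the expected motif is `NNAGAAW`, read 3′ of the
protospacer.

spacerTracer implements that measurement as a chain of small, separately
testable stages:

1. **read merging** — assemble each overlapping pair into one amplicon
   sequence;
2. **array parsing** — anchor direct-repeat occurrences with a
   mismatch-tolerant scan and read off the inter-repeat spacers;
3. **acquisition calling** — compare the parsed spacer list against the
   ancestral array;
4. **target classification and PAM inference** — map each new spacer to
   the references, tabulate target categories, extract the 7-nt 3′ flank
   of perfect matches, and summarise the flanks as a position frequency
   matrix with an IUPAC consensus;
5. **assay statistics** — plasmid-loss fractions with Wilson intervals,
   phage titers under the 30–300 plaque rule, efficiency of plaquing
   (EOP) and log-reduction;
6. **ORF calling and truncated anti-CRISPR screening** — six-frame ORF
   detection with alternative start codons, local protein alignment, and
   the homolog filter (≥50 % identity on the aligned section, e-value
   < 0.001, ≥30 aa, ≤90 % of the representative's length).

Because the real sequencing data live in an archive rather than in this
package, correctness is demonstrated by *parameter recovery*: a fully
seeded synthetic-data module generates cohorts with known ground truth at
the rates reported for the real experiment, and the pipeline must read
those rates back out.

## The synthetic cohort generator

`sim_config()` fixes the generative model. Per read, with probability
`p_acq` the array carries exactly one newly acquired spacer at the
leader-proximal position; otherwise the ancestral array is reproduced
verbatim. New spacers are `spacer_len`-nt windows sampled uniformly from
PAM-adjacent sites of a reference chosen by `target_weights`; a site is
eligible when a `pam_pattern` match sits immediately 3′ of the window on
the sampled strand. Sequencing is modelled as independent per-base
substitutions at `error_rate` on both mates, with constant-high base
qualities that dip at error positions.

Default choices, and why:

| parameter | default | rationale |
|---|---|---|
| `p_acq` | 0.33 | the control-condition acquisition rate the validation targets |
| `pam_pattern` | `NNAGAAW` | the CR1 PAM; sampling is constrained to it so motif inference is testable |
| `spacer_len` | 30 nt | typical type II-A spacer length; configurable |
| `repeat_seq`, `leader_seq` | 36-nt / 36-nt fixture strings | placeholders with realistic lengths, not the biological CR1 sequences; supply real ones for real data |
| `n_ancestral_spacers` | 2 | the leader-proximal window a 2 × 250 bp pair can span with one insertion |
| `read_len` | 250 nt | MiSeq v2 paired-end geometry |
| `error_rate` | 0.001 | a realistic post-filter MiSeq substitution rate |
| `target_weights` | 0.8 / 0.1 / 0.1 | plasmid-dominated acquisition, as seen when a plasmid is the only selection-free target |

The generator plants concrete `NNAGAAW` instances on alternating strands
of the plasmid-like (circular, 3 kb), *acr*-gene (600 nt) and host-genome
(2 kb) references so that PAM-constrained sampling never starves; it
refuses to run when fewer than 50 pattern matches (both strands) exist on
the plasmid. Ground truth records, per read, whether acquisition
happened, the spacer sequence, and its source interval (0-based
half-open) and strand.

What the generator deliberately does **not** model: PCR bias and
chimeras, indel sequencing errors, quality-score miscalibration, multiple
acquisitions per array, and array contraction. Passing recovery tests
therefore shows the analysis is correct *for substitution-dominated
amplicon data with single polarized insertions* — they do not validate
indel robustness or abundance-bias correction on real libraries.

## Numerical and algorithmic choices

**Merging.** Candidate overlaps of at least `min_overlap = 20` nt are
scored by mismatch count; the fewest-mismatch overlap wins, ties going to
the longest. A pair is rejected (and counted, not silently dropped) when
the best overlap exceeds `max_mismatch_frac = 0.1`. Disagreements inside
the overlap resolve to the higher-quality base, ties to read 1. The
objective is plain mismatch counting rather than a probabilistic
posterior: it is fully checkable against a brute-force all-overlap
scorer, which the test suite does on small instances.

**Repeat anchoring.** Repeats are found by a substitution-only
(Hamming) sliding-window scan, forward orientation only — amplicons are
primer-oriented, so orientation is fixed by the merger's read-1 anchor.
Overlapping candidate windows resolve greedily left to right. Defaults:
`max_mismatch = 3` per 36-nt repeat occurrence, `novelty_max_mismatch =
2` for deciding that a spacer is not one of the ancestral spacers
(length-mismatched comparisons count as infinitely distant). With a
0.001 per-base error rate, the chance that a 36-nt repeat accrues more
than 3 substitutions, or that a 30-nt ancestral spacer drifts beyond 2,
is far below the 1 % per-read disagreement the recovery tests tolerate.
Reads with fewer than two repeat hits are excluded from the denominator
and reported.

**Mapping and PAM extraction.** Spacers are mapped by exhaustive Hamming
scan over both strands of every reference — at spacer-vs-kilobase scale
this is cheap, deterministic and parameter-free, so no heuristic
seed-and-extend aligner is needed. The default `max_mismatch = 0`
reflects the perfect-match convention used for target classification.
The plasmid is treated as circular (windows and PAM flanks may wrap the
origin); gene and genome segments are linear, and a flank running off a
linear end is reported as absent rather than padded. The PAM is the 7 nt
immediately 3′ of the protospacer *on the protospacer strand*; published
descriptions of this experiment put the extracted heptamer on opposite
sides in different places, and 3′-of-protospacer is the convention under
which `NNAGAAW` is defined. A spacer whose best hit ties across
reference categories is reported `ambiguous`, never assigned.

**Consensus calling.** Per position of the PAM matrix, the consensus is
the smallest IUPAC degeneracy class whose member frequencies sum to at
least 0.9 (ties to the larger mass), `N` otherwise. The 0.9 threshold is
a package choice: it keeps a uniform position from collapsing to a
3-letter class by sampling noise at the cohort sizes used here (a
three-base class at a uniform position carries mass 0.75, more than 8
standard errors below 0.9 at 500 sites).

**Alignment statistics.** Protein alignments are Smith–Waterman (local)
or Needleman–Wunsch (global) under BLOSUM62 with gap open 11 / extend 1,
computed by `Biostrings::pairwiseAlignment()`. Identity is counted over
aligned columns with gap columns excluded from the denominator. Raw
scores convert to bits via Karlin–Altschul parameters **calibrated by
simulation under this exact scoring scheme** (Gumbel tail regression on
3000 shuffled-pair alignments: λ = 0.181, K = 0.0117), and the e-value
is *mn*·2^(−bits). Published BLAST constants (ungapped or gapped) made
the shuffled-sequence null anti-conservative here — several percent of
random pairs passed e < 0.001 — so the package carries its own
calibration and re-checks it with an empirical-null test. Parity with
any particular BLAST build is explicitly not promised; the 0.001 cut is
applied to this statistic.

**Interval estimates.** Binomial proportions (acquisition fraction,
plasmid loss) carry Wilson score intervals. At n = 100 the exact
coverage of the Wilson interval, computed by summing binomial mass over
covering outcomes, is 93.6–96.1 % across the loss rates of interest;
the tests assert that exact computation and require Monte Carlo
estimates to agree with it within sampling noise, rather than asserting
a noisy simulation against a sharp bound.

**Degenerate inputs.** Empty FASTQ input fails fast naming the merge
stage; an empty new-spacer set yields a clean empty classification; a
zero resistant-strain titer is censored at the detection limit
(`"> X logs"`), never reported infinite; plaque counts outside 30–300
are reported and excluded, and a titer without any admissible plate is
an error.

## Problem sizes and reproducibility

All randomness flows from one root seed through per-stage derived seeds,
so every stage is independently re-runnable and two runs with the same
configuration are byte-identical. The validation suite exercises
parameter recovery at 10,000 reads per condition (acquisition rates 0,
0.005, 0.33 and 1), 2,000-read cohorts for per-read truth agreement
(≥99 %), 500-site cohorts for PAM consensus recovery, and 1,000
replicate 100-colony screens for the loss-rate estimators; oracle
equivalence runs on 200 random sequences (repeat finder) and 100 read
pairs (merger). These sizes make binomial tolerances (3 standard
errors) tight enough to be meaningful while keeping a full run on one
CPU in minutes.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_reads = 2000, p_acq = 0.33, error_rate = 0.001,
                  seed = 42)
report <- run_pipeline(run_config(mode = "full", sim = cfg))
report$acquisition$estimate   # 0.333 (Wilson 95% CI 0.313-0.354)
report$abundance              # plasmid 0.808, acr 0.089, genome 0.104
report$pam_consensus          # "NNAGAAW"
```

## Known limitations

- Substitution-only matching throughout: an indel inside a repeat or
  spacer shifts the frame of everything downstream of it in that read.
- One acquisition per array: bursts of multiple insertions would be
  read as a single expansion plus novel spacers, not counted separately.
- The e-value calibration is tied to the package's scoring scheme and
  null model; screening decisions transfer, exact e-values do not.
- The fixture repeat/leader sequences are not the biological CR1
  sequences; analyses of real amplicons must supply the real repeat.
- The denominator of the acquisition fraction is parseable merged reads;
  unmerged and unparseable reads are reported but excluded, which can
  bias the fraction if mergeability correlates with expansion (longer
  expanded amplicons merge with smaller overlap).
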