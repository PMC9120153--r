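# spacerTracer

Quantifying CRISPR spacer acquisition (adaptation) from paired-end
amplicon deep sequencing of *Streptococcus thermophilus* type II-A CR1
arrays — plus the surrounding assay arithmetic and a truncated
anti-CRISPR homolog screen.

## What it computes

A type II-A CRISPR array is a series of direct repeats R separated by
spacers, expanded at the leader end when the cell acquires immunity:

```
leader - R - S_new - R - S1 - R - S2 - R - trailer
```

Given overlapping 2 × 250 bp read pairs over the leader-proximal window,
the package:

- **merges** each pair into one amplicon (minimum-mismatch overlap,
  quality-aware consensus);
- **parses** the array by a Hamming-tolerant scan for the repeat and
  reads off inter-repeat spacers;
- **calls acquisition** per read: expanded iff the read shows more
  repeat–spacer units than the ancestral window or contains a spacer
  farther than `novelty_max_mismatch` from every ancestral spacer; the
  cohort estimate `p̂ = expanded / parseable` carries a Wilson 95 %
  interval;
- **classifies targets**: each new spacer is mapped by exhaustive
  perfect-match search over both strands of the plasmid (circular),
  *acr*-gene and host-genome references, and read-count-weighted
  category abundances are reported;
- **infers the PAM**: the 7 nt 3′ of each perfectly matched protospacer
  (on its strand) enter a position frequency matrix; per-position
  information content is `2 + Σ p·log2 p` bits and the IUPAC consensus
  is the smallest degeneracy class reaching 90 % frequency mass —
  recovering `NNAGAAW` for CR1;
- **assay statistics**: plasmid-loss fractions with Wilson intervals,
  phage titers from plates with 30–300 plaques
  (`count · 10^-dilution / 0.1 ml`), efficiency of plaquing and
  log-reduction (`EOP · 10^logs = 1`, zero titers censored at the
  detection limit);
- **screens truncated anti-CRISPRs**: six-frame ORFs (ATG/TTG/GTG
  starts, ≥30 aa, longest per stop region), Smith–Waterman/BLOSUM62
  alignment with a simulation-calibrated e-value, and the filter
  identity ≥ 50 %, e < 0.001, length ≥ 30 aa and ≤ 90 % of the
  representative allele.

A fully seeded synthetic-data module (`sim_config()`,
`simulate_cohort()`) generates references with planted `NNAGAAW` sites,
arrays with leader-proximal insertions at a configurable per-read
probability, error-bearing read pairs, and colony screens — with ground
truth — so every stage is validated by parameter recovery rather than by
fixtures.

## Worked example

```r
library(spacerTracer)

cfg <- sim_config(n_reads = 2000, p_acq = 0.33, error_rate = 0.001,
                  seed = 42)
report <- run_pipeline(run_config(mode = "full", sim = cfg))

report$acquisition
#> $estimate 0.333   $lower 0.313   $upper 0.354
#> $n_expanded 666   $n_total 2000
unlist(report$abundance)
#>  plasmid      acr   genome unmapped ambiguous
#>    0.808    0.089    0.104    0.000     0.000
report$pam_consensus
#> [1] "NNAGAAW"
```

2000 simulated reads at a true acquisition probability of 0.33 give an
estimated expanded-read fraction of 0.333 (Wilson 95 % CI 0.313–0.354);
about 81 % of acquired spacers map perfectly to the plasmid, and the 666
extracted protospacer flanks collapse to the `NNAGAAW` consensus. The
report also carries merge/parse accounting, a chi-square statistic for
positional uniformity of plasmid protospacers, and a provenance block
(seed, thresholds, version).

File-based runs use the same engine: `run_config(mode = "analyze",
paths = list(r1 = ..., r2 = ..., references = ...,
ancestral_spacers = ...))` for FASTQ input, `mode = "screen"` for
contig/representative FASTA, `mode = "assay"` for colony-count tables. A
thin command-line wrapper is installed at
`inst/scripts/spacer-tracer.R`.

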