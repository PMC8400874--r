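# hbdscan

Model-based detection of **homozygous-by-descent (HBD) segments** and
estimation of genomic inbreeding from diploid SNP-array genotypes, aimed at
livestock and other managed populations (the motivating use case is purebred
and crossbred pigs).

Rule-based runs of homozygosity lump together autozygosity of very
different ages. `hbdscan` instead fits a hidden Markov model whose states
are HBD **age classes** with exponentially distributed segment lengths
(rates R = 2, 4, …, 512 per Morgan; expected length 1/R; ancestor age
≈ R/2 generations) plus one non-HBD class. Between markers separated by
*d* Morgans the current class-*c* segment survives with probability
e^(−R_c·d), otherwise a new segment starts from the class **mixing
proportions** *m*, which are estimated per individual by EM. Genotype
emissions depend on the allele frequency and a genotyping-error rate ε; HBD
states are (near-)homozygous, the non-HBD state is Hardy–Weinberg. From the
posterior decoding the package reports **realized autozygosity** per class
and the **inbreeding coefficient** F = 1 − (non-HBD proportion); Viterbi
decoding yields the segment records themselves.

The package also provides:

* PLINK PED/MAP and BED/BIM/FAM (plus plain TSV) panel I/O, the call-rate
  QC filter (≥ 95% by default), allele frequencies and the
  physical-to-genetic map (1 cM/Mb fallback);
* per-group segment summaries (counts, mean lengths ± SE per class,
  per-animal averages, five-number F summaries);
* overlap of decoded segments with genomic feature intervals (QTL/genes)
  from BED files;
* a generative simulator — the exact generative counterpart of the
  inference model, plus an F1-like outcross generator — with recorded
  truth for parameter-recovery validation;
* a file-level pipeline (`run_simulate`, `run_fit`, `run_segments`,
  `run_summarize`, `run_overlap`) and a thin CLI wrapper
  (`inst/cli/hbdscan.R`).

## Worked example

Simulate a small purebred-like cohort with 25% of the genome planted in
HBD classes, fit each animal, and summarise:

```r
library(hbdscan)

model <- default_model()                       # rates 2..512 + non-HBD, eps 1e-3
occ   <- c(rep(0.25 / 9, 9), 0.75)             # 25% HBD genome, split over classes
truth <- hbd_model(model$rates, mixing_for_occupancy(occ, model$rates))
sim   <- simulate_panel(sim_config(n_chrom = 5, markers_per_chrom = 1000,
                                   model = truth, n_individuals = 5, seed = 42))

fit  <- fit_hbd(sim$panel, model, by_group = FALSE)
fit$results[, c("sample_id", "F", "loglik", "n_iter")]
#>   sample_id      F  loglik n_iter
#> 1   sim_001 0.1927 -3434.2    239
#> 2   sim_002 0.1042 -3590.0    595
#> 3   sim_003 0.1376 -3560.9    281
#> 4   sim_004 0.1278 -3608.9    654
#> 5   sim_005 0.1156 -3580.4    493

segs <- decode_segments(sim$panel, fit)
head(segs, 5)
#>   sample_id chrom class_rate start_bp   end_bp n_snps length_mb
#> 1   sim_001     2         64 10000001 13400001     35       3.4
#> 2   sim_001     2         64 37100001 40000001     30       2.9
#> 3   sim_001     3         64 24300001 27900001     37       3.6
#> 4   sim_001     3        128 53800001 55800001     21       2.0
#> 5   sim_001     4          2 49900001 99900001    501      50.0

summarize_segments(segs, sim$panel$samples)$by_group
#>   group n_animals n_segments segments_per_animal mean_length_mb mean_n_snps
#> 1   sim         5         38                 7.6       6.573684    66.73684

inbreeding_table(fit$results$F, fit$results$group)
#>   group n    min     q1 median   mean     q3    max
#> 1   sim 5 0.1042 0.1156 0.1278 0.1356 0.1376 0.1927
```

Each fitted `F` is that animal's genome fraction in *any* HBD class; the
`class_rate` column tags each decoded segment with its age class (rate 2 ≈
parental-generation inbreeding, 512 ≈ very ancient). On this cohort the
true simulated F values are 0.23, 0.17, 0.20, 0.17, 0.17 — the fit tracks
individual differences while estimating ancient, few-marker segments
conservatively (see the methods vignette for why).

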