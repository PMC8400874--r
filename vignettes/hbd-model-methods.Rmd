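---
title: "Model-based HBD segment detection: methods and design choices"
author: "hbdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based HBD segment detection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdscan)
```

## The model

`hbdscan` detects homozygous-by-descent (HBD) genome segments — stretches
where both chromosome copies descend from a single ancestral copy — from
unphased diploid SNP-array genotypes. Rule-based runs of homozygosity (ROH)
conflate autozygosity of very different ages; the model-based alternative
implemented here assigns every marker to one of several **HBD age classes**
or to a **non-HBD** background, using a hidden Markov model.

Each class $k$ has an exponential segment-length distribution with rate
$R_k$ per Morgan: the probability that a segment survives between two
markers separated by $d$ Morgans is $e^{-R_k d}$, and its expected length is
$1/R_k$ Morgans. Because segment length halves with each meiosis, a class
with rate $R$ collects autozygosity from common ancestors roughly $R/2$
generations back: $R = 2$ corresponds to parents, $R = 4$ to grandparents.
The default ladder uses nine HBD classes with rates
$2, 4, 8, \dots, 512$ plus one non-HBD class sharing the last rate, ten
states in all. (Only nine HBD rates exist even though there are ten states;
the non-HBD class borrows the 512 rate so that non-autozygous stretches can
also be interrupted at realistic scales.)

The hidden state sequence follows the transition kernel

$$A_{c,c'}(d) = e^{-R_c d}\,\mathbf 1\{c = c'\} + \bigl(1 - e^{-R_c
d}\bigr)\, m_{c'},$$

where $m$ is the vector of **mixing proportions** — the probability that a
newly started segment belongs to each class. Chromosomes are independent;
each starts from $m$.

Emissions depend on the coded-allele frequency $p$ and an error
probability $\varepsilon$ that folds genotyping error and mutation into one
nuisance parameter (default $10^{-3}$). All HBD classes share

$$P(2) = (1-\varepsilon)p + \varepsilon p^2, \quad
  P(1) = \varepsilon\, 2p(1-p), \quad
  P(0) = (1-\varepsilon)(1-p) + \varepsilon (1-p)^2,$$

while the non-HBD state emits Hardy–Weinberg proportions
$p^2, 2p(1-p), (1-p)^2$. The essential role of $\varepsilon$ is to allow
occasional heterozygous calls inside a true HBD segment; the non-HBD
emissions are left unperturbed. Missing genotypes are uninformative
(likelihood 1 in every state).

## Inference

* **Forward–backward** (scaled, per chromosome) yields per-marker posterior
  state probabilities. Averaging them over the genome gives the **realized
  autozygosity** per class; the **inbreeding coefficient** is the summed
  HBD realized autozygosity, identically $1 -$ the non-HBD proportion.
* **EM** estimates the mixing proportions per individual; the rate ladder
  stays fixed. The M-step sets each class frequency proportional to the
  expected number of segments *started* in that class: chromosome-start
  occupancies plus expected termination ("reset") events inside
  transitions. Treating the reset indicator as an extra latent variable
  makes this an exact EM step, so the log-likelihood is provably
  non-decreasing — the implementation raises an error if it ever drops by
  more than numerical noise, and the test suite asserts monotonicity.
  Mixing is estimated per individual because partial inbreeding of
  different ages varies strongly between animals even at equal total $F$.
* **Viterbi** decodes the single most probable state path (log-space,
  per chromosome) from which segment records are built. Ties are broken
  toward the lowest class index, i.e. the most recent class — a
  deterministic convention that keeps recent inbreeding visible.

Realized autozygosity and $F$ are reported from the posterior decoding;
segment counts and lengths come from the Viterbi path. The two views are
kept clearly separate in all outputs.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| rate ladder | 2…512 (+512 non-HBD) | Morgan⁻¹ | age resolution of the classes |
| `eps` | 0.001 | probability | heterozygotes tolerated inside HBD |
| `min_call_rate` | 0.95 | fraction | the only genotype QC: marker call rate |
| `cm_per_mb` | 1 | cM/Mb | physical→genetic map when no cM column exists |
| EM `tol` | 1e-6 | log-likelihood | convergence; `max_iter` 1000 |

The 1 cM/Mb fallback is the standard constant-rate assumption for livestock
SNP arrays; an explicit centiMorgan column in the map, when present, always
takes precedence. QC is deliberately minimal — a marker-wise call-rate
filter only, no MAF or sample filters — because every additional filter
distorts the allele frequencies that the emissions rely on. Allele
frequencies default to per-group computation (pooled on request): emissions
in breed-stratified data are better calibrated within group.

## The synthetic-data generator

`simulate_panel()` draws latent class paths *through the same transition
kernel the inference uses*, at marker resolution, and genotypes through the
same emission model; at fine spacing this coincides with drawing continuous
exponential segment lengths, and it is the correct oracle for recovery
tests. Defaults: 10 chromosomes × 1,000 markers at 0.001 Morgan spacing
(a dense array), allele frequencies i.i.d. Uniform(0.05, 0.95), 20
individuals. The generator records the truth — state paths,
segment-termination events, occupancy fractions, true $F$ — so parameter
recovery can be scored exactly. Termination events are recorded separately
from the path because a terminated segment may be followed by a new segment
of the same class, which is invisible in the state sequence alone.

`simulate_outcross()` produces F1-like individuals by drawing one allele
from each of two independent frequency pools per marker — offspring of two
unrelated populations, carrying no recent autozygosity.

What the generator does **not** emulate: linkage disequilibrium between
markers, allele-frequency estimation error, array ascertainment bias,
genotyping batch effects, and pedigree-based recombination. Passing
recovery tests therefore demonstrates correctness of the inference
machinery under its own assumptions, not robustness to real-data artefacts.

Because the non-HBD class shares the steep 512 rate, the *uniform-mixing*
default model implies an almost fully autozygous genome at stationarity
(occupancy is proportional to $m_c/R_c$). The recovery suite uses exactly
that default as the generating truth. For study-like simulations the helper
`mixing_for_occupancy()` converts a target genome fraction into mixing
proportions; the pipeline's simulate command plants 25% HBD genome mass by
default, a level typical of intensively selected livestock.

## Numerical choices

* Scaled forward–backward (per-marker scaling constants); log-space
  Viterbi; probabilities floored at 1e-300 to avoid underflow on
  monomorphic or contradictory markers.
* Survival probabilities $e^{-R_c d_t}$ are precomputed once per fit — they
  depend only on the fixed rates and marker spacing — which makes EM cost
  linear in markers × states per iteration.
* EM stops on an absolute log-likelihood change below `tol` or at
  `max_iter`; with `tol = Inf` exactly one update is performed. A
  log-likelihood decrease beyond 1e-6 aborts with an error, as it can only
  indicate an implementation defect.
* Quartiles in the inbreeding summary use linear interpolation (type 7),
  the convention of standard statistical summaries.
* Segment bounds are the first/last marker of the Viterbi run — no
  extension halfway toward flanking markers — so a single-marker segment
  has physical length 0 and SNP count 1, consistent with joint
  length-and-SNP-count reporting. Adjacent runs of different HBD classes
  are distinct segments.
* Interval overlap converts segments to 0-based half-open coordinates
  (`start_bp − 1`, `end_bp`) before intersecting with BED features; any
  nonzero intersection counts. A feature spanning several segments counts
  once in the distinct-feature totals and once per segment in the listings.

## Verification strategy and problem sizes

The test suite validates the recursions against brute-force enumeration
over *all* state sequences on instances of up to 8 markers and 3 states
(agreement to 1e-10 relative, for both the forward likelihood and the
Viterbi path probability), and every counting operation (QC, frequencies,
run-length decomposition, interval overlap, summaries) against an
independent quadratic or tally oracle. End-to-end checks use the generator:
$F$ recovery on 20 individuals at 10 × 1,000 markers (mean absolute error
well under 0.03 in practice), EM monotonicity across 20 individuals, the
$1/R$ mean-length law for $R \in \{2, 32, 512\}$ within two standard
errors, and a purebred-vs-outcross contrast (25% planted HBD genome vs F1)
that must hold in every one of ten seeded replicates. These sizes keep a
full run of the suite at a few minutes on one CPU while leaving each check
statistically sharp.

## Known limitations

* Rates are never estimated; the ladder is part of the model definition.
  If the true age structure falls between rungs, mass is shared by the
  neighbouring classes.
* Very ancient classes (rates 256–512 at typical array densities) generate
  segments of only a few markers; their individual occupancies are weakly
  identified and partially absorbed by the non-HBD class, so total $F$ on
  moderately autozygous genomes is conservatively estimated.
* Allele frequencies are plugged in as known; uncertainty from small group
  sizes is not propagated.
* The model is haplotype-free: phased data, and relatedness *between*
  individuals, are out of scope.
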