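---
title: "Methods: ancient-DNA mitogenome identity matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancient-DNA mitogenome identity matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical model and
the design decisions behind it. It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The inference and its assumptions

The question answered by the pipeline is: *do two museum specimens carry
the same complete mitochondrial genome?* The mitogenome is haploid and
maternally inherited, so all tissues of one individual share one
sequence; an exact match over a sufficiently long comparable region is
therefore strong evidence of common origin, under two assumptions that
the user must justify externally: (i) mitochondrial diversity in the
population is high enough that unrelated individuals differ (for the
target species here, surveyed individuals all carried distinct
haplotypes), and (ii) the compared consensuses are free of reference
bias and damage artefacts — which is what most of the machinery below
is for.

A match is *never* declared from raw distance alone: the
`match_candidates()` report requires `diff_count == 0` **and** at least
`min_overlap` jointly defined positions (default 10,000 of a ~16.7 kb
mitogenome). The guard is deliberate: complete deletion removes every
column undefined in *any* sample, so one ruined library shrinks the
comparison for everyone, and a "perfect match" over a few hundred
columns would be vacuous.

## Damage model

Post-mortem deamination converts cytosine to uracil, read as C→T, with
the complementary strand showing G→A. Overhanging fragment ends
deaminate fastest, so the mismatch frequency decays from each end. We
model the probability that an eligible base at terminal offset
\(i\) (0-based) is deaminated as

\[ d_i = d_0 \, \lambda^i, \qquad 0 \le d_0 \le 1,\; 0 < \lambda < 1, \]

truncated to zero beyond a window (default 25 bp). Single-stranded
library preparations exhibit C→T at **both** read ends; double-stranded
preparations show C→T at 5' and G→A at 3'. The estimator
(`estimate_damage()`) counts, per offset, reads with T over a reference
C (and the analogous series), and fits \((d_0, \lambda)\) by least
squares over offsets with at least 25 informative observations. The
geometric form is a pragmatic two-parameter summary, not a mechanistic
nick-frequency model; its purpose is quality rescaling, not authenticity
testing.

Rescaling (`rescale_quals()`) inflates the error probability of each
damage-consistent mismatch: \(e' = e + d_i(1-e)\), new quality
\(\lfloor -10\log_{10} e' \rceil\). Bases within reach of both ends
combine the per-end probabilities as \(1-(1-d_5)(1-d_3)\). Only
transitions consistent with deamination chemistry are touched; rescaling
can only lower a quality. Applying damage at the template level and
sequencing error per emitted read (so PCR duplicates share damage but
not error) mirrors the physical process and is what the simulator does.

## Genotyping and consensus tiers

Per site, the haploid log-likelihood of allele \(b\) is
\(\sum_{r} \log(1-e_r)\) over reads carrying \(b\) plus
\(\sum_r \log(e_r/3)\) over the rest, with \(e_r\) from the (rescaled)
Phred quality. GQ is \(10(\log_{10} L_{best} - \log_{10} L_{2nd})\),
capped at 99. Exact likelihood ties go to the reference allele when it
is tied, else to the alphabetically first, with GQ 0 — ties only arise
from symmetric evidence, and the GQ ≥ 30 consensus gate masks them
anyway. MAPQ is *not* folded into the likelihood; it is a hard gate
(< 20 removed) upstream, matching how the original toolchain used it.

The two consensus tiers carry the published thresholds exactly:

| tier | GQ | depth | majority fraction | max missing |
|------|----|-------|-------------------|-------------|
| relaxed | ≥ 30 | ≥ 3 | > 0.33 | ≤ 0.33 |
| strict | ≥ 30 | ≥ 10 | > 0.90 | ≤ 0.20 |

Boundary semantics follow the thresholds' wording literally: "less than
30 filtered" means GQ 30 passes; "no more than 20% missing" is
inclusive; the majority-fraction rule is a strict inequality (0.90
exactly fails the strict tier). Fractions are computed on raw read
counts. Where the called (likelihood-best) allele exactly ties another
allele in count, the site is masked; when the likelihood-best allele is
not the count majority (possible after damage rescaling), the
likelihood wins — that is the point of rescaling, and the conservative
alternative (mask) would silently discard exactly the sites the damage
model was built to rescue. Missingness is accounted against the full
reference length, matching per-sample sequence-length bookkeeping.

## Alignment, distances, matching

Because every consensus lives in shared reference coordinates and the
analysis is substitution-only, the default "alignment" is reference
projection — the consensus strings stacked as-is. A genuine multiple
aligner adds value only if indels exist among the consensuses; none are
modelled here (gapless alignment model; indel realignment is out of
scope). An externally produced alignment FASTA can be ingested instead,
and ragged rows raise an error rather than being silently padded.

Complete deletion keeps exactly the columns where every row has A/C/G/T
('-' treated like N), preserving order; the pairwise matrix counts
differing columns (count-form p-distance, no evolutionary correction,
matching how such matrices are published). Pairwise-deletion mode is
available for diagnostics.

## Phylogeny

The tree stage fixes the substitution model to HKY (unequal base
frequencies, transition/transversion ratio κ) — model selection is out
of scope, HKY being the selected model in the motivating analysis — and
proceeds: NJ on normalised p-distances (`diff/positions`), then iterated
bounded one-dimensional optimisation of each branch length in [0, 10]
substitutions/site with κ optionally profiled on the same schedule,
until the log-likelihood improves by < 1e−6 or 50 sweeps. The likelihood
is Felsenstein pruning over compressed site patterns, with HKY transition
probabilities from the eigendecomposition of the reversible rate matrix
(symmetrised via \(\Pi^{1/2} Q \Pi^{-1/2}\) for numerical stability).
Two deliberate deviations from the motivating toolchain, both
documented limitations: the NJ start uses plain p-distances rather than
maximum-composite-likelihood distances (for near-identical mitogenomes
the two are numerically indistinguishable, and the start tree only
seeds optimisation), and no topology search beyond the NJ start is
performed (with a handful of near-identical sequences the NJ topology
is retained).

Bootstrap support resamples alignment columns with replacement, builds
an NJ tree per replicate, and reports the percentage of replicates
containing each internal bipartition of the reference tree. Because no
topology search is performed within replicates, per-replicate
branch-length optimisation cannot change any bipartition; it is
therefore off by default (`optimize_replicates = FALSE`) and supports
are identical either way — this is the one place the implementation
intentionally simplifies the stated per-replicate schedule.

## The synthetic-data generator

`simulate_study()` emulates the features of museum aDNA that the
pipeline's correctness depends on: short truncated-lognormal fragments
(meanlog = log 60, sdlog = 0.35, truncated to [15, 300] bp — generic
aDNA values, as the motivating libraries report no fragment-length
summaries), uniform placement on the circle with wrap-around, uniform
strand, geometric-decay terminal deamination with library-type-dependent
chemistry, per-base sequencing error with Phred-consistent qualities
(constant Q30 by default, optional jitter), PCR duplicates that copy the
damaged template, and per-sample coverages spanning the ~6–430×
range of real libraries. One root seed derives per-sample streams by
fixed offsets, so adding a sample never perturbs earlier ones, and a
fixed seed gives byte-identical FASTQ.

It does **not** emulate: indels, heteroplasmy, nuclear-mitochondrial
insertions, cross-species contamination (hook present, default 0),
insert-size structure of uncollapsed pairs, or reference bias from
mapping to a diverged reference. Passing tests therefore demonstrate
correctness of the pipeline's logic under its stated model, not
robustness to every artefact of real museum data.

Defaults used in the shipped analyses and acceptance checks were chosen
once as representative study conditions: 16.7 kb reference (the scale
of an auk mitogenome), 7 samples with one planted identical pair and
10–25 substitutions between the rest, 30× coverage, single-stranded
damage with \(d_0 = 0.2, \lambda = 0.5\) (moderate damage typical of
~150-year-old specimens); the damage-recovery check simulates
\(d_0 = 0.3\).

## Numerical and degenerate-input choices

* Coordinates are 1-based closed intervals (Bioconductor convention);
  circularity is handled by doubling the reference internally and
  reducing positions modulo its length on output.
* The mapper's MAPQ is a simplification (60 unique / 0 tied /
  `10·(mm2−mm1)` otherwise): downstream the value is only ever gated at
  ≥ 20, so aligner-faithful MAPQ modelling would add nothing testable.
* Adapter matches shorter than 9 bp are ignored; chance agreement of a
  read's last bases with the adapter start would otherwise nibble
  genuine sequence. Read-through pairs (fragment shorter than the read)
  are handled by allowing negative mate shifts in the merge alignment,
  which trims both adapters implicitly.
* Depth-0 sites are explicit no-calls, written as "." genotypes in VCF
  and counted as missing by every tier.
* NJ's negative intermediate branch lengths are clamped to 0; the
  3-taxon case uses the closed-form three-point formulas.
* Likelihood ties, count ties, and the `min_overlap` match guard are
  resolved conservatively (reference / mask / no-match respectively).
* Pattern compression, re-rooting invariance, and the pruning
  likelihood itself are verified against exhaustive-state and
  independent-library oracles in the test suite; problem sizes there
  (2–4 kb references for unit tests, full 16.7 kb for the end-to-end
  and acceptance checks) were chosen to keep the default test run fast
  while exercising the study-scale path.

## Known limitations

Substitution-only throughout (no indel calling or realignment); no
IUPAC ambiguity codes in consensuses (N only); no diploid or
multi-sample joint calling; no Bayesian damage model or formal
authenticity statistic; no gamma rate heterogeneity or model selection
in the tree stage. Coverage values and bootstrap supports of the
motivating study depend on its unreleased raw reads and are therefore
checked as reproducible *properties* (oracle equality, determinism,
strong-signal recovery) rather than as numbers.
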