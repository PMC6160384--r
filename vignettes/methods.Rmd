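---
title: "Models and methods behind mirnadelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirnadelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnadelta)
```

`mirnadelta` reimplements, as a reusable and tested toolkit, the
computational analysis of a knockdown-style small RNA sequencing study:
how reads become mature-miRNA and isomiR counts, how two unreplicated
libraries are compared, how arm selection and isomiR-pattern changes are
screened, how cancer-candidate miRNAs are selected from cohort data, and
how a risk-score survival screen works. Every stage can be driven by the
package's own seeded simulators, which plant a known ground truth, so the
entire pipeline is testable offline. This vignette explains the models,
the parameter choices, and the design decisions that were genuinely open.

## From raw reads to isomiR counts

**Adapter trimming.** Reads from short-insert small RNA libraries run
through the insert into the 3' adapter. `trim_adapter()` scans candidate
adapter start positions left to right and removes the first occurrence
(full or 3'-truncated) with an overlap of at least 6 bases and at most 2
mismatches; when no occurrence is found, the last 6 bases are removed;
remainders shorter than 10 nt are discarded. These three rules define the
behavior completely - the function is not a bit-for-bit reimplementation
of any particular trimming tool.

**Collapsing and placement.** Trimmed reads are grouped into unique reads
with multiplicities; unique reads seen fewer than 3 times are dropped by
default (configurable). `place_exact()` reports every zero-mismatch
occurrence of each unique read on both strands, via a hash index of
genome substrings - contract-equivalent to a zero-mismatch aligner at toy
genome scale. Multi-placement reads are retained with all placements;
assignment decides usage downstream.

**Assignment and classification.** A placement is assigned to a mature
arm when the read is 17-26 nt, the strand matches, and at least 17 of its
bases fall within the arm extended by 2 nt at each end. Classes follow
the end offsets, computed in transcript orientation against the annotated
mature ends (negative = trimming, positive = templated addition):
canonical (0,0); 5'-only shift; 3'-only shift; both-end shift; and the 3'
non-template single-nucleotide extension, defined as the exact mature
sequence plus one trailing base that differs from the genome-templated
next base. Non-template extensions cannot map to the genome exactly, so
they are recovered from the *unplaced* unique reads by direct comparison
against mature sequences. A templated one-base 3' extension maps exactly
and is classified as a 3' variant instead - the two cases are mutually
exclusive by construction.

Open choices resolved here: the offset window is capped at +-2 nt per end
(the dominant Drosha/Dicer wobble; larger offsets go to a spill log
rather than being force-classified); a read overlapping both arms of one
precursor goes to the arm with the larger overlap, with exact ties to the
5' arm; a read whose sequence matches arms of two different precursors
contributes its full count to each, which is conservative for
within-precursor arm ratios.

## Two-library count statistics

**Audic-Claverie test.** With a feature observed $x$ times among $N_1$
reads, the posterior-predictive law of its count $Y$ in a second library
of $N_2$ reads is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

i.e. $Y \mid x \sim \mathrm{NB}(x+1,\ N_1/(N_1+N_2))$. `ac_test()`
computes tails by exact log-space summation (no approximation). Two
decisions were open. First, sidedness: the package doubles the smaller
tail (two-sided), which is the conservative reading; users screening at a
one-sided threshold can halve the p-values. Second, the conditional law
is not symmetric in the two libraries for finite counts, yet no library
is privileged scientifically; each one-sided tail is therefore computed
as the average of the two conditional formulations (condition on $x$,
tail over $y$; condition on $y$, tail over $x$), which makes the
two-sided p exactly invariant under swapping the libraries. Tests hold
the implementation to an independent negative-binomial-CDF oracle at
$10^{-12}$ over the full grid $x, y \le 50$.

Each miRNA's expression enters the screen as the count of its single most
abundant sequence variant, and features are flagged at raw
$p < 10^{-3}$; with one library per condition there is no
replicate-based dispersion to estimate, and the screen applies a raw
threshold (a Benjamini-Hochberg column is emitted for information only).

**IsomiR pattern changes.** Per miRNA, a chi-square test (no continuity
correction) on the 2 x 4 table of the four isomiR classes - canonical
reads are excluded from the table but included in the share denominators.
A miRNA is flagged only when the test is significant at 0.05, its total
count reaches 1000 in at least one condition, and some class's share of
the total shifts by at least 5 percentage points. The share criterion is
read as percentage points (scale-free and stricter than a relative 5%);
it is configurable. Expected cells below 5 produce a warning column, not
an abort. Classes absent from both conditions are dropped with the
degrees of freedom adjusted; a condition with no isomiR reads at all
yields p = 1 rather than an undefined statistic.

**Arm switches.** Per precursor and condition the 5'/3' ratio is
$(c_{5p}+1)/(c_{3p}+1)$ - pseudocount 1 keeps zero-count arms finite -
and a precursor is flagged when the ratio changes at least 1.5-fold in
either direction, boundary inclusive.

## The candidate-selection pipeline

The cohort stage consumes miRNA and transcript count matrices, a
binding-site count matrix, and differential-expression tables in a fixed
`id, base_mean, log2fc, p, adj_p` layout. Any external DE tool producing
that layout can be used; the built-in `simple_de()` (Welch t on
log2(CPM+1)) exists only so synthetic runs are self-contained and is
deliberately not a reimplementation of any cohort DE method.

**Interactions.** Per-sample interaction signatures are pluggable:
the default rule activates a miRNA-transcript pair when it has a
predicted binding site and both features are expressed in that sample,
and drops miRNAs with fewer than 5 active targets in a sample; an
externally computed per-sample probability matrix can be dropped in
instead. Consensus targets are the exact per-miRNA intersection across
samples - interpretable, but intentionally strict: an interaction absent
from a single sample is excluded.

**Ranked enrichment.** Transcripts are ranked by a signed score:
$\log_{10}(\text{base mean}) + |\log_2 \text{FC}|$, plus
$|\log_{10}(\text{adjusted } p)|$ when the base mean exceeds 30, signed
by the fold-change direction. The enrichment of a target set toward
either end of the ranked list is evaluated at 30 rank-quantile cuts; at
each cut a two-tailed Fisher exact test of membership against side is
run, and the best p is Bonferroni-corrected for the number of cuts. The
cut count and correction are package choices (behavior-compatible with
threshold-free ranked-set tools, not bit-compatible with any), and the
result is invariant under order-preserving transformations of the score.
Clamps keep degenerate inputs finite: base mean below 1 is clamped to 1,
adjusted p below 1e-300 to 1e-300, and p-values are clamped to
[1e-16, 1-1e-16] before normal inversion.

**Selection.** Per miRNA, the DE and enrichment adjusted p-values are
combined by normal inversion ($z$-sum over $\sqrt{2}$), BH-adjusted
across miRNAs, and a candidate must satisfy: (A) DE FDR < 0.1; (B)
targets shifting opposite to the miRNA; (C) correlation with the
designated regulator gene at FDR < 0.1, computed within the tumor
samples so that tumor-control shifts cannot inject spurious correlation.
Over-representation of candidate sets in external categories uses the
upper-tail hypergeometric; generic term over-representation uses
two-tailed Fisher with BH. The network export emits deterministic
three-axis node/edge tables (miRNA, mRNA, term) rather than rendered
graphics.

## The survival screen

Per feature: a univariate Cox fit (Breslow ties, via the `survival`
package, convergence tightened to $10^{-9}$), a risk score defined as
coefficient x expression, a median split of the scores (HIGH strictly
above the median; exact-median ties LOW), and a two-group log-rank test,
BH-adjusted across features. The split point is configurable because the
choice between median, mean or optimal cut was genuinely open; the
median is the field's default and keeps group sizes within 1 on distinct
scores. Note that for a single feature the score is monotone in
expression, so the screen reduces to a median-expression split plus a
direction flag - that is by design and documented so users do not expect
more from the dichotomization. Features with no events, constant
expression, or monotone likelihood are reported as unfit rather than
silently dropped.

## What the simulators emulate - and what they do not

`build_reference()` embeds hairpins (5' arm, 12-nt loop, 3' arm = reverse
complement of the 5' arm with 1-2 substitutions) in random sequence,
alternating strands. The loop length is arbitrary but recorded in the
GFF3 so annotations are self-describing. `simulate_small_rna_library()`
draws reads as insert + adapter + uniform-random filler at a fixed 86-nt
read length; per-mature baselines are log-normal and shared across
conditions, condition 2 applies planted fold changes, per-precursor
5'-arm fractions can be overridden per condition, end offsets follow a
configurable distribution dominated by 3' variation, and non-template 3'
additions draw A:0.5, U:0.4, C/G:0.05 each (a typical tailing
composition; the composition of such additions is not otherwise
constrained). Offset pairs that would push an insert outside the 17-26 nt
profiling window are resampled, so every simulated read is in principle
recoverable. Sequencing error is a uniform per-base miscall; there is no
quality model, no structured error profile, and no rRNA/tRNA/piRNA
background beyond an optional uniform unannotated fraction. Passing tests
on these libraries therefore demonstrate correctness of the accounting
and the statistics, not robustness to real-platform artifacts.

`simulate_expression_cohort()` draws negative-binomial counts around
log-normal baselines with a per-sample biological log-normal factor
(`bio_sdlog = 0.8`, technical dispersion 0.02 - together a total CV near
1, typical of tumor cohorts). Suppressed targets' tumor means drop by the
planted repression strength times the miRNA's log2 change, and chosen
miRNAs share the regulator's latent factor at a requested correlation;
because counts add technical noise on top, the count-scale correlation
is mildly attenuated relative to the latent one (about 0.85 observed for
0.9 planted). `simulate_survival_cohort()` draws exponential survival
times with hazard $h_0 e^{\beta z}$ on standardized log expression and
independent exponential censoring whose rate matches the requested
censoring fraction under the baseline hazard.

## Problem sizes and numerical notes

The shipped tests and the acceptance script use deliberately small but
sufficient problem sizes: 50,000-read libraries over 20 hairpin loci for
classification accuracy; a 90-sample, 50-miRNA, 400-transcript cohort
with three planted suppressors for pipeline recovery; $n = 500$ for Cox
coefficient recovery; 200 permutations for survival null calibration;
1000 multinomial draws for the chi-square screen; and the full
$51 \times 51$ count grid at three library sizes for the
Audic-Claverie oracle. All simulators take explicit seeds and restore
the caller's RNG state; identical seeds give byte-identical FASTQ, FASTA,
GFF3 and TSV outputs.

Known limitations: exact placement does not model mismatched alignment
(mismatched reads are dropped, as in the zero-mismatch analysis the
package follows); the non-template-extension definition is anchored to
the annotated mature sequence (prefix-exact plus one non-templated base)
rather than to mismatch-tolerant genome alignment; consensus target sets
are brittle to single-sample dropouts by construction; and the
enrichment partition heuristic is a documented stand-in, so its p-values
are comparable in behavior, not in bits, to other ranked-set tools.
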