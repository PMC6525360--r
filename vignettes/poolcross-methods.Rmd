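---
title: "Estimating outcrossing rates from pooled amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating outcrossing rates from pooled amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcross)
```

## The measurement model

A mother plant with mixed mating produces a seed pool in which a
fraction $t$ of seeds are outcrossed and $1 - t$ selfed. Each diploid
seed carries one maternal allele; its paternal allele is maternal again
under selfing and drawn from the pollen cloud under outcrossing. At an
amplicon $a$, let $q_a$ be the combined frequency of the maternal
haplotype(s) in the pollen pool. Then the expected fraction of
*non-parental* alleles among the $2n$ alleles of an $n$-seed pool is

$$\mathbb{E}[f_a] \;=\; \frac{t}{2}\,(1 - q_a),$$

and the estimator reported by `estimate_outcrossing()` is
$\hat t = 2\,\overline{f_a}$, the doubled arithmetic mean over an
amplicon subset $S$. Amplicons are weighted equally in that mean; read
counts differ between amplicons for technical (amplification) rather
than biological reasons, so count-weighting would import exactly the
bias the equal-primer-efficiency design tries to avoid. $\hat t$
converges to $t(1 - q)$, never to $t$ itself, when sharing is present:
outcrossing by pollen that carries a maternal haplotype is invisible to
a pooled single-amplicon readout. Estimates above 1 are reported with
an `over_unity` flag and never clamped, so aberrant inputs stay
visible.

Fragments are classified against the maternal line's leaf libraries.
The leaf calling threshold (`min_parent_freq`, default 0.05 of the
leaf's retained fragments) only needs to sit well above the 1% noise
floor and well below the ~50% of a heterozygous allele; any value in
that wide corridor behaves identically for near-homozygous lines.
When the parental lines differ at an amplicon, counting "not my
mother's haplotype" would score the other line's pollen differently
for the two lines; `run_estimate(mode = "auto")` therefore switches
such amplicons to `exclude_all_parents`, where only haplotypes found
in *no* parental line enter the numerator (the denominator, all
retained fragments, is unchanged, so the focal-only frequency is
always an upper bound of the exclude-all frequency).

## Read handling

Each mate is matched at its 5' end against the gene-specific primers of
the panel: anchored comparison, substitutions only, allowed mismatches
$\lfloor r \cdot L \rfloor$ at error rate $r$ (default 0.1) and match
length $L$. Indels are deliberately not modelled: an indel inside the
primer shifts the downstream bases, and the exact-length filter would
discard the read anyway, so a substitution-only matcher reaches the
same retained set more cheaply and with simpler tie-break semantics
(fewest mismatches, then the longer heterogeneity variant over the
plain one, then panel order). `N` bases count as mismatches; base
qualities are carried but never interpreted, since the downstream
frequency filters subsume per-base quality weighting.

Trimming equalizes the two primer versions: a heterogeneity-matched
read loses primer plus its extra A/T; a plain-matched read loses the
primer and then one base from its 3' end. Both keep
`read_length − plain_len − 1` bases, so every fragment of an amplicon
has one fixed length and fragment identity is a pure string key. The
haplotype is the concatenation of the two kept mates in as-sequenced
orientation — no merging, no reverse-complementing — because ~300–400
bp inserts do not reliably overlap at 2 × 150 bp and counting only
needs identity, not assembly.

## The two filters

Within each library × amplicon cell, haplotype frequencies for
filtering are computed over the *pre-filter* totals; the sums of the
surviving fragments are the baseline for all later proportions. The
rules:

1. frequency < `min_freq` (default 1%) in the cell → removed there
   (random sequencing errors). A haplotype at exactly 1% is retained —
   the rule excludes strictly below-threshold haplotypes.
2. not reaching `min_freq` in at least `min_samples` (default 2)
   libraries of that amplicon → removed everywhere. An early-cycle PCR
   error can reach several percent, but only in the library where it
   happened; real donor haplotypes recur across libraries that share a
   pollen pool. Leaf libraries count as libraries here.

The presence rule ships in two variants because the source wording is
ambiguous: the default `at_threshold` requires ≥ `min_freq` in
≥ `min_samples` libraries; `any_count` accepts any nonzero count. The
`any_count` retained set is always a superset of the `at_threshold`
one. Setting `min_freq = 0` and `min_samples = 1` switches filtering
off, which the property tests use as an identity check.

A known limitation follows from the raw-total denominator: with
per-base substitution error $e$, only $(1-e)^{258}$ of fragments are
error-free (about 27% at $e = 0.005$ for 258-nt fragments), so every
*true* haplotype's raw frequency is thinned by that factor. When a true
donor haplotype's thinned frequency approaches `min_freq` — low $t$,
high sharing $q$, moderate read depth — rule 1 starts to truncate real
signal and $\hat t$ is biased below $t(1-q)$. The acceptance suite
measures this directly: recovery at $t = 0.3, q = 0$ is unbiased
within simulation noise, while the $q = 0.5$ arm at $e = 0.005$ and
2,000 reads/amplicon sits exactly at this threshold interaction and
under-recovers. Deeper sequencing, a lower error rate, or relaxing
`min_freq` all move the regime boundary.

## The simulator

`simulate_experiment()` generates the full design — by default two
maternal genotypes × two treatments (open pollination at $t = 0.3$,
insect exclusion at $t = 0$) × three replicate blocks, plus one leaf
library per genotype: 14 libraries, mirroring a field trial with
pooled ~300-seed samples. Per seed, outcrossed status is drawn once
(it is a property of the seed, shared across amplicons); per amplicon,
an outcrossed paternal allele is maternal with probability $q_a$ and
otherwise uniform over the non-maternal donor haplotypes. The donor
pool holds two distinct non-maternal haplotypes per amplicon by
default: the emulated trial's pollen donors were two near-isogenic
lines — isogenic away from their differing locus, hence one shared
background haplotype — plus one inbred outcrosser-like line. Reads
sample alleles uniformly (no amplification bias; the panel design
targets single-copy, low-polymorphism genes precisely to justify
this), choose the heterogeneity or plain primer variant with equal
probability per mate, and acquire i.i.d. per-base substitution errors
(default $e = 0.005$). Each cell can receive one sample-private
jackpot haplotype at a uniform 1–5% frequency (probability 0.2 per
cell by default), exercising the single-sample rule. Constant "I"
qualities are emitted; the pipeline ignores them.

What the simulator does *not* model — and what passing tests therefore
do not certify about real data: indels and chimeric reads, quality
decay along the read, index hopping, amplification efficiency
differences between haplotypes by default (`maternal_efficiency`
optionally skews read sampling toward maternal alleles to demonstrate
how even modest amplification bias hides outcrossing; it is 1 — no
bias — in every standard run), biparental inbreeding
structure in the pollen cloud, and read-length variation. Insert
sequences are i.i.d. random DNA, so distinct haplotypes are far more
distinguishable than real alleles that differ at a handful of sites;
collision behaviour of near-identical alleles is untested by design.

Determinism: all randomness flows from the single config seed, and an
identical seed reproduces the experiment byte for byte (plain-text
FASTQ by default; gzip optional).

## Primer design module

`design_panel()` demonstrates the panel-design strategy on population
alignments: flag each column invariant / polymorphic / gap-or-N, collect
all invariant windows of the primer length whose GC fraction lies in
0.4–0.6 and whose Wallace-rule melting temperature
($2(A{+}T) + 4(G{+}C)$) is within 55 ± 5 °C, then pick the window pair
maximizing enclosed polymorphic columns subject to a 300–400 nt
enclosed region. Wallace-rule Tm rather than nearest-neighbour
thermodynamics is a stated simplification: the module demonstrates the
conserved-window search, not oligo chemistry. Coordinates are 1-based
inclusive in reports, 0-based half-open internally. Emitted primers
carry the adapter tails and alternating A/T heterogeneity bases and
re-parse through the panel module unchanged.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on simulated data at
sizes chosen to exercise every code path while staying desk-scale: unit
tests use a 3-amplicon toy panel with 30-nt reads and a few hundred
pairs; the recovery runs use 20 simulations × 3 seed pools × 8
amplicons × 2,000 read pairs, the read depth and pool size of the
emulated study. Recovery is judged against three empirical standard
errors of the mean over simulations. Ties in primer matching are fully
deterministic (documented above), as is the window-pair choice in
design (first pair in scan order among equals), so reruns are
byte-identical. Degenerate statistics are defined explicitly rather
than left to NaN: zero variance in both groups yields p = 1 when means
agree and p = 0 otherwise, always flagged; empty amplicons are dropped
from the averaging subset with a flag, and an empty subset is an
error, not a silent zero.
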