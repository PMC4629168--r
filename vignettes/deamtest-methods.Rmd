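---
title: "Authenticating ancient DNA from 5' deamination profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating ancient DNA from 5' deamination profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamtest)
```

## The statistical model

Postmortem cytosine deamination in single-stranded overhangs leaves an
excess of C→T mismatches at the 5′ end of ancient reads. Writing $y_x$ for
the fraction of reference cytosines read as thymine at read position
$x = 1, \dots, 20$ (in read orientation, position 1 = first aligned base),
the damage signal is modelled as

$$ y_x \sim N e^{-\mathrm{rate}\, x}, $$

fitted by nonlinear least squares over the positions with a defined
frequency. The evidence for decay is summarised by a one-sided t-test on
the rate parameter: $t = \widehat{\mathrm{rate}} / \mathrm{se}$, with the
standard error taken from the Jacobian-based covariance of the
least-squares solution (residual variance on $n_\text{points} - 2$ degrees
of freedom), and the *goodness-of-fit p-value* is
$P(T_{df} > t)$. Small values indicate significant exponential decay — an
ancient-looking profile. The test is one-sided because only decay, not
growth, is evidence of deamination; a profile increasing with $x$ gets
$p \ge 0.5$ by construction.

Because a handful of reads carries too little information for this fit to
be interpreted on its own, the authenticity decision is made by reference
to an *empirical distribution*: the reference library (bona fide ancient,
or bona fide modern) is subsampled with replacement $M$ times at the size
$n$ of the test set, each subsample yielding one goodness-of-fit p-value.
In ancient mode the empirical p-value of the test is the fraction of
subsamples with a p-value greater than or equal to the test set's,
rejecting (when small) the null hypothesis that the test reads carry
damage comparable to or stronger than the reference. In modern mode the
count runs the other way. Both comparisons are inclusive, the resolution
is $1/M$, and a count of zero is reported as $< 1/M$ rather than being
given a pseudo-count.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_mapq` | 30 | minimum mapping quality (inclusive) |
| `min_length` | 30 bp | minimum aligned query length (inclusive) |
| entropy threshold | 50 | reads with trinucleotide entropy ≤ 50 are removed |
| `max_pos` | 20 | 5′ positions entering the fit |
| `M` | 10,000 | subsamples per empirical distribution |
| `n` | test-set size | subsample size (150 is the canonical small-set scale) |

The filtering defaults are the standard stack for sedimentary aDNA:
mapping quality and length filters, coordinate-based duplicate removal,
and a low-complexity filter. The entropy score is the Shannon entropy
(base 2) of the overlapping 3-mer frequency distribution, scaled by
$100/\log_2(\min(K, 64))$ with $K$ the number of counted 3-mer windows;
3-mers containing N are not counted. This trinucleotide dialect is a
declared convention of this package — entropy filters in common
preprocessing tools exist in several variants, and the boundary
("less than or equal to the threshold is removed") follows the filter's
customary phrasing.

## The simulator: what it emulates and what it does not

`simulate_reads()` draws reads of truncated-normal length (mean 55 bp,
sd 12, hard minimum 30 bp to respect the mapping-length filter) at uniform
positions and strands from an i.i.d. random reference, then applies two
substitution channels:

* **deamination**: each reference C at read-orientation position $x$
  becomes T with probability $a e^{-r x} + \text{baseline}$;
* **sequencing error**: each base is replaced by a uniformly chosen other
  base with probability `seq_error` (so the error leak into the C→T
  channel is `seq_error`/3), strand-symmetric and position-independent.

The canonical "ancient-like" library uses $a = 0.15$, $r = 0.3$,
baseline 0.005 — first-base damage around 11–12%, in line with strongly
damaged archaeological samples — and the "modern-like" library sets
$a = 0$, keeping only the flat baseline. Default sequencing error is
0.002, a typical Illumina substitution rate. Reverse-strand reads are
stored in reference orientation exactly as a SAM file would, so the
counting code's strand handling is exercised, not bypassed.

Deliberately *not* modelled: fragment-end overhang biophysics (nick-based
models), the 3′ G→A mirror channel (library-protocol dependent; the test
uses the 5′ end only), indels, base-quality profiles, contamination
mixtures, and non-uniform genomic coverage. Passing simulation-based tests
therefore shows that the statistical machinery behaves as designed under
the stated generative model — it does not by itself validate behaviour on
real libraries with, say, heavy CpG methylation effects or reference
bias.

## Numerical choices

* **Optimizer.** Levenberg–Marquardt least squares (`minpack.lm`), start
  values $N_0 = \max(y)$, $\text{rate}_0 = 0.5$, with restarts at
  $\text{rate}_0 \in \{0.01, 0.1, 1.0\}$. The contract is the minimum of
  the residual sum of squares, not the algorithm; the test suite checks
  equivalence against an independent dense grid search with
  finite-difference standard errors to $10^{-3}$.
* **Non-convergence** (all restarts fail, or a singular Jacobian): the
  subsample contributes $p = 1$ and is counted in `n_failed_fits`. A
  profile on which no decay can be fitted is precisely "no evidence of
  ancient damage", and this is conservative toward modernity.
* **Perfect fits** (numerically zero residuals, SE $= 0$, t undefined):
  $p = 0$ if the fitted rate is positive *and* the amplitude is positive;
  $p = 1$ otherwise. The amplitude condition matters: an all-zero profile
  is fitted perfectly by $N = 0$ with the rate unidentifiable, and must
  not count as perfect decay.
* **Undefined positions** (no reference C observed) are dropped from the
  sum, never imputed; the degrees of freedom follow the retained point
  count. Fewer than two defined points is an error.
* **x convention.** Positions are numbered $1..20$; a $0..19$ convention
  would rescale the amplitude but barely move the rate's t-test.
* **Ties and seeds.** Duplicate removal keeps the highest-MAPQ read per
  (reference, start, end, strand) key, ties broken by lexicographically
  smallest read id, so output is deterministic. Every stochastic function
  takes one seed; internal stages derive child seeds deterministically, and
  the caller's RNG state is restored afterwards.

## Design decisions

* **Subsample unit** is the alignment record, drawn uniformly with
  replacement — the resampling mirrors drawing read sets of the size
  actually observed, and the reference distribution at a given size is a
  fixed property of the reference library. `power_curve()` therefore
  builds one $M$-subsample distribution per size and scores all test
  repetitions against it, rather than rebuilding it per repetition.
* **Duplicate handling** replaces consensus-building deduplicators with
  coordinate-key dedup: consensus construction is a separate tool's
  contract and does not materially change the damage statistic.
* **No base-quality threshold** is applied by default (none is part of
  the standard workflow this package follows); reads aligned over
  reference N are kept in the set but contribute nothing to C→T counts.
* **Whole-set test statistic.** The test set's goodness-of-fit p-value is
  computed from all its reads at once; the subsample size of the reference
  distribution is matched to the test-set size unless overridden.

## Problem sizes used by the checks

The simulation-based checks run at desk scale, chosen to bound sampling
error without excess: libraries of 50,000 reads; power curves over sizes
100–1000 with 200 repetitions per size against 1,000-subsample
distributions; calibration on 2,000 subsamples of 500 reads from a
zero-amplitude library; parameter recovery over 20 replicates of 50,000
reads. At these sizes the binomial standard error on a 5% rejection rate
is about 0.5%, and the observed behaviours (type-I rate ≈ 3.5–5%, median
empirical p below 0.05 for all sizes above 300 when testing damage-free
reads against a damaged reference) are stable across seeds.

One caveat found analytically and worth knowing: with a nonzero flat
baseline the pure-exponential model is misspecified, and the fitted rate
is deterministically biased low (fitting
$0.15 e^{-0.3x} + 0.0057$ gives rate $\approx 0.25$, about 17% under the
generating value). Parameter-recovery checks therefore run with
baseline 0, where the model is well specified and the fitted rate is
unbiased; fits on baseline-contaminated profiles are checked against the
wider ±20% band that the misspecification warrants. This bias affects the
*rate estimate*, not the *test*: the goodness-of-fit p-value remains a
monotone summary of decay evidence, and the empirical comparison is
between like-for-like fits.

## Known limitations

* The test compares damage signal only; it cannot distinguish an ancient
  sample from a modern one spiked with ancient-like damage, nor detect
  contamination that is itself ancient.
* Reference libraries must be honestly labelled: an "ancient" reference
  with weak damage makes the ancient-mode test lenient (the empirical
  p-value of a test set rises with the reference's own goodness-of-fit
  p-value).
* Very small test sets (tens of reads) yield wide empirical p-value
  distributions; the power analysis (`power_curve()`) should accompany any
  negative claim.
* MD-tag reconstruction trusts the aligner's tags; with neither MD tags
  nor a reference FASTA, affected records are rejected by name.
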