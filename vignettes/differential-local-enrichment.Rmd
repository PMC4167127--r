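---
title: "Local and differential local motif enrichment: the model behind motifzoom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local and differential local motif enrichment: the model behind motifzoom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifzoom)
```

## The problem

ChIP-seq peak regions and promoter windows, aligned on a common anchor (the
peak center or the transcription start site), concentrate functional
transcription-factor binding sites at preferred positions: the assayed
factor's motif piles up near the center of peak windows, and co-factor motifs
often occur at constrained offsets. motifzoom asks two questions about a
compendium of known motifs (position weight matrices, PWMs) and one or two
sets of equal-length sequences:

1. **Local enrichment** — in which sub-region of the aligned sequences are a
   motif's best matches concentrated, and how significantly?
2. **Differential local enrichment** — is that concentration stronger in a
   primary set than in a control set (e.g. treated vs. untreated cells)?

## The model

### Best-match scanning

Each motif is converted to a log-odds scoring matrix in bits against a
0-order background. For each sequence we keep at most one site: the
maximal-scoring window over all starts and (for DNA) both strands, and only
if it reaches a score threshold. Sequences with no qualifying match are
ignored. With sequences of length $L$ and a motif of width $w$ there are
$N = L - w + 1$ possible start positions; we count forward-strand starts once
regardless of strand mode, and index a minus-strand site by its leftmost
forward-strand base, so the trial space below does not depend on the strand
mode.

Tied maximal windows are broken uniformly at random under a caller-supplied
seed. A leftmost rule would bias the positional distribution toward the 5'
end; the random rule is unbiased and reproducible per seed. As a consequence,
per-sequence results are deterministic given the seed and the scan order, and
scores (but not tie-broken positions) are invariant under permutations of the
input records.

### The binomial sub-region test

A sub-region is a span of $M$ consecutive start positions out of $N$. Under
the null hypothesis that a best site lands uniformly on the $N$ starts, it
falls in the sub-region with probability $r = M/N$. If $S$ sequences have a
best match and $s$ of those fall in the sub-region, the enrichment p-value is
the binomial upper tail

$$p' = \Pr(X \ge s), \qquad X \sim \mathrm{Binomial}(S,\, r),$$

evaluated in log space so that extreme significance keeps a usable magnitude.

Candidate sub-regions come in two modes. **Central** mode tests only
sub-regions exactly centered in the sequence (widths sharing the parity of
$N$), matching the assumption that ChIP-seq peak windows center the true
binding sites; it is linear in $L$. **Local** mode tests sub-regions of every
width in a grid at every feasible start, which is quadratic in $L$ but
sensitive to off-center concentrations (e.g. positioned elements upstream of
a TSS).

### Multiple tests, E-values

Testing $n$ sub-regions inflates the best p-value. Treating sub-regions as
independent — conservative, because overlapping sub-regions are strongly
positively correlated — the adjusted p-value is

$$p = 1 - (1 - p')^{\,n},$$

computed with `log1p`/`expm1`; when $p'$ is so small that $(1-p')^n$ loses
all precision we switch to the exact-to-first-order $p \approx n p'$ regime,
so the natural-log column in reports stays finite and informative far below
the double-precision underflow point. The motif's E-value multiplies $p$ by
the number of motifs in the compendium; its ceiling is the compendium size.

When the score threshold is optimized per motif (candidates are the distinct
observed best scores, thinned to at most 100 by quantiles), the search is
accounted for by multiplying $n$ by the number of candidates evaluated. The
method's description leaves this accounting open; we chose the conservative
product rather than ignoring the search.

A motif can be significant in several overlapping sub-regions. Reported
sub-regions are selected greedily: sort significant candidates by increasing
raw p-value (ties: smaller width, then smaller start — a deterministic
ordering), and emit each unless it overlaps an already-emitted one. Central
mode reports the single best sub-region. The default reporting gate,
E-value $\le 10$, follows a report-many/filter-later philosophy; note that it
only bites when the compendium is large (with $k$ motifs it corresponds to
$p \le 10/k$).

### The differential test

Differential analysis only examines sub-regions significantly enriched in
the *primary* set — enrichment in the control alone is not evidence about
the primary condition. For each such sub-region we form the 2x2 table of
best matches inside ("success") and outside ("failure") the sub-region in
the two sets and compute the two-sided Fisher exact test: the sum of the
hypergeometric probabilities of all tables (margins fixed) at most as
probable as the observed one, with a $10^{-7}$ relative slack for
floating-point ties. Fisher p-values are adjusted with the *same* $n$ as the
enrichment test and multiplied by the compendium size ("Fisher E-value").
The odds ratio $(ad)/(bc)$ is reported as the effect size, with the
Haldane–Anscombe $+0.5$ correction applied to all cells only when some cell
is zero.

A motif with *no* sub-region passing the enrichment gate carries no
differential evidence; its report row carries an adjusted Fisher p-value of
1 and a Fisher E-value at the ceiling (the compendium size) rather than a
missing value. This mirrors how paired ChIP-seq analyses behave in practice:
in the direction where the known motif is not locally enriched, its Fisher
E-value sits at the maximum.

We deliberately do *not* choose the sub-region by optimizing the Fisher
statistic itself: the enrichment-first construction avoids the degenerate,
extremely narrow sub-regions that a Fisher-optimizing search produces.
One-sided Fisher variants are likewise out of scope.

### Control suitability

For paired experiments on the same factor, differential enrichment of a
co-factor motif in A over B is only interpretable if experiment B was not
simply less efficient. The protocol: test the *known* motif of the assayed
factor in both directions. If A-vs-B gives a Fisher E-value $\ge 1$, B is a
safe control; if B-vs-A gives one below 0.05, A is not. E-values between
0.05 and 1 are reported as inconclusive — the protocol's "much larger than
1" is operationalized as $\ge 1$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| score threshold | 5 | bits | conventional fixed default; or optimized per motif |
| pseudocount | 0.1 | counts | spread over the background; keeps log-odds finite |
| effective nsites | motif's `nsites`, else 100 | sites | weights the pseudocount |
| sub-region width grid | 10 to $N$ step 5 | start positions | bounds $n$ and runtime in local mode while covering the space; full enumeration via `min_width = 1, width_step = 1` |
| reporting gate | E-value $\le 10$ | — | report-many, filter-later |
| background | estimated from the data, strand-symmetrized, floored at $10^{-3}$ | — | both strands are scanned; the floor keeps log-odds defined |
| curve smoothing | 11 | bp (odd) | display only; raw histogram kept alongside |

## What the synthetic generator emulates — and what it does not

`generate_background_set()` draws i.i.d. letters; `plant_motifs()` gives each
sequence one site with a set occupancy, sampling site letters from the PWM so
planted score distributions are realistic, with uniform, Gaussian
(clipped by resampling, not truncation, to avoid artificial edge pile-ups)
or fixed placement, on either strand. `make_paired_fixture()` builds the
paired designs used throughout the tests: `differential-central` (primary
Gaussian $\mu = 0$, $\sigma = 30$ bp; control uniform; occupancy 0.6 in both,
500 sequences of 500 bp — the scale of a typical ChIP-seq peak-set
analysis), `null`, and `swapped`.

Passing tests on these fixtures show that the statistics do what they claim
under the stated model: i.i.d. backgrounds, at most one planted site per
sequence, independent sequences. Real peak regions violate all three —
repeats and CpG islands structure the background, sites cluster, peaks
overlap — so fixture results validate the machinery, not biological recall
on any particular dataset.

## Numerical and design choices

* Binomial tails via `stats::pbinom` (log space); exactness is verified
  against direct pmf summation for all $S \le 200$ in the test suite.
* The Fisher summation uses `stats::dhyper` log-probabilities; R's
  `fisher.test` serves as an independent cross-check in tests, not as the
  implementation, because the tie convention (relative $10^{-7}$ slack) is
  part of the method's definition here.
* $-\infty$ log-odds (zero probability at zero pseudocount) are stored as a
  $-10^{30}$ sentinel; windows containing `N` score the sentinel, so they
  can never beat a clean window but arithmetic stays finite.
* Sub-region coordinates are reported as `region_center` (bp, relative to
  the sequence center: $\mathrm{start} + (M-1)/2 - (N-1)/2$) and
  `region_width` ($M$, the number of start positions), matching how local
  enrichment tools present their output columns.
* Degenerate inputs: an all-ambiguous sequence can never yield a site; a
  motif with no qualifying matches is skipped with a message and reported at
  the E-value ceiling; an all-zero 2x2 table has Fisher p-value 1 by
  convention.
* The TSS proximity split measures the edge-to-point distance (0 inside a
  peak), so a TSS exactly at the radius is "bound".
* Report TSV numbers are serialized with 6 significant digits (scientific
  notation), counts as exact integers; `write -> parse -> write` is a fixed
  point.

## Problem sizes used by the checks

The packaged checks run the binomial oracle over every $S \le 200$, the
Fisher oracle over 10,000 random tables with totals up to 40, the null
calibration at 10,000 simulated motifs ($S = 100$, $N = 400$, local grid),
and the paired-design recovery at 20 replicate seeds per direction at the
full fixture scale (500 x 500 bp per set). The acceptance script
(`scripts/acceptance.R`) re-derives the same quantities at moderately
reduced simulation counts (printed as `n` in its output) so a complete run
stays under a minute.

## Known limitations

* The conservative independence adjustment over-corrects heavily when
  sub-regions overlap (the null calibration shows rejection rates far below
  nominal); ranks are unaffected, absolute adjusted p-values are
  conservative.
* No sequence weighting, no bin smoothing of counts before testing, and no
  higher-order background models.
* The per-sequence best-match model ignores secondary sites; a motif with
  many weak occurrences per sequence is summarized by one site only.
* Local mode's default width grid trades exhaustiveness for runtime; with
  `width_step > 1` the greedy selection can report slightly different
  boundaries than a full enumeration would.
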