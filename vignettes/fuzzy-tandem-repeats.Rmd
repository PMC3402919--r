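---
title: "Detecting fuzzy amino-acid tandem repeats"
author: "fuzzytr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fuzzy amino-acid tandem repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzytr)
```

Tandemly repeated units in protein sequences often fold into stacked
structural elements, and proteins keep the fold long after the copies have
diverged far beyond easy recognition.  Detecting such *fuzzy* tandem repeats
(FTRs) from sequence alone therefore needs a notion of approximate copy
identity that understands amino-acid substitutability, not just literal
matches.  This vignette describes the model the package implements, the
parameters that matter, how candidates are generated and validated, what the
synthetic-data generator emulates, and where the method's limits are.

## The weighted metric

A similarity matrix (BLOSUM family) is converted into substitution costs

$$C_{ij} = \frac{D_{ij}}{D_{\max}}, \qquad
  D_{ij} = M_{ii} + M_{jj} - 2M_{ij},$$

so that $C_{ii} = 0$, costs are symmetric, and the most dissimilar residue
pair costs exactly 1.  Indels cost 1.  The weighted edit distance
$d(a, b)$ is the minimum total cost of an edit script between two residue
strings; with a unit-cost matrix it reduces to the classical Levenshtein
distance.  These costs are *near*-metric: `triangle_inequality_audit()`
scans all residue triples and reports the rare violations, which is worth
knowing when reasoning with triangle-inequality arguments but does not
affect the detector itself.

The divergence budgets below scale with $E_C$, the expected cost of a
substitution.  We define it conditionally on the two residues differing,

$$E_C = \frac{\sum_{i \ne j} p_i p_j C_{ij}}{\sum_{i \ne j} p_i p_j},$$

so that the unit-cost matrix gives $E_C = 1$ exactly and the weighted
budgets reduce to the classical "fraction of mismatches" budget.  The
background $p$ defaults to uniform over the 20 canonical residues — the
reproducible choice; a composition-derived background is available via
`tr_config(background = "sequence")`, and a Monte-Carlo estimator
(`expected_substitution_cost(..., method = "monte_carlo")`) audits the
closed form.  For BLOSUM50 with the uniform background $E_C \approx 0.48$.

## The repeat definition

A span decomposed into units $x_1 x_2 \cdots x_t$ ($t \ge 2$) is a valid
weighted Steiner tandem repeat at error level $\mu \in [0,1]$ and pair
constant $c \in [1,2]$ when

* **(a)** consecutive copies stay close:
  $d(x_i, x_{i+1}) \le c\,\mu\,|x_i|\,E_C$ for every $i$, and
* **(b)** a consensus (Steiner) string $\bar x$ exists with
  $d(\bar x, x_i) \le \mu\,|x_i|\,E_C$ for every $i$.

Condition (a) is normalized by the first unit of each pair, exactly as
defined, and becomes vacuous for $\mu \ge 1/c$.  Defaults are $\mu = 0.3$
and $c = 1.5$; $c = 2$ is the loose setting appropriate for low-divergence
repeats (where (a) follows from (b) by the triangle inequality).  A
fractional trailing or leading unit is admitted and checked pro-rata
against the matching end of $\bar x$.  Reported repeats must span at least
6 residues and at least 2 copies.

Finding a true Steiner string is intractable, so the package certifies
condition (b) with a column-wise minimum-cost consensus over a center-star
alignment of the units (the center is the unit closest to all others).  Any
certificate satisfying (b) proves existence, so the approximation can only
under-report, never over-report.  The practical gap is small: on short
strings where the Steiner condition can be checked by exhaustive
enumeration, the certificate agrees with the enumeration on all clear-cut
cases (see the validation tests).

## Candidate generation

Scanning every (period, position) pair is hopeless; candidates come from a
seeded scan:

1. **Gapped q-gram probes.**  The complete family of 3-grams with span 2-4
   (`tr_shapes()`, six shapes) probes every position; two grams match when
   at least two sampled positions are identical and the remaining residues
   are mutually within similarity rank $z$ of each other ($z = 1$ exact;
   3 and 5 admit conservative substitutions).  Each probe records the
   distance to its next $h = 5$ matching occurrences.  The degenerate
   (2,1)-seed `##` is implemented but disabled by default: with only two
   sampled positions its homology test collapses to exact equality of a
   residue pair, and the complete 3-gram family is the documented
   six-seed default.  An X never matches any gram (including itself) and
   costs the maximal substitution in the distance.
2. **Anti-smear weighting.**  Indels between matching probes perturb the
   detected distance, smearing the period histogram.  Each detected period
   $k_g$ is credited with $\sum_{k \in Q} 2^{-|k_g - k|}$ against a queue
   $Q$ of the last $H = 20$ detected distances, evaluated before the
   probe's own values are enqueued (making the update order-independent
   within a probe).  The queue starts empty at each block and simply keeps
   the most recent $H$ values.
3. **Multiplicity weighting.**  Multi-copy repeats also match at integer
   multiples of their period, so $w_1(k) = \sum_{m \ge 1} w_0(mk)$, summed
   over observed periods only.  The top $L = 50$ periods by $w_1$
   (ties to the smaller period) go forward.
4. **Positional k-density.**  For each retained period, the positions of
   contributing probes (first probe of each hit whose period is a multiple
   of $k$, counted once) are smoothed with a $k$-window sum $F$; windows
   with $F$ at or above $\alpha \cdot \mathrm{mean}(F)$ (default
   $\alpha = 1$; the mean over all windows, empty ones included) become
   candidate start positions.  A window must also contain at least one
   contributing probe — the reading under which an empty contributor set
   yields no candidates.  Consecutive passing positions are coalesced to
   the first of each run, plus the first actual probe position inside the
   run: the run start is a window coordinate and can precede the repeat,
   which matters when budgets are tight.

Long sequences are scanned in blocks of 2000 residues overlapping by half
a block, which keeps the quadratic probe scan local; unit extension (next
section) deliberately runs over the full parent sequence, so repeats
crossing block borders are still recovered in full, and repeats found from
two overlapping blocks collapse in the enclosure filter.  For sequences
shorter than a block, blocking is a no-op and the result is identical to a
single giant block.  Across very different block granularities the same
repeats are recovered, though block-local weighting can shift a reported
boundary by a few residues.

## Validation

Each candidate $(k, i)$ seeds a unit at $[i, i+k-1]$ and grows it one unit
at a time, rightward then leftward (leftward growth runs the same code on
the reversed sequence; edit distance is reversal-invariant).  At each step
one prefix DP row gives the distance of the current consensus to every
candidate unit end within $\max(2, \lceil \mu p \rceil)$ of the consensus
length; the best end is accepted while its distance stays within
$c\,\mu\,|x|\,E_C$ times a growth slack of 1.2, and the consensus is
re-derived after every acceptance.  The growth gate deliberately uses the
*pair* budget of condition (a) rather than the per-unit budget of (b):
early in growth the consensus is dominated by the previous unit, so the
measured distance behaves like a copy-to-copy distance, and gating at the
tighter per-unit budget truncates valid arrays at their first moderately
divergent copy.  Final acceptance is never slackened.

The greedily grown boundaries then get three refinements:

* **Wraparound re-segmentation.**  The full-unit region is globally
  aligned against the unrolled consensus $\bar x^m$ (the copy count $m$
  chosen by minimum cost), and unit boundaries are reset to the alignment's
  wrap points.  Greedy growth accumulates indel drift; alignment-optimal
  boundaries noticeably lower unit-to-consensus distances.  Two rounds of
  re-segmentation and consensus refinement are applied (regions too large
  to segment within a fixed memory budget skip this step).
* **Strict verification with end-trimming and splitting.**  Conditions (a)
  and (b) are re-checked with no slack.  A violating terminal unit is
  dropped; a violating interior unit splits the array and the longer valid
  side is kept (the shorter side is typically re-derived from its own
  candidate).  Fractional units failing their pro-rata check are dropped.
* **Harmonic re-probing.**  A repeat whose base-period decomposition
  breaks at one locally divergent copy can still be valid at two to four
  times the period — longer pseudo-units average the divergence out — so
  accepted repeats are re-seeded at small multiples of their period around
  their boundaries.  This mirrors, at validation level, what multiplicity
  weighting does at scan level, and it is why reported repeats sometimes
  carry a longer period and lower copy number than the generating unit:
  the longer-span decomposition is preferred whenever it validates.

Finally, repeats completely enclosed in another are removed; among repeats
with identical span the shortest period wins; and shifted re-readings of
one locus (same period, spans overlapping by more than half of the
shorter) collapse to the longest span.  Reported fields are
the 1-based inclusive span, period (consensus length), fractional copy
number (span/period, 1 decimal), consensus string, and mean unit divergence
$\frac{1}{t}\sum_i d(\bar x, x_i)/(|x_i| E_C)$ — divergence 1.0 means the
units sit exactly at the budget.

Numerical details: costs are compared with an absolute tolerance of
$10^{-9}$; consensus column ties break to the alphabetically first residue;
period ties in ranking break to the smaller period; all steps are
deterministic, so identical input and configuration give identical output.

## Synthetic data and what the tests show

The generator builds three kinds of material:

* `random_protein()` draws i.i.d. residues from a long-run proteome-average
  composition (UniProtKB-style frequencies) — or any supplied composition.
* `shuffle_sequence()` permutes a sequence uniformly, preserving its
  residue multiset exactly.  Shuffles of real (or composition-realistic)
  sequences are the control material: anything the detector reports there
  is false structure.
* `generate_planted_tr()` implants `copies` tandem copies of a unit into a
  random background, each copy independently mutated — substitutions at a
  per-position rate with the replacement drawn from the background
  composition (never the original residue), indels at a per-position rate,
  insertion residues from the composition.  Ground-truth span and realized
  mutation counts are returned for recovery scoring.

Composition-random substitution is a deliberately adversarial model of
divergence: real fuzzy repeats diverge mostly through conservative,
matrix-favoured substitutions, which cost far less under the weighted
metric.  One consequence, verified directly in the test suite, is that
arrays mutated at 15-20% composition-random substitution regularly contain
copies whose weighted distance exceeds the $\mu = 0.3$ budget — such arrays
are *not* valid repeats under the definition, and the maximal valid
sub-repeat is the correct answer.  The recovery experiments therefore run
under the unit-cost metric, where a substitution costs exactly 1 and the
budget has the same meaning the mutation rate does; there the detector
recovers $\ge 90\%$ of the planted span in well over 90% of fixtures, while
100 shuffled controls of 400-1000 residues never yield a repeat longer
than 20 (mean longest around 8, consistent with detection thresholds of
14-20 used for corpus summaries).  Passing these tests shows the machinery
is correct and calibrated on composition-matched randomness; it does not
by itself demonstrate sensitivity to the conservative divergence patterns
of real protein families, which is what the BLOSUM metric and $z > 1$ are
for.

## Significance testing

`wilcoxon_shuffle_test()` pairs every input sequence with one
composition-preserving shuffle, runs the detector on both, and feeds the
longest-repeat lengths to a one-tailed Wilcoxon signed-rank test
(alternative: originals longer).  Lengths are floored at the 6-residue
reporting limit; pairs where neither run reports anything are ties and are
excluded, and zero differences after flooring are dropped as standard
signed-rank zero-differences (the floor makes "nothing found" and "6-residue
repeat found" indistinguishable, which is the conservative direction).
Per-pair shuffle seeds derive from the master seed by a fixed counter
scheme, so runs reproduce exactly.  `parameter_sweep()` reproduces the
tuning experiment: mean longest reported repeat on shuffled material as a
function of $\mu$, $c$ and $z$ — the false-structure ceiling detection
thresholds must clear; it grows with both $\mu$ and $c$.

## Problem sizes

The shipped experiments are sized for a single CPU: recovery and control
experiments use 100 sequences of 600-1000 residues; significance replicates
use corpora of 8 sequences of 250 residues (the signed-rank test's minimal
attainable one-tailed p with 8 untied pairs is $2^{-8} \approx 0.004$,
comfortably below 0.05).  All sizes are plain function arguments and scale
up directly.

## Known limitations

* The consensus is a center-star certificate, not an optimal Steiner
  string; a repeat whose only valid consensi are far from every unit could
  be missed (rare in practice, impossible to enumerate exactly).
* Candidate generation is heuristic: a period outside the top-$L$ list or
  a start position in a low-density window produces no candidate.  The
  harmonic re-probe recovers the common cases.
* Overlapping non-nested decompositions of one region at *different*
  periods (e.g. the same array read at $p$ and at $2p$ with a shifted
  start) are all reported when none encloses another; only same-period
  shifted duplicates are merged.  Consumers wanting strictly one row per
  locus should group by overlap.
* Condition (a) is enforced exactly as written (normalized by the first
  unit of each pair, not symmetrized); with strongly varying unit lengths
  the pair budget is therefore slightly asymmetric.
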