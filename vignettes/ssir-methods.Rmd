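---
title: "Superposing significant interaction rules: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superposing significant interaction rules: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssir)
```

## The model

SSIR ranks samples of a two-class library described by categorical
fingerprints — strings of symbolic levels such as the absent/marginal/present
(A/M/P) detection calls of microarray platforms. Its building block is the
*rule*: a conjunction that fixes the level at `k` descriptor positions
(order-`k`), each selector either positive (`pos:LEVEL`) or negated
(`pos:!LEVEL`, any level but this one); all other positions are wildcards.
A rule *covers* the samples satisfying every selector.

Coverage is scored with the urn model. The library holds `a` samples, `b` of
the interest class; a rule covers `c` samples of which `d` are of interest.
Under the null that the rule draws samples at random,

$$P(d, c; b, a) = \frac{\binom{b}{d}\binom{a-b}{c-d}}{\binom{a}{c}},$$

with support $\max(0, c+b-a) \le d \le \min(b, c)$, mean $cb/a$ and variance
$bc(a-b)(a-c)/(a^2(a-1))$. The rule's significance is the upper tail

$$p(d^{+}, c; b, a) = \sum_{i=d}^{\min(b,c)} P(i, c; b, a),$$

small when the rule is enriched in the interest class; the lower tail
$p(d^{-})$ is small when the rule *avoids* the interest class, and by the
duality $p(d^-, c; b, a) = p([b-d]^+, a-c; b, a)$ a depleted rule is the
mirror image of its complement's enrichment.

Training enumerates every canonical rule of the requested orders, skips
rules covering no sample, and admits each rule with $p(d^+) \le p_c$ (vote
$+1$) or $p(d^-) \le p_c$ (vote $-1$) into the pool. Since
$p(d^+) + p(d^-) \ge 1$, no rule earns both votes while $p_c < 0.5$. A
sample's score is the sum of votes of all covering pool rules — the
superposition — and the scores rank training and external samples alike.
Descriptors appearing in many selected rules are flagged by
`descriptor_votes()`, which is how the method doubles as a variable
selector.

### Assumptions

* The a-priori-random-draw null treats the systematic rule generator as an
  exchangeable sampler of subsets; p-values are raw, not adjusted for the
  millions of rules inspected. The cutoff `p_c` is instead calibrated by
  validation (leave-one-out, label randomization), which is the method's
  deliberate stance rather than an oversight.
* Votes are unit-valued. The pool is a simple voting procedure; no p-value
  weighting or calibration of scores into probabilities is attempted.
* Rules selecting identical sample subsets are *not* deduplicated before
  voting: the pool is the raw set of significant rules, which is what the
  published rule counts reflect.

## Parameters that matter

* `p_c` — the admission cutoff, $0 < p_c < 0.5$. Shrinking it can only
  remove rules (selection is monotone), making the pool more demanding but
  eventually spurious when only a handful of rules survive. It is the main
  dial, swept over powers of ten in practice (`ssir_cli("sweep", ...)`).
* `orders` — rule orders to enumerate, usually 1–2; exhaustive order-3+ is
  combinatorially explosive (`count_rules()` before you enumerate). The
  Monte Carlo mode (`mode = "sample"`) draws rules uniformly from the
  canonical space when exhaustion is infeasible.
* threshold for confusion metrics — a sample is called positive when its
  score exceeds 0, the neutral point of a ±1 vote sum; configurable in
  `ssir_auroc()`.

## Canonical rule space and counting

On a two-level position the negated selector is rewritten as the other
level, so a binary position offers 2 canonical selectors; an m-level
position (m ≠ 2) offers 2m (each level, plain and negated). The order-k
count is the k-th elementary symmetric polynomial of the per-position
selector counts — for all-binary schemas $\binom{n}{k}2^k$, e.g. 26,564,760
order-2 rules over 3645 binary descriptors. Alphabets are the levels
*observed* per descriptor (or declared explicitly), so a three-level
platform whose descriptor shows only two levels contributes like a binary
one; this "observed levels" convention is the package's fixed choice where
published order-1 counts are ambiguous. Enumeration order is lexicographic
(positions, then levels, then negation), so runs and logs are reproducible.

## Numerical choices

* Floating-point probabilities go through log-gamma binomials
  (`lchoose`), and each tail sums its shorter side, complementing for the
  longer one, so accumulated rounding stays near machine precision; the
  suite checks agreement with `stats::phyper` and with exact enumeration to
  1e-12 (absolute, for identities involving cancellation).
* The exact-rational mode reproduces printed fractions (20/63, 5/126,
  45/126) verbatim. It uses exact integer arithmetic in doubles —
  Pascal-triangle binomials and Euclid GCD — and is valid whenever
  $\binom{a}{c} < 2^{53}$ (libraries up to ~55 samples); larger problems
  use the float mode.
* Tails are total and monotone in `d`: below the support minimum the upper
  tail is 1, above the maximum 0. This keeps rule scoring free of edge
  cases; zero-coverage rules have both tails 1 and are skipped.
* Ranking ties break by input order; the ROC uses mid-rank AUC (the
  Mann–Whitney statistic), so all-tied scores give exactly 0.5.
* Missing cells satisfy no selector, positive or negated: missing data
  never contributes evidence to a rule. Unseen external levels fail
  positive selectors and satisfy negated ones, the set semantics of
  negation.
* MCC is reported as 0 when its denominator vanishes; precision is `NA`
  when nothing is called positive.

## Validation protocols

**Leave-one-out** repeats the entire training per fold: on the remaining
`a − 1` samples, `b` and every rule's `c`, `d`, tails and votes are
recomputed before the held-out sample is scored. The default
`"incremental"` method caches each rule's full-data coverage — coverage
does not depend on labels — and retains a rule for fold reuse only if some
single-sample removal could push a tail under `p_c`, checked exactly over
the four reachable count states $(b\!-\!y_i,\, c\!-\!m_i,\, d\!-\!m_i y_i)$
with $a-1$. The result is bit-identical to `"naive"` from-scratch
re-enumeration, which the suite asserts on twenty random libraries; this
equality is the module's central correctness contract.

**Label randomization (Y-scrambling)** permutes the training labels
(class counts preserved), retrains, and records the training AUC (against
the shuffled labels) and the external AUC (against untouched external
labels) per shuffle. Because coverage is label-free, each shuffle
re-derives counts, tails and votes from the cached coverage — exactly the
from-scratch model, also asserted by test. A Gaussian fitted to the
shuffled external AUCs yields the true model's z-score and upper-tail
normal p. One master seed spawns per-shuffle substreams, so runs
parallelize reproducibly; an `include_identity` flag lets the true point be
reproduced as shuffle 1.

## The synthetic generator

`ssir_plant_spec()` / `ssir_simulate()` emulate categorical call matrices
with known ground truth: labels drawn to a fixed balance, background cells
i.i.d. from a per-descriptor level distribution, and planted rules whose
level pattern is imposed on target-class samples with probability
*penetrance*. By default the background at planted positions excludes the
planted level, so the pattern occurs iff imposed: penetrance 1 gives a
perfectly separating rule (held-out AUC 1), penetrance 0 removes the
planted level entirely and the library is pure noise (held-out AUC ≈ 0.5).
This makes penetrance the single, analyzable signal dial consistent with
the urn model; set `background_excludes_planted = FALSE` to let patterns
also arise by chance in either class.

Defaults are 40 samples, 30 binary (A/P) descriptors, balance 0.5, one
order-2 planted rule at penetrance 1 — a size at which every fold of
leave-one-out retains the planted structure and the whole pipeline runs in
seconds. What the generator does *not* emulate: continuous intensities and
the call-generation step, within-class correlation structure between genes,
and batch effects. Tests passing on planted data therefore demonstrate the
machinery's correctness, not performance on real transcription data.

Test and validation problem sizes used throughout the suite — identity
grids up to `a = 40`, twenty random libraries of 10–14 samples for the
leave-one-out equality, 200 shuffles for the randomization check — are the
package's chosen desk-scale study conditions; the algorithms themselves
have no such limits.

## Known limitations

* Exhaustive enumeration beyond order 2 (or order 2 over tens of thousands
  of descriptors) is infeasible in memory-resident form; use
  `count_rules()` first and the sampling mode where needed. The match-matrix
  implementation favors clarity and exactness over the bit-packed coverage
  of a large-scale implementation.
* Raw `p_c` means the pool's size, not its family-wise error, is
  controlled; interpret single-rule p-values only comparatively.
* The exact-rational mode is bounded by double-precision integer range
  (`choose(a, c) < 2^53`).
* Scores are integer vote sums; heavily tied rankings are resolved by input
  order, which matters only for small pools.
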