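---
title: "Representative and statistically significant shapelet mining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representative and statistically significant shapelet mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s5m)
```

## The problem

Temporal biomarker discovery looks for short, recurring subsequences of
longitudinal measurements — *shapelets* — whose occurrence in a patient's
series is statistically associated with a binary phenotype (say, in-ICU
mortality, or onset of sepsis). Two failure modes plague the naive
approach of testing every sliding window:

1. **Multiple testing.** A dataset of $n$ series of length ~$m$ induces
   on the order of $n\,m^2$ candidate windows, each tested at up to $n$
   distance thresholds. Uncorrected, nearly everything is "significant";
   Bonferroni-corrected, nearly nothing is.
2. **Redundancy.** Windows overlapping a genuine marker by one or two
   points are nearly as significant as the marker itself, so the
   significant set contains thousands of near-copies — useless for a
   clinician and statistically wasteful, since every copy inflates the
   correction factor.

This package mines shapelets that are *simultaneously* significant and
structurally representative: a streaming submodular optimizer classifies
each candidate as representative or redundant, and only representatives
count toward the multiple-testing correction.

## Model and procedure

**Distance and prediction.** For sequences $r$ (shorter) and $s$
(longer), $\mathrm{dist}(r,s)$ is the minimum over all alignments of the
Euclidean norm of the pointwise difference (`min_euclidean_distance()`).
A shapelet is a pair $(s, \theta)$; it predicts label 1 for series $t$
iff $\mathrm{dist}(s, t) \le \theta$. No z-normalization is applied:
the package targets data like severity scores and vital signs whose
absolute level is meaningful. Windows use 0-based, half-open
coordinates.

**Significance.** For a candidate $s$, the *minimum p-value*
$p_{\min}(s)$ is the smallest $\chi^2$ (1 df, no continuity correction
by default; a Yates flag exists) independence p-value over all
thresholds induced by the observed distances $\{\mathrm{dist}(s,t^i)\}$.
Degenerate splits (an empty prediction margin) are defined to have
$p = 1$: no split, no evidence. Ties in $p$ go to the smallest
threshold. Bonferroni divides the target FWER $\alpha$ by
(candidates × thresholds); Tarone's correction instead finds the
largest $\delta = \alpha/k$ such that at most $k$ candidates have
$p_{\min} < \delta$, discounting untestable candidates. Testability is
assessed on the observed minimum p-value; see *Limitations* for what
this costs under a continuous-valued null.

**Representativeness.** Similarity is
$\mathrm{sim}(r,s) = (1+\mathrm{dist}(r,s))^{-1} \in (0,1]$. A
representative subset $R$ of a ground set $S$ is scored by the mixture

$$f_\lambda^S(R) \;=\; \lambda_{\text{mix}}\, f_{fl}^S(R)
  \;+\; (1-\lambda_{\text{mix}})\, f_{sr}^S(R)
  \;+\; \lambda_{\text{size}}\, |R|,$$

where the *facility location* $f_{fl}$ is the mean over $s \in S$ of the
best similarity to $R$ (coverage; monotone, submodular; the empty max is
0), and the *sum redundancy* $f_{sr}$ is the total pairwise similarity
over $S$ minus that within $R$ (diversity; monotone decreasing,
submodular). Both pair sums range over ordered pairs *including*
self-pairs — the cheapest convention to maintain incrementally, and the
one under which $R = S$ gives exactly 0.

**The size term's sign.** The objective is sometimes described as
penalizing larger subsets, which suggests $-\lambda_{\text{size}}|R|$.
With the self-pair convention above, however, the redundancy term
already charges $(1-\lambda_{\text{mix}})$ for every admitted item
before any pairwise similarity is counted; at the defaults
$\lambda_{\text{mix}}=0.5,\ \lambda_{\text{size}}=1$ an *additional*
explicit penalty makes the marginal gain of even the first, perfectly
novel item negative ($0.5\,\Delta f_{fl} - 0.5 - 1 < 0$), so every
selector returns the empty set. We therefore keep the positive sign as
written: the diagonal of the redundancy sum is the effective per-item
penalty and $\lambda_{\text{size}}$ offsets it, leaving a net admission
budget. A `size_penalty` flag in `mixture_params()` flips the sign for
users who want the explicit penalty (with a smaller
$\lambda_{\text{size}}$).

A useful consequence of the default parameters: an item is admitted
roughly while its cumulative similarity to the current representatives
stays below
$(\lambda_{\text{size}} - (1-\lambda_{\text{mix}}))\,/\,(2(1-\lambda_{\text{mix}})) = 0.5$
(facility-location gains are normalized by the processed-set size and
become negligible as the stream grows). This is the mechanism that
bounds the returned set's cardinality — and also its resolution; see
*Limitations*.

**BIG, the streaming optimizer.** `big_step()` processes one item: it is
provisionally appended to the discard set $B$; the clipped gains of
(a) promoting it to $\hat R$ and (b) removing it again from $B$ are
computed against the current ground set $\hat R \cup B$, and the item
moves to $\hat R$ with probability $a^+/(a^+ + b^+)$ (0.5 if both
clipped gains vanish — in particular early on, when $B$ is nearly
empty). Two normalization details are deliberate choices where the
construction is ambiguous: the add-side gain is evaluated on the
post-append ground set (size $i{+}1$); the remove-side compares the
$(i)$-normalized mean against the $(i{+}1)$-normalized one, while both
redundancy totals refer to the current (post-append) ground set. The
incremental caches (per-item best similarity to $\hat R$ and to $B$,
plus running ordered-pair totals) make a step $O(i)$; their equality
with from-scratch recomputation is asserted, to $10^{-9}$ relative
tolerance, at every step of randomized test runs. The greedy and
bidirectional-greedy baselines evaluate the objective from scratch by
design — that cost difference is precisely what the streaming optimizer
removes, and the package's runtime comparison measures it.

**The interleaved loop.** `s5m_mine()` scores all candidates, sorts them
by $p_{\min}$ (stable on extraction order), and streams them through
`big_step()`. Non-representative candidates fall into $B$ and never
enter the testable count. After each admission the corrected threshold
is lowered to $\min(\hat\delta, \alpha/|\hat R|)$ (it never rises —
Tarone's threshold is monotone within a run; with $\hat R$ empty the
effective threshold is $\alpha$), and members whose $p_{\min}$ no
longer clears it are evicted to $B$, largest $p$ first, never to
return. The stream stops at the first candidate with
$p_{\min} \ge \hat\delta$; since the stream is sorted this early exit
provably returns the same set as scanning the remainder, and the test
suite checks that equivalence.

Four comparison pipelines share every component: representative
selection first then Tarone (`feature_selection_tarone`), Bonferroni
then selection (`bonferroni_submodular`), Tarone then selection
(`tarone_submodular`), and the interleaved loop with a random-threshold
representativeness rule (`s5m_threshold`, whose cutoff $\tau$ is drawn
uniformly per run).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | target family-wise error rate |
| `lambda_mix` | 0.5 | coverage-vs-diversity weight in $[0,1]$ |
| `lambda_size` | 1 | size-term weight (sign per `size_penalty`) |
| `window_lengths` | user-set | sliding-window widths (points); simulations pass the ground-truth length |
| `dedup` | `TRUE` in mining | collapse identical windows before testing |
| `correct` | `FALSE` | Yates continuity correction |
| `seed` | 0 | run RNG for all stochastic decisions |

Defaults for `alpha`, `lambda_mix`, `lambda_size` follow common practice
for this objective family; $\lambda_{\text{mix}}$ is reported to be
insensitive on (0.25, 0.75).

## What the synthetic data emulate

`make_prototype_set()` ships five fixed, qualitatively distinct shapes —
ramp up, ramp down, peak, valley, step — of length 10, zero-centered
with total range 10 (values in $[-5, 5]$; the scale of a clinical
severity score's dynamic range). Zero-centering is essential, not
cosmetic: the simulated series ride on a zero-baseline uniform noise
background, and centered shapes make a prototype window *closer to
pure-noise controls than to cases carrying a different prototype*. With
all-positive shapes, any structured window splits all-cases-from-
all-controls — the five planted associations collapse into a single
"has any structure" signal and every candidate becomes maximally
significant, which is not the regime a per-prototype evaluation is
meant to probe.

Two designs are generated (reproducibly per `(spec, seed)`):

* **Replication design** (`generate_replicates()`): per prototype,
  `n_per_prototype` copies with i.i.d. $U(-\sigma, \sigma)$ noise per
  point. Used to compare subset-selection optimizers.
* **Classification design** (`generate_labeled_dataset()`): cases are
  length-20 noise backgrounds with one noisy prototype injected at a
  uniformly random offset (the window is replaced); controls are pure
  noise with the same $\sigma$; prototypes are assigned round-robin so
  every shape is planted equally often; the annotation records each
  injection. The method-comparison study runs
  $n \in \{100, 200\} \times \sigma \in \{1, 2, 5\}$ with five
  repetitions — the full noise range of the reference design with the
  sample-size grid halved to keep a single-CPU run in minutes.

What these simulations do *not* emulate: integer-valued scores (ties in
distances are measure-zero here but pervasive in, e.g., SOFA data),
irregular sampling, missingness, autocorrelated backgrounds, and
multivariate signals. Passing tests on these designs therefore show the
machinery is correct and the comparisons behave as described on clean
planted signal — not that effect sizes transfer to clinical data.

## Evaluation

Each retrieved shapelet maps to its most similar prototype (ties to the
lowest index); $k_d$ is the number of distinct prototypes hit;
recall $= k_d/|R|$, precision $= k_d/|\hat R|$, F1 their harmonic mean,
with empty retrievals scoring 0 rather than erroring. `min_sim` reports
the worst best-match similarity — a worst-case fidelity measure.
`compare_methods()` is a two-sided Welch $t$-test on per-repetition F1
scores; we report it pooled across the grid (per-cell tests on 5
repetitions have little power either way).

## Numerical choices and degenerate inputs

* Thresholds are the exact observed distances; duplicates collapse to
  one split. Prediction is inclusive ($\le \theta$).
* Degenerate 2×2 tables return $p = 1$; a single-class dataset is an
  error for any statistical operation.
* Tie-breaks are deterministic everywhere: candidate ordering is stable
  on extraction order (series, then width, then offset); the exhaustive
  oracle prefers smaller then lexicographically smaller sets; greedy
  takes the earliest best item.
* Incremental-vs-scratch agreement is enforced at $10^{-9}$ relative
  tolerance; evictions rebuild the best-similarity-to-$\hat R$ cache
  (a max cache cannot be patched after removal).
* All stochastic decisions draw from one seeded run RNG, so pipeline
  variants are comparable under common random numbers and runs are
  bit-reproducible.

## Known limitations

* **FWER under a continuous null.** Testability uses the *observed*
  minimum p-value, and the interleaved correction factor is
  $|\hat R|$. On continuous-valued null data the minimum over ~$n$
  thresholds is selection-inflated, so small corrected thresholds of
  order $\alpha/|\hat R|$ do not bound the false-discovery probability:
  the package's own null calibration (20 label-shuffled noise runs)
  finds spurious discoveries in every run. Strict FWER control would
  need the margin-based minimum *attainable* p-value plus an accounting
  of threshold multiplicity, which is out of scope here. On heavily
  discretized data (few distinct thresholds) the gap between observed
  and attainable minimum p-values narrows and the procedure is far less
  anticonservative.
* **Admission budget vs. retrieval metrics.** The default objective
  admits items while cumulative similarity to the representatives is
  below ~0.5. With realistic cross-candidate similarities this caps the
  returned set near 8–14 and lets 2–4 near-copies of one prototype in
  before the budget exhausts — so per-prototype precision saturates
  well below 1 at low noise, and occasionally a prototype whose windows
  arrive late is never admitted. This also makes the interleaved loop
  and the two-step Tarone pipeline nearly (often exactly) coincide on
  the planted designs: the admitted prefix of the p-sorted stream lies
  below every stage-1 threshold. The package reports these comparisons
  as computed; it does not adjust the objective to separate them.
* The shapelet distance is not a metric (no triangle inequality), which
  is why representatives are selected by submodular optimization rather
  than clustering; but it also means similarity values are
  scale-dependent — users mining data on very different value ranges
  should expect different effective admission budgets.
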