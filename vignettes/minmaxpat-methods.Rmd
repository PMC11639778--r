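---
title: "Methods: the MinMaxPat descriptor, CWINCA selection, and the tkNN ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MinMaxPat descriptor, CWINCA selection, and the tkNN ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic experiments do and do
not demonstrate.

## The descriptor

A recording is cut into non-overlapping segments of `duration_s` seconds
(default 15 s; at the default 512 Hz a segment holds 7680 samples; a
trailing remainder shorter than one segment is dropped, never padded).
Within a segment, every stride-1 window of `W = 16` samples contributes one
code,

$$\mathrm{code} = W\,(\mathrm{maxi}-1) + (\mathrm{mini}-1),$$

where `mini` and `maxi` are the 1-based positions of the window minimum and
maximum. The histogram of the $\mathrm{Len}-W+1$ codes over the
$W^2 = 256$ possible values is the feature vector. Two invariants pin the
implementation down and are asserted in the tests: the histogram mass
always equals the block count, and the codes form a bijection with the
(maxi, mini) grid.

Assumptions worth stating: the descriptor sees only *ordinal* structure
inside 16-sample windows. It is exactly invariant to adding a constant and
to positive rescaling, and negating the signal transposes the code matrix
(min and max swap). It carries no spectral phase information beyond what
extremum positions encode, and at 512 Hz a 16-sample window spans ~31 ms —
the descriptor is therefore sensitive to morphology at the scale of fast
deflections (QRS-like events), not slow waves.

### Fixed numerical conventions

* **Argmin/argmax ties → first occurrence.** Constant windows code as
  (1, 1) → 0. This matches the default contract of mainstream numeric
  environments and must be fixed for bit-reproducibility.
* **Raw counts, not frequencies.** The histogram function is left
  unnormalized so the conservation invariant (sum = block count) holds and
  segment length stays recoverable; `normalize = TRUE` divides by the block
  count for workflows mixing segment lengths.
* **`W` and the code base are one parameter.** Other widths are supported,
  but 16 is the tested default and the only value the 256-bin contract
  refers to.
* No filtering, detrending or amplitude normalization is applied before
  extraction; the offset/gain invariance above makes the usual baseline
  corrections redundant for this descriptor.

## NCA feature weighting

Weights are learned by maximizing

$$F(w) = \frac{1}{n}\sum_i p_i \;-\; \lambda\sum_r w_r^2,
\qquad p_i = \sum_{j\neq i,\; y_j = y_i} p_{ij},$$

with $p_{ij} \propto \exp(-\sum_r w_r^2\,|x_{ir}-x_{jr}|)$ normalized over
$j \neq i$ — the leave-one-out probability that sample $i$ is correctly
classified by a stochastic nearest neighbor under a weighted city-block
metric. The distance family, regularizer and optimizer are open choices in
this model family; the package fixes:

* **weighted L1 distance**, the standard choice for per-feature (diagonal)
  NCA feature selection;
* **λ = 1/n by default** (scales the penalty with the amount of evidence),
  `max_iter = 200`, `tol = 1e-6` on the objective increase;
* **full-batch gradient ascent with an adaptive step** (step halved until
  the objective increases, grown 1.2× after acceptance). Accepted objective
  values are non-decreasing by construction, and the suite asserts this
  monotonicity along with an analytic-vs-finite-difference gradient check
  at 1e-5 relative tolerance;
* **columns standardized** to zero mean and unit variance first (constant
  columns become all-zero and their weight is driven to zero by the
  penalty). Histogram counts scale with segment length, so unstandardized
  columns would let high-mass bins dominate the metric for no
  class-relevant reason. Weights are reported in standardized space;
* softmax rows are shifted by their minimum distance before
  exponentiation, so the objective is finite even when initial distances
  are in the hundreds (256 standardized features at unit weights);
* the returned weights are $|w|$ (the objective depends on $w$ only through
  $w^2$), and the descending sort breaks ties by ascending feature index.

## CWINCA: cumulative-weight iterative selection

With weights sorted descending, `cumulative_weight_bound(w, t)` returns the
smallest prefix holding a fraction `t` of the total weight mass. The
candidate subset sizes are `start = bound(0.85)` to `stop = bound(0.99)`;
for each size the *loss classifier* — 1-NN, city-block, under seeded
stratified cross-validation (10 folds, capped at the smallest class size) —
is evaluated on the weight-ranked prefix, and the most accurate prefix
wins, ties going to the smallest size. Only prefixes of the weight order
are ever considered; the search is one-dimensional by design.

Two points here were contradictory or unstated in the sources this design
follows, and are therefore explicit package decisions:

* **Start threshold 0.85 vs 0.80.** Both values circulate for this
  selector. The package defaults to 0.85 — the value from the method's
  declared parameter table — and accepts `t_start = 0.80` as an argument;
  the resolved thresholds are always logged and embedded in artifacts.
* **The loss classifier and its evaluation.** Nothing pins down which
  classifier scores the prefixes, or whether it uses cross-validation or
  resubstitution. 1-NN/city-block under 10-fold CV is the customary choice
  in this model family and the default; `eval_scheme = "resub"` is
  available. (Resubstitution with 1-NN would be trivially perfect, so the
  resubstitution path is mainly useful with larger `loss_k`.)

## The tkNN ensemble

The 90-configuration grid is enumerated distance-major (city-block,
Euclidean, cosine), then k = 1..10, then weight (equal, 1/d, 1/d²) — a
fixed order so that "outcome 37" means the same model everywhere. Per
configuration, out-of-fold predictions are pooled over the CV folds into
one full-length vector. Iterative majority voting sorts the 90 vectors by
accuracy (stable sort; ties keep grid order) and emits the element-wise
mode of the top 3, 4, …, 90 — 88 voted vectors. The greedy step scores all
178 and keeps the first index attaining the maximum, so parameter-based
outcomes beat voted ones on exact ties.

Hard rules the contract fixes (each is exercised by a dedicated test):

* zero-distance neighbors under 1/d or 1/d² weighting take the vote alone
  (the infinite-weight limit), majority among them, ties to the first
  class level;
* neighbor ties at the k-th distance keep earlier training rows (stable
  order), exactly k neighbors;
* vote ties resolve to the smallest class code;
* cosine distance is $1 - \frac{u\cdot v}{\lVert u\rVert\,\lVert v\rVert}$
  and rejects zero vectors by row number;
* a configuration whose k exceeds a fold's training size falls back to all
  available neighbors — only reachable with degenerately small folds, e.g.
  leave-one-record-out over a handful of short records.

### Paper versus honest protocol

In the published protocol the selector sees the full labeled matrix and
the ensemble sorts and picks its winner on the very pooled test
predictions it reports. Selection and model choice therefore leak label
information into the reported score; with 178 candidates the optimism is
real even though each candidate is itself honestly cross-validated. The
package keeps this as `mode = "paper"` because reproducing the protocol is
the point, warns about it here and in the function documentation, and
offers `mode = "honest"`: per outer fold, feature selection is re-run on
the training rows, the 90 configurations are scored by leave-one-out on the
training rows, IMV and the greedy pick happen there, and only the chosen
model touches the test rows.

## Evaluation

Both schemes pool per-fold test predictions into a single confusion matrix
(rows actual, columns predicted) before computing metrics, so each segment
is counted exactly once. The five reported metrics, as percentages:
accuracy (trace/total), macro precision and recall (unweighted class means;
an empty predicted column contributes precision 0), F1 (harmonic mean of
the two macro averages) and the G-mean (geometric mean of class recalls).
The macro and G-mean definitions are package choices — the sources report
single precision/recall/G-mean values for a two-class task without defining
them — and per-class values are emitted alongside for transparency.
Stratified 10-fold assignment is seeded and balances every class across
folds to within one segment; LORO builds one fold per record and warns (but
still evaluates) when a held-out record's class is missing from its
training fold.

## The synthetic generator

`generate_dataset()` emulates the *shape* of a multi-record two-class ECG
corpus: per record, an asymmetric triangular waveform — sharp rise to a
unique peak at each period start, slow linear decay to a unique trough at
mid-period, then recovery — repeated at the record's period, plus white
noise. Class is encoded in the period (defaults 20 vs 26 samples); each
record draws one period jitter (SD 1 sample) and one phase offset, so
records are exchangeable within class but not identical, which is what
leave-one-record-out needs to be meaningful. Because the trough sits at
half the period, the peak-to-trough spacing inside a 16-sample window — the
exact geometry the descriptor codes — differs by class; with the noise off,
the two classes' dominant histogram bins are disjoint, and the suite
asserts this.

Default study conditions, fixed once: 10 records per class, 4 segments per
record (80 segments of 7680 samples), 512 Hz, noise SD 0.05 relative to
unit pulse amplitude. These sizes keep a full pipeline run in seconds while
leaving all structural properties (multi-record grouping, ≥10 segments per
class for stratified 10-fold) intact.

What the generator does **not** model: PQRST morphology, heart-rate
variability, baseline wander, electrode artifacts, class overlap, or
record-level covariate shift. Passing the synthetic recovery and
separation tests therefore shows the pipeline's machinery is correct and
self-consistent — it does not predict accuracy on clinical recordings,
where class geometry is far subtler. The planted-feature fixture
(`generate_planted_feature_matrix`) is deliberately simpler still: a mean
shift of 3 noise-SDs on 3 of 20 columns, n = 200 — the scale at which the
selector's recovery rate over 20 seeds is measured.

## Known limitations

* Input is limited to in-memory records and delimited text (per-record CSV
  plus a manifest); binary waveform formats are out of scope.
* tkNN emits hard labels only: no probabilities, hence no ROC/AUC.
* The paper-mode accuracy is an optimistic, self-organized figure by
  construction; use honest mode (or an outer held-out set) for deployment
  estimates.
* All-pairs distances make NCA O(n²p) per iteration; the compiled kernels
  handle thousands of segments comfortably, but the method is not designed
  for very large n.
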