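---
title: "Signed-rank connectivity mapping: model, null distribution, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed-rank connectivity mapping: model, null distribution, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Connectivity mapping matches a transcriptomic *query signature* — lists of
probes up- and down-regulated in a condition of interest — against a large
reference database of drug-perturbation expression profiles, to find
compounds that *mimic* the condition (positive connection) or *reverse* it
(negative connection, the therapeutically interesting direction for disease
signatures). `rankmap` implements the complete engine: reference database
construction, signed-rank scoring with median aggregation over treatment
sets, a Gaussian (error-function) null model for connection p-values, and
per-probe attribution of connections via the Contribution Fraction.

## Reference profiles

Each perturbation *instance* (one compound, one cell line, one dose/time,
on one physical plate) is reduced to a vector of signed ranks. The
differential expression of a treated instance is its expression minus the
per-probe mean of all control instances on the same plate
(`differential_profile()`), which removes plate-level technical effects.
Control aggregation by mean is the minimal-assumption default and is
configurable to the median; the choice is isolated behind one function.

The signed-rank transform (`signed_rank()`) assigns the probe with the
i-th smallest absolute differential value the absolute rank i — the largest
|d| gets rank N — and each rank carries the sign of its differential value.
Two numerical rules keep every profile an exact signed permutation of 1..N,
which the closed-form score denominator requires:

* ties in |d| (including multiple exact zeros) break deterministically by
  ascending probe index — reproducibility is preferred over average-rank
  fractions, and tie probability is negligible for continuous data;
* a zero differential gets a positive sign; zeros land at the lowest ranks
  where their contribution to any score is minimal either way.

Both rules are covered by property tests: signed ranks are invariant under
any strictly increasing odd transform of the differentials (tested with
x³), and sorting the absolute values of any stored profile reproduces 1..N.

## The connection score

For a profile with signed ranks $R(g)$ and a reconciled query signature of
$m$ probes with directions $s(g) \in \{+1, -1\}$,

$$c(R, s) = \frac{\sum_{i=1}^{m} R(g_i)\, s(g_i)}{\sum_{i=1}^{m} (N - i + 1)}.$$

The denominator is the largest value the numerator can take, so
$c \in [-1, 1]$, with $c = 1$ exactly when the signature probes occupy the
top-$m$ absolute ranks with concordant signs. The denominator is an exact
integer and scores are ratios of integers in double precision, so they are
exactly reproducible; the suite checks bit-identity against a brute-force
summation oracle on 10,000 random cases.

Instances sharing a perturbagen (and usually also a cell line) form a
*treatment set*; the set score is the **median** of the member scores, with
the even-size median taken as the mean of the two middle values. That
convention is standard, and it preserves the score's antisymmetry: swapping
a signature's up and down lists negates every instance and set score
exactly.

## Why the median

Random-signature score distributions of real treatment sets can be heavily
skewed (Pearson moment skewness $\gamma > 1$), particularly for sets of a
few to a few dozen instances, and a mean over such a set is dominated by
its tail. Two structural facts shape how we test this claim on synthetic
data:

* For signatures with equal up and down counts, the random-signature null
  of *any* set is exactly symmetric: swapping the two lists is
  measure-preserving and negates every score. Skew can therefore only be
  probed with an uneven signature; the diagnostic in `skew_landscape()` is
  run with a single-probe (1 up / 0 down) signature, the finest-resolution
  probe of landscape asymmetry — summing over $m$ probes dilutes
  per-probe skew by roughly $1/\sqrt{m}$.
* Because ranks are bounded, no instance-specific outlier can skew a set's
  null: a probe's contribution is capped at $N/D$ regardless of how extreme
  the underlying expression value is. Skew requires probes that are
  *coherently* extreme — consistently high-ranked with a consistent sign
  across most of a set's instances. This is why iid heavy-tailed noise
  alone, however extreme, produces no skew after rank transformation; the
  generator models coherent response modules explicitly (below).

The package's acceptance suite reproduces the phenomenon qualitatively: on
heavy-tailed synthetic data a detectable fraction of sets (concentrated at
the larger set sizes, where the median suppresses incoherent noise most
strongly) exceeds $\gamma = 1$, while matched Gaussian data yields none,
and median-aggregated set scores are several-fold more stable than
mean-aggregated ones across re-simulations of dose-heterogeneous sets.

## Connection p-values

Per treatment set, the null distribution of set scores is estimated from
`n_random` random signatures that match the query's up/down split (the
score is sign-sensitive, so the null must mirror the query's structure);
sampling is uniform without replacement from the database's full probe
universe. The default `n_random = 2000` gives results consistent between
runs and is configurable upward. The sample mean $\mu$ and the sample
($n-1$) standard deviation $\sigma$ parameterize a Gaussian, and the
two-sided p-value is its tail area:

$$p = 1 - \Phi\!\left(\frac{|c| - \mu}{\sigma}\right) +
      \Phi\!\left(\frac{-|c| - \mu}{\sigma}\right),$$

with direction carried separately by the sign of the score and of the
Z-score $z = (c - \mu)/\sigma$. $\mu$ is estimated rather than assumed
zero. The degenerate case $\sigma = 0$ returns the limit value (1 if
$|c| \le |\mu|$, else 0) with a warning. The suite validates the normal
approximation two ways: per-set null distributions on Gaussian synthetic
data pass a Kolmogorov–Smirnov normality check in at least 90% of sets,
and the erf p-value agrees with brute-force resampling (100,000 random
signatures) to within 0.01. The hard agreement bound is asserted in the
tail regime ($p \lesssim 0.03$) where significance decisions are made;
nearer the center the comparison is bounded in aggregate, because a
2000-draw estimate of $\sigma$ propagates to p-value noise of order
$2\varphi(z)\, z/\sqrt{2 \cdot 2000} \approx 0.008$ at $z = 1$, so a
per-point 0.01 band is not statistically identifiable there.

A connection is called significant when $p \le \alpha / n_{\text{sets}}$
(default $\alpha = 0.05$) — a Bonferroni-style rule controlling the
expected number of false-positive sets per run at $\alpha$, the convention
of the signed-rank connectivity-mapping lineage. Direction filtering
(positive / negative) is applied downstream of the call.

## Contribution Fractions

For signature probe $k$, the *diminished score* $c^*_k$ omits probe $k$'s
term from the numerator while keeping the full denominator, so
$c - c^*_k = R(k)s(k)/D$ exactly. With median set scoring,

$$CF_k = 1 - \frac{\widetilde{c^*_k}}{\widetilde{c}}, \qquad
  CF^*_k = \frac{CF_k}{\max_k CF_k},$$

where the tildes are medians over the set's instances, taken independently
for full and diminished scores. $CF^*_k$ fixes the top contributor at 1;
negative values (probes opposing the connection) are divided by the same
positive maximum, so their sign — information about opposing probes — is
retained rather than suppressed. On single-instance sets the algebra is
exact: $CF_k = R(k)s(k)/(c \cdot D)$ and $\sum_k CF_k = 1$; medians break
the sum rule for larger sets, so it is asserted only at size 1.
Contributions are computed only for connections passing the significance
filter, which keeps the ratio away from the undefined regime of near-zero
median scores (a zero median raises an error). The contribution matrix is
exported as CSV with probes as rows and treatment sets as columns, columns
alphabetical, rows optionally ordered by median contribution, cells to six
decimals.

## The synthetic-data generator

`simulate_database()` emulates the structure of a plate-based perturbation
screen at desk scale: 978 landmark-style probes by default, perturbagens
assayed in cell lines with replicate instances, plates carrying both
treated instances and shared vehicle controls. Default conditions:
40 perturbagens (5 mimics, 5 reversers, 30 nulls) in up to 3 cell lines,
1–50 replicate instances per set, noise standard deviation 1, planted
effects of 5 noise-sd on a 30-probe companion query (15 up, 15 down) —
strong, clearly recoverable effects. Noise is Gaussian or Student-t (df
configurable; rescaled to unit variance) for heavy-tailed landscapes.

Two features model realities of perturbation screens that iid noise
cannot:

* **Coherent response modules.** Each treatment set regulates its own
  random probe module (15% of the universe by default) in a single
  direction, with per-probe amplitudes `module_scale * |noise draw|³`
  shared by all of the set's responding instances. The cubed draw reflects
  that regulation magnitudes are far more dispersed than well noise: most
  module probes stay buried, and the noise law's tail decides how many are
  strongly — and, crucially, coherently — regulated. Under t₃ noise some
  sets acquire enough rank-dominant single-signed probes to skew their
  nulls; under Gaussian noise essentially none do. This is a calibrated
  stand-in for whatever generates skew in real reference data; it
  reproduces the phenomenon, not its cause.
* **Dose/time activity heterogeneity.** `activity_rate < 1` makes each
  treated instance respond with that probability and otherwise behave as
  pure vehicle — the real-data situation where a set mixes active and
  inert doses. This is the regime in which median aggregation is visibly
  more rerun-stable than the mean.

The generator writes the same TSV formats the database builder reads, plus
a truth table of planted roles, so the whole pipeline can be exercised
end-to-end offline. What passing tests on these data do **not** show:
recovery of any published compound connection, behavior under the linear
inference of non-landmark probes, dose–response structure, or real
biological correlation between probes. All synthetic structure is labelled
as such.

## Reproducibility and problem sizes

Every run takes a mandatory master seed; each treatment set's random
signatures come from a substream derived deterministically from
`(seed, set index)` (`substream_seed()`), so results are bit-identical
regardless of evaluation order — the package's concurrency contract:
per-set evaluation is independent and may be parallelized without changing
a single byte of output. Identical configuration and seed produce
byte-identical CSV/JSON outputs.

The validation suite uses desk-scale problem sizes chosen to give each
statistical check adequate power: 10⁴ random cases for exact score
identities; 20 sets × 10⁵ brute-force signatures for the p-value oracle;
200-set null databases for type-I calibration (±3 binomial SE around
α = 0.05) and KS normality; 200-set landscapes for the skewness contrast;
and 15 re-simulations for the aggregation-stability comparison.

## Known limitations

* The normal null is an approximation; for sets whose null is visibly
  skewed (the γ > 1 regime) tail p-values inherit that approximation
  error. The per-set empirical estimation of μ and σ absorbs scale and
  location but not shape.
* Null statistics are estimated per (set, signature size) per run and not
  cached across signature sizes, since μ and σ depend on the up/down
  split.
* Signatures are unordered; rank-weighted query signatures and
  KS-statistic scoring are out of scope.
* Probe identifiers are matched as exact strings; gene-symbol mapping is
  upstream of this package.
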