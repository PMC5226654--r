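---
title: "Multi-timescale cell assembly detection: model, statistics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale cell assembly detection: model, statistics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(spikeassembly)
```

## The problem

A *cell assembly* is a group of neurons whose spiking forms a recurring,
supra-chance activity pattern with a specific constellation of time lags.
Such patterns live on very different temporal scales: sub-millisecond
synchrony, spike sequences spanning tens of milliseconds, or coordinated
firing-rate excursions lasting a second. A detector that fixes one bin
width, or that assumes stationary firing, will either miss most of this
spectrum or flood the analyst with false positives driven by slow rate
(co-)fluctuations — oscillatory drive, behavioural state, stimulus
onsets. `spikeassembly` detects assemblies of arbitrary lag structure at
a user-chosen set of bin widths, with a parametric pairwise test that is
corrected for non-stationarity *locally*, without surrogates or
bootstrapping.

## The pairwise test

Spike trains are binned at width $\Delta$ into count series
$\{c_{K,t}\}$, $t = 1\ldots T$ (half-open bins, trailing partial bin
dropped). Each count series is split into $M_K = \max_t c_{K,t}$ nested
binary layers, layer $\alpha$ marking bins with $c_t \ge \alpha$. For two
units $A, B$ and lag $l$ (bins), the joint count

$$\#AB_{,l} = \sum_{\alpha=1}^{M} \#AB^{\alpha}_{,l}, \qquad
  M = \min(M_A, M_B),$$

sums matched-layer coincidences; because the layers are nested this
equals $\sum_t \min(c_{A,t}, c_{B,t+l})$, which is how the package
computes it (and an identity the test suite checks exhaustively). Under
independence with fixed marginals each layer count is hypergeometric,
and accounting for the dependence between layers gives closed-form null
moments: with layer totals $\#A^\alpha, \#B^\alpha$ on the overlapping
window of length $\tilde T = T - |l|$,

$$\mu_{AB,l} = \sum_\alpha \frac{\#A^\alpha \#B^\alpha}{\tilde T},
\qquad
\sigma^2_{AB,l} = \sum_{\alpha}
  \frac{\#A^\alpha \#B^\alpha}{\tilde T}
  \frac{(\tilde T-\#A^\alpha)(\tilde T-\#B^\alpha)}{\tilde T(\tilde T-1)}
  + 2 \sum_{\alpha<\gamma}
  \frac{\#A^\gamma \#B^\gamma}{\tilde T}
  \frac{(\tilde T-\#A^\alpha)(\tilde T-\#B^\alpha)}{\tilde T(\tilde T-1)}.$$

Marginal totals are recomputed per lag on the overlapping window, so the
forward and reference counts below use comparable marginals.

A statistic standardized by these moments (`uncorrected_statistic`)
is valid only under stationarity. The corrected test instead uses the
**difference count**

$$\#ABBA_{,l} = \#AB_{,l} - \#AB_{,l^*},$$

with reference lag $l^* = -l$ (and $l^* = -2$ for the synchronous case
$l = 0$; a neighbouring bin would remove true structure through
spillover). Rate fluctuations slower than $|l|\Delta$ move both terms
alike and cancel, so $E[\#ABBA] = 0$ under independence at scale
$\Delta$ even when the two units share slow drive. Its variance is
estimated over $C$ segments of $k$ bins (default $k = 100$):

$$\hat\sigma^2_{ABBA} = 2\sum_c \mathrm{var}(\#AB^c)
                      - 2\sum_c \mathrm{cov}(\#AB^c, \#BA^c),$$

with per-segment hypergeometric variances and the within-segment
forward/reverse covariance
$\mathrm{cov}_c = -\mathrm{var}_c / (k_c - 1)$ — negative and exactly
this magnitude under the permutation null, which the test suite verifies
against a shuffle-bins Monte Carlo. Cross-segment covariances are
omitted. Finally

$$Q_l = \frac{\#ABBA_{,l}^2}{\hat\sigma^2_{ABBA}} \sim F_{1,v},
\qquad v = 2(T-|l|)M - 1,$$

is used for upper-tail testing. A conservative alternative $v = T-|l|$
is available (`dof = "conservative"`, selected automatically when
$T < 50$; the difference is negligible for $T > 400$). The moment
approximations require an expected joint count above 4; sparser pairs
are flagged untested rather than trusted. A pair is significant only
when the gate passes, the difference is positive (excess in the selected
direction), and $p$ clears the Bonferroni-corrected level.

Calibration, reproduced by `test-acceptance.R` at 4000 replicates:
under a stationary null the empirical $Q$ matches $F_{1,v}$ at lags 0,
5, 10 (Kolmogorov–Smirnov distance below the 1% critical value); under
*coupled* step-like or slow autoregressive rate modulation $Q$ remains
approximately calibrated with segmented variance while the uncorrected
statistic fails completely.

## Lag selection and multiplicity

For each pair, all lags $l \in \{-l_{\max}, \ldots, l_{\max}\}$ are
scanned and the lag with the highest joint count is tested (ties break
towards the smallest $|l|$, then the non-negative lag). Because the
marginals barely change across lags this equals testing every lag and
keeping the smallest p-value, so the Bonferroni budget charges all
$2l_{\max}+1$ lags: the pair-screening family is
$R_1 = N(N-1)(2l_{\max}+1)/2$ tests at level $\alpha/R_1$, and each
agglomeration iteration is charged
$R_i = N_{a,i}\, N_{u,a}\, (2l_{\max}+1)$, with $N_{a,i}$ the assemblies
tested in that iteration and $N_{u,a}$ the candidates eligible for
assembly $a$.

These budgets make the error rate of each *single-scale* analysis at
most $\alpha$, and because per-lag p-values are well calibrated the
bound is nearly tight — not loose. A multi-scale sweep over $S$ bin
widths would therefore approach $S\alpha$ if each scale received the
full budget, so `detect_assemblies` divides $\alpha$ by the number of
scales analysed: the family-wise guarantee covers the entire sweep the
user actually runs. On fully independent stationary datasets the
measured probability of returning any assembly is then below the nominal
$\alpha$ (recomputed by `scripts/acceptance.R`). Embedded structure is
unaffected in practice — true assemblies at realistic occurrence rates
carry p-values tens of orders of magnitude below either threshold.

## Recursive agglomeration

Significant pairs become two-unit assemblies. Each assembly formed in
the previous iteration is then paired, as a pseudo-unit, against every
single unit that had a significant pair relation with at least one
member (the screening matrix $Z$), at all lags; significant extensions
append the candidate at the winning lag, with lags re-referenced so the
earliest unit carries lag 0. This tests genuine higher-order structure
— $P(\text{set}, c)$ against $P(\text{set})P(c)$ through the set's
activation series — not an aggregate of pairwise relations. The test
suite verifies this with a triplet whose third unit is pairwise
independent of both members but coupled to their joint activations: the
extension test detects it while the direct pair tests do not. (Under the
single-unit screening restriction such a unit is not *eligible* during
the recursion; the restriction is what keeps the search tractable, and
its cost is exactly this corner case.)

The assembly's activation series counts, per bin, the complete lag
constellations anchored there: $\min_j c_{u_j, t+l_j}$. The
matched-layer $\min$ keeps the series on the same scale as unit counts —
for a pair its total equals the pairwise joint count, so the recursion
is exactly self-consistent. (The user-facing *activation score* of the
`activation` functions instead counts each combination of member spikes,
i.e. the product of member bin counts, which is the natural occurrence
count for scoring.)

After each iteration, among same-unit-set assemblies with different lag
vectors only the lowest-p variant survives; the recursion stops when
nothing is added; strict unit-subsets are pruned within each scale. The
whole scheme is re-run per bin width, and each assembly's
characteristic scale $\Delta^*$ is the width with its lowest p-value.
Optional across-scale prunings (cosine-distance near-duplicates,
across-scale subsets) are off by default and intended for visualization.
At very coarse bins a series may never fall below a positive floor
count; those non-informative baseline spikes are removed per pair
(`subtract_floor`) when both series have a positive minimum. A
hierarchical variant (fuse only the lowest-p pair of current sets,
yielding strictly nested structure) is available via
`method = "hierarchical"`; it cannot represent overlapping assemblies
and is off by default.

## The synthetic ground truth

`generate_background` draws each unit's rate from a stable AR(1) latent
process through an error-function sigmoid,
$\lambda_t = (1 + \mathrm{erf}(\upsilon\, s_t/\sigma_s))\bar\lambda$,
bounded in $(0, 2\bar\lambda)$, with defaults $\bar\lambda = 5$ Hz,
$D = 0.9$, $\sigma_s = 0.01$, $\upsilon = 0.2$, refractory
$\tau_{\mathrm{ref}} = 15$ ms. The latent step is 0.1 s, putting the
rate autocorrelation time near 1 s — slow co-fluctuation of exactly the
kind the corrected statistic must tolerate. Spikes are sampled as an
exact inhomogeneous Poisson process over the piecewise-constant rate
grid (time-rescaling inversion) with a refractory dead time; for a
constant rate this renewal process is identical to drawing
exponential inter-spike intervals and adding $\tau_{\mathrm{ref}}$. The
refractory delay biases realized rates below nominal by
$\approx \lambda\tau/(1+\lambda\tau) \approx 7\%$; we keep the
construction rather than rescaling rates.

Five assembly archetypes are embedded at uniformly random activation
instants (overlaps allowed), with background spikes of the same unit
erased within ±15 ms of every inserted spike: (I) exact synchrony;
(II) a frozen sequence with inter-member lags drawn once from
$U[0, 0.1]$ s; (III) a frozen per-member spike template drawn once at
Poisson 10 Hz over 0.2 s (redrawn until every member contributes — an
empty member would make membership meaningless); (IV) sequential 0.3-s
windows (lags drawn once from $U[0, 0.4]$ s) with spikes redrawn at
Poisson 10 Hz per occurrence; (V) a simultaneous rate step 5→10 Hz for
1 s, implemented as extra Poisson 5 Hz spikes over the window. The
`figure1` scenario embeds one assembly of each type as disjoint 5-unit
groups among 50 units; its default occurrence count is
$0.25 \times$ duration (0.25 /s sits on the retrieval plateau, far from
the degradation regime, which is what a reference scenario should be).
Calibration scenarios cover step-like Bernoulli rate changes at
elementary-bin resolution (coupled or independent, fast or slow) and a
common 4-Hz oscillatory drive
$\lambda_{A,B}(t) = 5(0.6\sin(2\pi\,4t) + a_{A,B})$, $a_A = 1$,
$a_B = 0.5$ — read with 0.6 multiplying the sinusoid, the only reading
that yields the stated 5 and 2.5 Hz means; unit B's negative
instantaneous rates are clipped at 0, biasing its realized mean
slightly upward (~0.1 Hz). Sorting errors reassign a stated fraction of
all spikes to uniformly drawn other units, conserving spike count.

What the generator does *not* emulate: bursting and other non-Poisson
interval statistics, common-input correlations between background units,
electrode drift, or realistic sorting-error structure (errors between
similar waveforms are not uniform across units). Passing tests on these
simulations therefore demonstrate statistical correctness of the method
under controlled violations — calibrated nulls, recovery of planted
structure — not performance on any particular recording system.

## Evaluation metrics

Partition agreement uses the plain Rand index
$R = (r+s) / \binom{n}{2}$ over a declared unit universe (default: the
union of true and detected assembly members; units in no assembly count
as singletons; the detected-members-only universe is also reported by
the CLI since the definition of $n$ is ambiguous when memberships
differ). Units detected in several assemblies are resolved
lowest-p-first before comparison. The retrieval score is the fraction of
true members recovered by the best-overlap-matched detected assembly;
the false-assignment fraction follows the convention of its source
figure — falsely assigned units over all recorded units. Assignment
matrices (units × assemblies, cells = lag to the leading unit) mirror
the standard visualization.

## Numerical and design choices

* Bins are half-open `[left, right)`; a spike exactly on an edge joins
  the later bin; the trailing partial bin is dropped.
* Lag-profile ties: smallest $|l|$, then the non-negative lag.
* Segment schemes: trailing remainders of at least $2(|l|+1)$ bins form
  a final shorter segment, otherwise they merge into the previous one.
* Zero estimated variance with a non-zero difference is flagged
  untestable, never significant; silent units and segments contribute
  nothing.
* Layer totals and all moment formulas are computed in double precision
  (window factors like $(\tilde T - \#A)(\tilde T - \#B)$ overflow
  32-bit integers at fine bins on long recordings).
* Iteration order over pairs, assemblies, and candidates is fixed
  (ascending unit order), and detection itself uses no randomness, so a
  given dataset and configuration always yields the identical catalog.
* Duplicate (unit, time) rows in input files are kept as two spikes,
  with a warning.

## Problem sizes used by the test and acceptance suites

The statistical checks run at reduced but representative sizes chosen to
keep the full suite in the minutes range: null calibration at 4000
replicates of $T = 10^4$ bins (stationary) and 1500 replicates of
$T = 4\cdot10^3$ bins (coupled non-stationary variants, state lengths
scaled proportionally); the five-archetype scenario at 1000 s with 250
occurrences per assembly over the bin-width grid
$\{0.015, 0.05, 0.15, 1\}$ s with $l_{\max} = 10$; false-assignment and
family-wise-error sweeps at 10–30 units and 200–1400 s; the
occurrence-rate and sorting-error sweeps at the full 1400 s duration
with 10 replicates per condition.

## Known limitations

* The denominator degrees of freedom under segmented variance are not
  exactly known; $v$ is configurable and the default follows the
  standard choice.
* The symmetric synchrony statistic
  $\#AB_{,0} - (\#AB_{,l^*} + \#AB_{,-l^*})/2$ is not implemented (its
  variance has no closed form here).
* A fixed far reference lag (`reference = "fixed"`) removes
  non-stationarity at a coarser effective timescale and measurably
  raises false discoveries under slow rate fluctuations at coarse bins;
  it is provided as a robustness check, not a default.
* Precisely time-reversed patterns at identical lag and scale cancel in
  the mirrored difference statistic and go undetected — inherent to the
  correction.
* Extremely sparse assembly activation series at coarse bins interact
  with the expected-count gate; gated extensions are simply not tested,
  which can truncate deep assemblies on short recordings.
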