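# spikeassembly

Detection of **cell assemblies** — groups of neurons whose spiking forms
recurring, supra-chance patterns with specific time-lag constellations —
in multivariate spike-time recordings, across a whole range of temporal
scales, for electrophysiologists and computational neuroscientists
working with simultaneously recorded single units.

Assemblies live on wildly different timescales (sub-millisecond
synchrony, spike sequences, second-long rate co-modulations), and naive
coincidence tests are confounded by slow firing-rate fluctuations. The
package implements:

* a **non-stationarity-corrected parametric pair test**: spike-count
  series binned at width Δ are split into nested binary layers; the
  lagged joint count `#AB,l = Σ_α #AB,l^α = Σ_t min(c_A[t], c_B[t+l])`
  has closed-form multivariate-hypergeometric null moments, and the
  *difference count* `#ABBA,l = #AB,l − #AB,l*` (reference lag
  `l* = −l`, or −2 for synchrony) cancels slow rate (co-)fluctuations
  locally. With a segmented variance estimate (segments of k = 100
  bins), `Q = #ABBA² / σ̂² ~ F(1, v)`, `v = 2(T−|l|)M − 1`, giving fast
  surrogate-free significance tests at any lag `l ∈ {−l_max … l_max}`
  and any bin width;
* **recursive agglomeration** of significant pairs into higher-order
  assemblies: each formed assembly is treated as a pseudo-unit through
  its activation series and paired against eligible candidate units,
  under strict Bonferroni budgets
  (`R1 = N(N−1)(2·l_max+1)/2` at pair screening), with lag-variant and
  subset pruning; the whole scheme runs per bin width and assigns each
  assembly its characteristic scale Δ* (lowest p across widths);
* a **ground-truth simulator**: 50-unit inhomogeneous-Poisson recordings
  with AR-latent rates (5 Hz mean, 15 ms refractory), five embedded
  assembly archetypes (synchrony, frozen sequences, frozen templates,
  sequential rate windows, 1-s rate steps), spike-sorting-error
  corruption, and step-rate/oscillation calibration scenarios;
* **evaluation metrics**: Rand index, retrieval score, false-assignment
  fraction, assembly-assignment matrices.

## Worked example

Simulate a 700-s recording of 50 units with two embedded 5-unit
assemblies — one synchronous (type I, units u01–u05), one a frozen
sequence (type II, units u06–u10) — then detect at two bin widths:

```r
library(spikeassembly)

sc   <- generate_scenario("figure1", seed = 7, duration = 700,
                          n_occurrences = 175, types = c("I", "II"))
catl <- detect_assemblies(sc$dataset, deltas = c(0.015, 0.1), l_max = 10)
catl
#> assembly_catalog: 3 assemblies across 2 bin widths
#>   delta 0.015 s: {u04,u05,u03,u02,u01} lags (0,0,0,0,0), p = 1.05e-229, delta* = 0.015
#>   delta 0.015 s: {u06,u07,u08,u09,u10} lags (0,1,6,6,10), p = 2.09e-76, delta* = 0.015
#>   delta 0.1 s: {u06,u09} lags (0,1), p = 5.38e-07, delta* = 0.1

m <- retrieval_metrics(sc$truth, catl)
sprintf("retrieval %.2f, false fraction %.2f, Rand index %.2f",
        m$retrieval, m$false_fraction, rand_index(sc$truth, catl)$rand_index)
#> "retrieval 1.00, false fraction 0.00, Rand index 1.00"
```

Reading the output: the synchronous assembly is recovered with an
all-zero lag vector and the sequence with its frozen lag order (lags in
bins of 15 ms, relative to the earliest unit), both with characteristic
scale Δ* = 0.015 s; the two-unit entry at Δ = 0.1 s is the same sequence
re-surfacing coarsely and would be removed by the optional across-scale
pruning (`prune_catalog`). No background unit is ever assigned
(`false fraction 0`), and the membership partition matches ground truth
exactly (`Rand index 1`).

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/spikeassembly.R`:

```sh
Rscript inst/cli/spikeassembly.R simulate --scenario figure1 --seed 7 --out sim
Rscript inst/cli/spikeassembly.R detect --input sim.spikes.csv \
    --binwidths 0.015,0.05,0.1,0.15,1 --maxlag 10 --alpha 0.05 --out catalog.json
Rscript inst/cli/spikeassembly.R activation --input sim.spikes.csv \
    --catalog catalog.json --out activations.csv
Rscript inst/cli/spikeassembly.R evaluate --truth sim.truth.json \
    --detected catalog.json --out metrics.json
```

See `vignettes/assembly-detection.Rmd` for the statistical model, the
design decisions, and the generator's scope.

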