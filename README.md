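# bispecref

Quantifies how the choice of EEG reference distorts **bispectral**
measures of non-linear brain coupling. Scalp EEG is a potential
*difference*, so a non-neutral reference — the vertex electrode (Cz),
digitally linked mastoids (DLM), or the channel average (AVE) — mixes its
own signal into every channel. `bispecref` measures the resulting bias in

* **bicoherence** `b_i(f1, f2) = <v_i(f1) v_i(f2) v_i*(f1+f2)> / (Q_i(f1) Q_i(f2) Q_i(f1+f2))`,
  with `Q_i(f) = ((1/L) Σ_l |v_i(f, l)|³)^{1/3}` so that `|b| ≤ 1`,
* **cross-bicoherence** `cb_ijk`, its three-channel generalization, and
* **antisymmetric cross-bicoherence**
  `acb_ijk = (B_ijk − B_kji) / (N_ijk + N_kji)`, which vanishes for any
  superposition of independent sources and so suppresses
  volume-conduction artifacts,

by simulating EEG referenced to a point at infinity (an ideal neutral
reference, available only in a forward model), re-referencing it with
each scheme — including **REST** (reference electrode standardization,
`T = G_∞ G_m⁺` built from equivalent-source-distribution lead fields) —
and computing the relative error

    RE_X = Σ |b^X − b^INF|² / Σ |b^INF|²   (reported in percent)

against the infinity-reference gold standard.

The package contains the full pipeline: an analytic three-shell spherical
head model with idealized 10-20/10-10/10-5 electrode layouts (21, 34, 74,
128 channels), a simulator of two time-delayed quadratically
phase-coupled dipole sources (6, 10 and 16 Hz, 10 ms delay) with
broadband noise dipoles at SNR = 1, segmented-FFT bispectral estimators,
the relative-error experiment harness, and permutation-based group
statistics (paired t, sign-flip permutations, Benjamini–Hochberg FDR).

## Worked example

```r
library(bispecref)

model  <- head_model()                 # 0.080/0.085/0.092 m, 0.33/0.0066/0.33 S/m
layout <- make_layout(21, model)       # 10-20 montage + TP9/TP10
rec    <- gen_dataset(sim_config(seed = 1), layout, model)
print(rec)
#> EEG recording: 21 channels x 150000 samples at 500 Hz, reference INF
rec$provenance$achieved_snr
#> [1] 1

S <- segment_fft(rec, freqs = c(6, 10, 16))     # 300 Hann-windowed 1 s segments
b <- abs(bicoherence_channels(S, 6, 10))
round(sort(b, decreasing = TRUE)[1:5], 3)
#>    F3    Fz   Fp1    C3    Cz
#> 0.634 0.632 0.630 0.627 0.625
b_max(b)
#> $value 0.634   $channel "F3"
```

The coupled sources light up bicoherence at exactly (6, 10) Hz — the scan
`bicoherence_scan(segment_fft(rec), "F3", 40)` peaks there. Re-referencing
distorts it; for this dataset:

```r
Tcz  <- make_simple_transform("Cz", layout)
Scz  <- segment_fft(apply_transform(Tcz, rec), freqs = c(6, 10, 16))
bcz  <- bicoherence_channels(Scz, 6, 10)
100 * relative_error(bcz, bicoherence_channels(S, 6, 10))
#> [1] 193.2
```

A 193% relative error: under a Cz reference the per-channel bicoherence
pattern of this dataset bears little resemblance to the unbiased one. The
experiment harness (`exp_config()` + `run_experiment()`) repeats this over
100 random source configurations, all schemes, three measures and several
electrode densities; `summary()` returns box-plot statistics with the
notch-based significance readout. The numbered scripts under `analysis/`
walk through the full study: simulation, transform construction,
bispectral maps, the relative-error experiment and the group statistics,
writing tables under `results/`.

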