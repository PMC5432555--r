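---
title: "How the EEG reference distorts bispectral measures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the EEG reference distorts bispectral measures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scalp EEG measures potential differences, so every channel implicitly
contains the signal at the reference. A non-neutral reference (the vertex
electrode Cz, digitally linked mastoids, even the channel average) mixes
its own brain signal into every channel. Linear connectivity metrics are
known to be distorted by this; `bispecref` quantifies the distortion for
*bispectral* metrics — bicoherence and two bispectrum-based cross-frequency
connectivity measures — by simulation against an ideal neutral reference, a
point at infinity, which is only available in a forward model.

The estimators are, with `v_i(f, l)` the Hann-windowed Fourier coefficient
of channel *i*, segment *l*:

* auto-bispectrum `B_i(f1, f2) = <v_i(f1) v_i(f2) v_i*(f1 + f2)>` with
  `<.>` the mean over segments;
* bicoherence `b_i = B_i / (Q_i(f1) Q_i(f2) Q_i(f1 + f2))` where
  `Q_i(f) = ((1/L) sum_l |v_i(f, l)|^3)^(1/3)`;
* cross-bicoherence `cb_ijk` — the same construction with three channels;
* antisymmetric cross-bicoherence
  `acb_ijk = (B_ijk - B_kji) / (N_ijk + N_kji)`, which vanishes identically
  for any instantaneous superposition of independent sources and therefore
  suppresses volume-conduction artifacts.

The three-norm normalization makes every magnitude a Hölder ratio, so
`|b|, |cb|, |acb| <= 1` exactly on the empirical segment measure — the
package keeps the `1/L` factor in both numerator and normalization so the
bound is exact, and the test suite asserts it on every tested dataset.

## The simulation conditions

The generator reproduces the study conditions: `s1` is the sum of three
unit-variance oscillators — white Gaussian noise band-passed 1 Hz wide
around 6 Hz and around 10 Hz, and their pointwise product band-passed
around 16 Hz, which installs quadratic phase coupling at (6, 10) Hz; `s2`
is `s1` delayed by 10 ms (exactly 5 samples at 500 Hz). Four independent
noise dipoles carry white Gaussian signal band-limited to 0.5–100 Hz. All
six dipoles are drawn uniformly from a 5 mm grid filling the brain sphere,
with uniformly random orientations (normalized Gaussian triples). Sensor
signals are the lead-field projections, with the noise-source gain solved
so the ratio of mean channel variance (coupled sources over noise sources)
equals exactly SNR = 1, plus white sensor noise at 1% of the signal RMS
(−40 dB; the study states "a low level" without a number). Recordings are
5 min at 500 Hz; 1 s non-overlapping Hann-windowed segments give a 1 Hz
frequency resolution and L = 300 segments.

Unstated details fixed here once: Butterworth order 3 per pass, run
forward and reverse (zero phase, effective order 6) — sharp enough for
1 Hz bands without ringing; the three oscillators standardized to unit
variance before summation; the delay implemented circularly, with two
extra seconds simulated and discarded so delivered recordings carry no
filter or wrap-around edges.

What the generator does *not* emulate: realistic cortical geometry and
orientation structure, 1/f background spectra, non-stationarity, and
artifacts. Passing tests therefore demonstrate the estimator and
reference algebra under controlled quadratic phase coupling, not
performance on real recordings.

## Head model and layouts

The study computed forward solutions on MRI-derived realistic meshes; this
package substitutes the standard three-concentric-shell spherical
conductor (radii 0.080 / 0.085 / 0.092 m for the brain, skull and scalp
boundaries; conductivities 0.33 / 0.0066 / 0.33 S/m). The solver is the
truncated Legendre series for concentric shells, implemented as one 5×5
interface-matching solve per degree with interface-localized basis
functions so every matrix entry stays O(1) up to degree 200. The series is
truncated per dipole when the current term falls below 1e-12 of the
accumulated potential — machine-level for all realistic eccentricities —
and the homogeneous-sphere closed form (summed analytically from Legendre
generating functions) serves as the oracle in the tests.

Electrode templates are idealized spherical 10-20 / 10-10 / 10-5-style
tables built from the proportional-arc construction (outer ring at 72°
inclination, rows as great-circle arcs between ring and midline), nested
21 ⊂ 34 ⊂ 74 ⊂ 128. The montages of the original study are not published
as label lists, so these sets are documented stand-ins: the 34-set is a
quasi-uniform down-sampling of the 10-10 system retaining Cz and the
mastoid proxies, and the 128-set adds 10-5-style intermediate rows. TP9
and TP10, on the equatorial circle near the mastoids, act as the
linked-mastoid pair at every density. Layouts ship as `.sfp`-style text
under `inst/extdata/` and are regenerated programmatically by
`make_layout()`.

## Reference transforms

Cz, DLM and AVE are the exact matrices `I − R` (ones in the Cz column,
0.5 in the mastoid columns, 1/N everywhere); they are idempotent and
annihilate common offsets to machine precision. REST is
`T = G_inf · pinv(G_m)` where `G_inf` is the infinity-referenced lead
field of a 4000-dipole equivalent source distribution — a spherical cap
(0–130° polar, at 0.95 × brain radius) closed below by a transverse disk,
quasi-uniform by Fibonacci/sunflower spirals, normally oriented — and
`G_m` the same lead field under the acquisition reference (Cz here,
matching an acquisition referenced at the vertex). The pseudoinverse
truncates singular values below 1e-8 of the largest; the ESD lead field is
numerically low-rank at high electrode counts and the truncation level is
an explicit knob, as are the cap extent and radius, since the study does
not state either.

One property of REST deserves emphasis because it shapes several results.
Re-referencing destroys exactly one dimension of the data — the per-sample
common offset — and REST restores it from the head model. The restoration
is well-posed only when the electrodes cover (nearly) the whole conductor
surface: the external field of any interior source integrates to zero over
a closed surface, which pins the offset. With upper-head montages the
offset is weakly identifiable: any closed source layer can produce a
near-constant pattern on a half-coverage array at low amplitude. In our
tests REST recovers ESD-generated infinity-referenced data to well below
1% Frobenius error on a dense whole-sphere covering, while at the 21–128
channel montages the spatial pattern is recovered to machine precision but
a per-sample common offset of roughly 20–30% of signal norm remains. This
is a genuine geometric limitation, not an implementation artifact, and it
is why REST's advantage over AVE in the experiment below is systematic but
not dramatic under the spherical stand-in.

The mismatched-REST variant (`REST_perturbed`) scales the brain and skull
boundary radii by 0.9 and the skull conductivity by 1.1 while keeping the
scalp radius (the electrode shell is observed). Scaling all radii together
would be a no-op — the REST composite map is invariant under uniform
rescaling — and, in the concentric geometry, conductivity mismatch alone
largely cancels through the pseudoinverse because it acts as a
near-diagonal multiplier on spherical-harmonic degrees. A genuine
geometric perturbation is therefore part of the default.

## The experiment and its statistics

For each repetition an infinity-referenced dataset is generated; the
re-referenced copies are obtained by applying each transform to the
spectral coefficients (exactly equivalent to transforming the time series,
by linearity of windowing and the DFT, and much cheaper). Relative error
of a scheme X for, say, bicoherence is

    RE = sum_i |b_i^X - b_i^INF|^2 / sum_i |b_i^INF|^2

and analogously over all ordered channel triplets for `cb` and `acb`
(degenerate triplets contribute zeros to both numerator and denominator of
`acb` and are harmless). The modulus applies to the *complex* difference:
that is the literal reading of the defining formula, it retains
reference-induced phase rotations of the estimates, and it reproduces the
reported error levels; comparing magnitudes instead (available as
`re_on_complex = FALSE`) discards the phase component and yields errors
several times smaller. Each repetition draws new source positions,
orientations and time courses; 100 repetitions per density (the original
study ran 1000 across ten realistic head models; one spherical geometry at
100 repetitions is the desk-scale design here, and the notch-based
significance readout in `box_stats()` — median ± 1.57 × IQR/√n, type-7
quantiles — makes the Monte-Carlo resolution explicit). Within one
repetition the same seed drives all densities, so the per-density datasets
share their sources but are not channel subsets of a single recording.

Group statistics follow the study's recipe: per-channel paired t-tests
between schemes across subjects; two-tailed p-values from sign-flip
permutations (swapping the two references within a subject), 10,000 random
partitions with the add-one convention so p is never exactly 0 — or
exhaustive enumeration of all 2^n sign patterns when that is cheaper,
giving exact p. Identically-zero differences give t = 0 (identical
conditions), while a zero-variance non-zero shift leaves t undefined and
flagged. The FDR correction is Benjamini–Hochberg (the study names only
"fdr-corrected"); both uncorrected and corrected masks are reported
because the study is explicit about correction only for the global b_max
comparison.

## What replicates and what does not

With the spherical stand-in at 21 and 34 channels (100 repetitions,
complex-difference RE at (6, 10) Hz) the package reproduces, and its
acceptance suite asserts: Cz as the worst reference (median RE above 70%
for bicoherence, above 100% for cross-bicoherence); AVE above 30% and DLM
above 50% for cross-bicoherence; REST (matched model) best everywhere;
and AVE degrading with electrode density while Cz and DLM are
density-stable.

Three findings of the original study do *not* replicate under the
spherical substitution, and the corresponding acceptance assertions are
knowingly left failing rather than weakened. First, the study finds DLM
clearly worse than AVE; in the spherical model the two swap for
bicoherence and stay close for the connectivity measures. The mastoid
proxies sit on the equator of a brain-filling sphere where left/right
fields of the randomly placed deep sources partially cancel in the
mastoid average, whereas real mastoids sit below a cerebrum that is
entirely above them — the spherical geometry makes the mastoid reference
*too clean*. Second, the study reports antisymmetric cross-bicoherence
errors systematically above cross-bicoherence errors; here that holds for
every scheme except Cz, whose `cb` error is already saturated by the
strong vertex signal. Third, the mismatched REST model should err more
than the matched one; the perturbation's effect on the median RE (a few
percent of a ~12% median) sits below the Monte-Carlo resolution of a
100-repetition median, and at montage coverage the weakly identifiable
offset dominates both variants, so the contrast does not resolve. All
three deviations are geometry effects of the stand-in, not estimator
defects; they are discussed here so that a reader comparing numbers
against the original figures knows what to expect.

## Numerical choices, in one place

* Frequencies are addressed on the integer-Hz segment grid; off-grid
  requests are rejected, never interpolated.
* Hann windowing uses no amplitude correction: all reported quantities are
  ratios in which the window gain cancels.
* All-zero channels (e.g. the vertex after Cz-referencing) make the
  bicoherence normalization 0/0; the value is defined as 0 (warned once in
  user-facing calls, silent inside the experiment loop where it is an
  expected consequence of the Cz transform).
* The full-triplet tensors are accumulated as per-segment outer products
  (a Khatri–Rao product against the conjugated third slice); the result is
  contractually identical (< 1e-12) to the naive triple loop, which the
  tests enforce on small problems.
* Lead-field series truncation is decided per dipole so that superposition
  concatenates columns exactly; inner products in the solver avoid BLAS
  shape-dependent rounding for the same reason.
* Ties in the bicoherence scan resolve to the lowest `f1`, then lowest
  `f2`; `b_max` ties resolve to the lowest channel index.
* Seeds: every experiment derives per-repetition seeds from one master
  seed via R's generator; identical seeds give bit-identical results.

## Limitations

The spherical conductor, idealized montages and uniform source space are
stand-ins for realistic anatomy; absolute error levels shift with them
(the original study's realistic-model REST variants cannot be built
without the MRIs). The offset component of REST is weakly identifiable at
standard montages, as discussed. Only stationary, continuously coupled
sources are simulated; event-related or non-stationary designs are out of
scope, as are wavelet bispectra and alternative bicoherence
normalizations.
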