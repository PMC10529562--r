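---
title: "Integrating heterogeneous ECG databases for heartbeat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating heterogeneous ECG databases for heartbeat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgfuse)
```

## The problem

Annotated arrhythmia databases are individually too small and too imbalanced
to train a classifier over a fine-grained beat taxonomy: a single Holter
collection may hold two examples of one premature-beat class and seventy-five
thousand normal beats, while a second collection holds thousands of exactly
the class the first one lacks. Merging collections is the obvious remedy, but
the public databases disagree on everything that matters mechanically:
sampling frequency (360, 128 and 257 Hz for the three databases this package
targets), available leads, amplitude calibration and population. `ecgfuse`
implements a complete harmonization pipeline — beat extraction around
annotated R peaks, sampling-frequency unification, per-beat normalization,
label harmonization onto a 16-class scheme, stratified splitting — together
with two reference classifiers and an evaluation harness, plus a seeded
synthetic generator so that every stage is testable without any download.

## The beat window

All extraction is anchored on the annotated R peak. The window length follows
resting heart-rate physiology: at heart rate $f_{heart}$ bpm and sampling
frequency $f_{sample}$ Hz one beat spans

$$ \mathrm{numOfSample} = \frac{60 \, f_{sample}}{f_{heart}}, \qquad
   60 \le f_{heart} \le 100, $$

so the admissible per-beat sample count lies between $0.6\,f_{sample}$ and
$f_{sample}$. At the unified frequency of 360 Hz this gives the default
window $L = 260$ samples, split $M = \lfloor (L-1)/2 \rfloor = 129$ samples
before the peak and $N = L - 1 - M = 130$ after it. Beats whose window
crosses a record boundary are dropped and logged, never padded: a padded
fragment would contaminate the amplitude statistics the preprocessing
operators rely on.

```{r window}
numOfSample(100, 360)
splitWindow(260)
```

## Order of extraction and resampling

For a record sampled at a native frequency other than the 360 Hz target, the
default path extracts first and resamples second: a native-length window
$L_{nat} = \mathrm{round}(L \cdot f_{nat} / f_{target})$ is cut around each
R peak with the same centring rule, then each beat is Fourier-resampled to
exactly $L$ samples. This guarantees a fixed output length regardless of
rounding in the frequency ratio. The alternative (`path = "recordwise"` in
`extractBeats()`) resamples the whole record before cutting; both are
supported because annotation indices survive either order, and on clean
synthetic data the two paths agree to within resampling error.

Resampling itself is band-limited via the FFT (spectrum zero-padding or
truncation with Nyquist-bin splitting). This is exact for constant signals
and preserves content below the lower Nyquist frequency away from the record
edges; polyphase filtering is the other standard choice but its zero-padded
edges badly distort windows as short as a beat, which is why the Fourier
form is used here.

## The five preprocessing operators

With the beat matrix $A$ ($m$ beats $\times$ $n$ samples), four classical
operators act column-wise, i.e. per sample position over the beat
population: standardization $(a_{ij} - \bar a_{\cdot j}) / s_{\cdot j}$,
extremum (min–max) scaling onto $[0,1]$, division by the column mean, and
division by the column standard deviation. All standard deviations are
sample standard deviations (denominator $m-1$ column-wise, $n-1$ row-wise).

The fifth operator — per-beat *self-processing* — acts along rows instead:

$$ a'_{ij} = \frac{a_{ij} - \bar a_{i\cdot}}{s_{i\cdot}} . $$

Each beat supplies its own statistics, so the operator is invariant under
per-beat affine amplitude maps $\alpha x + \beta$ ($\alpha > 0$) — precisely
the gain and offset differences that separate recording devices and
databases — and it is idempotent. Column-wise standardization cannot remove
these differences: applied to a pooled two-database matrix it rescales every
column globally, leaving the between-database separation intact. This
algebraic contrast, not any filter, is what makes the merged database
trainable; the classical ECG noise processes (baseline wander below
~0.5 Hz, 50/60 Hz mains pickup, broadband electromyographic noise) are
deliberately *not* filtered here — they are modelled in the synthetic
generator so that tests exercise robustness to them.

Degenerate inputs are handled per operator: a zero-variance column is an
error naming the column (it indicates a broken extraction, not a bad beat);
a constant column under extremum scaling maps to 0 with a warning; a
flatline beat under self-processing is dropped and logged rather than
aborting a whole database build.

Column-wise operators need population statistics, which raises a leakage
question the pipeline makes explicit: `integrateDatabases()` leaves them
*pending* by default, and `stratifiedSplit()` fits them on the training
split only, applying the frozen statistics to the test split.
`pooledStats = TRUE` reproduces the pooled behaviour. Self-processing needs
no population statistics at all, which is an operational advantage of the
method: a single beat can be normalized at inference time with no reference
to any training distribution.

## Label harmonization and splitting

The default `"hercules16"` class map assigns the conventional
single-character beat codes (`N`, `L`, `R`, `A`, `a`, `J`, `S`, `V`, `F`,
`e`, `j`, `E`, `/`, `f`, `n`, `Q`) to 16 classes. Parent codes that subsume
retained classes — the generic bundle-branch-block code `B`, which contains
the retained `L` and `R` — are excluded to avoid duplicate labelling, as are
non-beat marks (rhythm changes, artifacts, signal-quality annotations). The
map ships as an editable table because annotation practice varies between
databases.

Splitting is stratified per class with an 80/20 default: a class of
$m_c \ge 2$ beats contributes $\max(1, \lfloor 0.2\,m_c \rfloor)$ test
beats (so every multi-member class is represented in the test set; a
floor-only rule would leave 2–4-member classes untested), singletons stay in
training. Assignment is a seeded within-class shuffle recorded in the
result, making every split exactly reproducible.

## The synthetic generator

Each of the 16 classes is a sum of five Gaussian bumps modelling the P, Q,
R, S and T waves (amplitudes in mV, centres in seconds relative to the R
peak, widths as Gaussian sigmas), with small per-beat amplitude and P/T
timing jitter. A five-Gaussian additive morphology was chosen over a
dynamical (ODE) ECG model because it gives fully controllable class
separation and an analytic R-peak location; the templates encode
textbook-style contrasts (absent/inverted P for escape and junctional
beats, widened R with discordant T for ventricular and bundle-branch-block
classes, early prominent P for atrial prematures) but make no claim of
clinical fidelity. All classes keep a positive dominant R bump so the
annotation invariant — the annotated index is a strict local maximum of the
clean signal — holds uniformly; after composing a beat train, each
annotation is snapped to the local argmax within ±20 ms, since neighbouring
Q/S/T bumps can shift the composite peak by a sample.

Each emulated database has a profile: sampling frequency (360/128/257 Hz by
default), an amplitude gain and offset (1.0/0, 1.2/−0.1 and 3.6/−0.3 — the
published per-database signal statistics show roughly a 3.5–4× amplitude
spread between the 12-lead Holter collection and the reference database),
mains frequency (60 Hz for the two US collections, 50 Hz for the European
one), baseline wander (0.2–0.5 Hz sinusoid, 0.05 mV), electromyographic
noise (white noise band-limited to 5 Hz–Nyquist, 0.02 mV), a 60–100 bpm
resting heart-rate range, and a class mixture. The default mixtures follow
the published per-database beat counts, including which classes each source
lacks entirely — the complementarity that motivates integration.

What the generator does *not* emulate: real QRS morphology variability
within a class, rhythm context (the classes are drawn i.i.d. from the
mixture), pathological noise bursts, electrode motion artifacts, or
inter-patient morphology drift. Passing tests on this corpus therefore
demonstrate that the *pipeline machinery* is correct and that the
normalization algebra behaves as claimed — not that the classifiers reach
any particular accuracy on real recordings.

## The reference classifiers

The 5-layer fully connected network takes the $L$ beat samples through an
input batch-normalization stage ("standardized in batches"), four hidden
layers of 256 rectified units with dropout 0.30, and a 16-unit softmax
output. The 12-layer 1-D residual network stacks three blocks with 64, 128
and 128 channels, each block three convolutions of kernel lengths 8, 5 and 3
(the time-series reading of the quoted square kernels), every convolution
followed by batch normalization and a rectifier, identity shortcuts with
1×1 projections where channel counts change, a strided 1×1 downsampling
convolution after each of the first two blocks, global average pooling and
a dense softmax layer. As usual, projection shortcuts are not counted in the
layer total (9 block convolutions + 2 downsampling + 1 dense = 12).

Both are trained with Adam (default learning rate 0.001, cross-entropy
loss, default budget 200 epochs, batch size 300, optional 30% validation
monitoring). Training is fully seeded — initialization, shuffling and
dropout masks all derive from the configuration seed — so runs are exactly
repeatable; both networks are implemented as plain seeded matrix code
(im2col convolutions), with gradients verified against finite differences
in the test suite. Early stopping is deliberately absent: the method trains
to a fixed epoch budget.

## Evaluation

`evaluateModel()` produces the confusion matrix (rows = true class),
per-class precision/recall/F1/support, overall accuracy, misclassified
count and macro averages. Macro recall and macro precision are the
"class-level" metrics of the preprocessing comparison — they weight each
class equally, which is the right lens for a corpus whose class sizes span
six orders of magnitude. Zero-support classes are excluded from macro
averages and flagged. F1 is defined as 0 when precision and recall are both
0. Printed tables round to 2 decimals; machine-readable output keeps full
precision. `comparePreprocessing()` re-runs integration, split, training
and evaluation once per operator with every seed held identical, so rows
differ only in the preprocessing; because the baseline rows of such
comparisons typically differ by fractions of a percent, results are
reported per seed rather than as a single number.
`holdoutDatabaseEval()` implements the inter-patient-style protocol: a
database never seen in training is processed with the identical window,
class map and preprocessing, and every extractable beat is scored.

## Problem sizes and numerical choices

The bundled studies run at desk scale: the test suite and the acceptance
script use an 8-class balanced three-database corpus of ~3,900 beats
(13 records × 100 beats per database) with the default noise levels, the
5-layer network and a 30-epoch budget — sizes at which the nearest-centroid
sanity oracle is perfect on clean data and the FC network exceeds 95% test
accuracy. Full-corpus reproduction (hundreds of thousands of beats, 200
epochs) uses the identical code paths via the same functions or the CLI
wrapper; only the sizes change.

Tolerances: normalization identities are asserted to 1e−10 in double
precision; softmax rows to 1e−6; WFDB amplitude round-trips to one
quantization step (1/gain mV, default gain 200 ADC units/mV, clipped to the
12-bit range ±10.24 mV). Annotation indices are 0-based internally and
converted at format boundaries. Ties in `max.col` cannot occur in practice
with continuous probabilities; the stratified split breaks ties by seeded
shuffle order.

## Known limitations

* WFDB support covers single-segment format-212 records and the MIT
  annotation stream — the subset the three target databases use; multi-lead
  formats 16/80, multi-segment records and waveform viewers are out of
  scope. A plain-text CSV/JSON fallback carries the same information.
* The published class scheme names 16 classes but not their annotation
  codes; the shipped code table follows the conventional WFDB mnemonics and
  is editable.
* Whether the original pipeline extracted beats before or after resampling
  whole records is not decidable from the published counts (they differ by
  44 beats out of ~109k); both paths are implemented and the beat-wise one
  is the default.
* Synthetic results transfer to real data only in the ways stated above;
  absolute accuracies on the real three-database corpus require the
  PhysioNet downloads and a full training budget.
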