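---
title: "Dual-domain local/global feature fusion for EEG artifact detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-domain local/global feature fusion for EEG artifact detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scalp EEG recorded during long-term monitoring of temporal-lobe epilepsy is
contaminated by artifacts: ocular (eye movements, blinks), myogenic (chewing,
sustained muscle tension, shivering) and technical (electrode steps, pops and
dropouts). Two of these — rhythmic chewing and stereotyped blinking produced
by ictal automatisms — are not nuisance signals at all: their presence is a
diagnostic clue. The task this package addresses is therefore not artifact
*removal* but artifact *classification*: given a fixed-length, single-channel
segment at 250 Hz, assign one of the labels CHEW, MUSC, ELEC, EYEM, SHIV, RC
(rhythmic chewing) or BLINK.

## The model

`build_model()` constructs a dual-branch network over two views of the same
segment $x(n)$:

**Time-domain branch.** A two-stage 1-D convolutional stack
(1→16 channels, kernel 8, stride 4; then 16→40, kernel 4, stride 2; each
followed by batch normalization, ELU and max-pooling of sizes 4/2 and 2/1)
produces the shallow local feature sequence $F_{\mathrm{CONV1Da}} \in
\mathbb{R}^{T\times 40}$ ($T = 59$ for 4-s segments). A transformer encoder
— 6 pre-norm layers, 5 heads, embedding 40, scaled dot-product attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with $d_k = 40/5 = 8$ — yields the
global features $F_{\mathrm{trans1}}$ of the same shape. A further kernel-3
convolution (40→40, batch-norm, ELU) over the transformer output extracts
deep local features $F_{\mathrm{CONV1Db}} \in \mathbb{R}^{(T-2)\times 40}$.

**Time–frequency branch.** The segment's STFT magnitude spectrogram
(Hamming window of 250 samples, overlap 200, one-sided, $\log(1+\cdot)$
compressed; 126 bins × 16 frames for 4 s) passes through a two-stage 2-D
stack (kernels (1,3) then (3,1), stride 1, with (2,2)/stride-1 max-pooling),
is flattened row-major over the spatial grid into a
$(H_{out}\cdot W_{out})\times 40$ sequence (1464 tokens at 4 s), encoded by a
second, independently weighted transformer of the same shape, and refined by
a (3,3) deep-local convolution ($T_2 = 1200$ tokens).

**Fusion and classification.** Within each domain the three sequences are
concatenated along the sequence (token) axis — they share the embedding
width 40, and concatenating along channels would contradict the
$T \times n$ shapes of the per-stage features — and mixed by a kernel-1
convolution ($T_3 = 175$, $T_4 = 4128$). The two domains are then
concatenated, time-domain first ($T_3 + T_4 = 4303$ tokens), flattened, and
classified by a 128-wide ELU layer with dropout 0.5 and a softmax output.
Cross-entropy is the training loss; Adam (learning rate $2\times 10^{-4}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) is the optimizer.

Ablation variants (`variant =` `"cnn"`, `"cnn_tf"`, `"cnn_tf_fusion"`,
`"cnn_tf_cnn_fusion"`) prune the time-domain pipeline back to the bare conv
stack; their trainable-parameter sets grow strictly monotonically up to the
full dual-domain model. Two alternative fusion strategies
(`fusion_strategy = "weighted"`, `"weighted_cnn"`) replace concatenation
with an MLP-attention weighted combination of the mean-pooled feature
groups.

### Choices the architecture description leaves open

Several hyperparameters are not derivable from the published architecture
description and are pinned here as package defaults:

- **Attention scaling.** The conventional per-head width $d_k = d_{model} /
  \mathrm{heads} = 8$ is used as the softmax temperature. (A reading in
  which $d_k$ equals the sequence length would make the divisor depend on
  the segment length and break the usual variance argument for the scaling;
  we treat it as an erratum.)
- **Positional encoding: none** by default. Self-attention then treats the
  token sequence as a set, and both encoders are permutation-equivariant —
  a property the test suite checks explicitly. Sinusoidal encoding is
  available behind `positional_encoding = "sinusoidal"`.
- **Feed-forward width 160** ($4\times d_{model}$, the standard transformer
  convention), pre-norm layer placement, and a final layer norm.
- **Deep-local convolutions**: 40→40 channels, kernels 3 and (3,3), stride
  1, no padding, batch-norm + ELU — the smallest kernels that refine local
  detail while preserving the embedding width for concatenation.
- **Classifier hidden width 128**, dropout 0.5.
- **2-D kernel order**: the parameter table's order ((1,3) on the time axis
  first, then (3,1) on the frequency axis) is the default because the
  canonical shape chain (126×16 → 122×12) follows from it;
  `conv2d_text_order = TRUE` swaps the two.
- **Initialization**: fan-in-scaled uniform weights, zero biases, unit
  batch-norm scale, all drawn from a `seed`-controlled generator, so that a
  freshly built model maps the zero segment to exactly uniform class
  probabilities and every run is bit-reproducible.
- **Short segments**: a 1-s segment yields a single STFT frame, too narrow
  for the (·,3) kernels, so when a spectrogram has fewer than 5 frames the
  2-D stages use "same" zero-padding along the time axis only. The same
  rule is applied to any individual 2-D stage whose input is narrower than
  its time-kernel (this is what lets the 2-s configuration, whose map
  reaches width 2 before the (3,3) deep-local convolution, build at all —
  required for the parameter-count comparison across segment lengths).
  Frequency-axis extents are always sufficient and are never padded.

### Numerical implementation

There is no deep-learning framework in the package's dependency set; the
forward pass, backpropagation and Adam are implemented directly in C++
(RcppArmadillo) in single precision. The time–frequency transformer runs
over 1464 tokens, so attention (score matrices of 1464²) dominates
compute; scores are formed transposed so the softmax runs down contiguous
columns, with a branch-free polynomial `expf` that auto-vectorizes.
Gradient correctness is verified in the test suite by comparing analytic
directional derivatives against central finite differences along a random
unit direction in parameter space. Batch normalization uses biased batch
variance with $\epsilon = 10^{-5}$ and running-statistic momentum 0.1;
layer norm uses $\epsilon = 10^{-5}$; softmax rows are max-shifted;
probabilities are clamped at $10^{-12}$ inside the loss. Argmax ties break
toward the lowest class index.

## Signal conditioning

`preprocess_recording()` applies, in fixed order: rational resampling to
250 Hz, 0.5–80 Hz band-pass, 50 Hz notch, annotation-driven interval
extraction (half-open sample spans, 0-based), non-overlapping segmentation,
and per-segment z-scoring.

- **Resampler**: the 256→250 Hz conversion uses the reduced factor 125/128 —
  a low-pass at the target Nyquist (windowed sinc, 81 taps), zero-insertion
  upsampling by 125, a Kaiser-windowed ($\beta = 8.6$) anti-aliasing sinc of
  length $10\cdot\max(125,128)$ taps evaluated in polyphase form, and
  decimation by 128. Each polyphase branch is normalized to unit DC sum so
  a constant input passes at exactly unity gain. Output length is
  $\mathrm{round}(N\cdot 125/128)$.
- **Band-pass**: order-4 Butterworth high-pass at 0.5 Hz cascaded with an
  order-4 low-pass at 80 Hz, each applied forward–backward (zero phase,
  effective order 8). The cascade is used instead of a single band-pass
  because an 8-pole transfer function with a 0.5 Hz edge at 250 Hz is
  numerically fragile in `b/a` form. Filtering uses odd-reflection padding
  (3 s) to suppress start-up transients.
- **Notch**: second-order IIR notch at 50 Hz, quality factor 30, zero-phase.
- **Z-scoring** (mean 0, SD 1, SD guarded at $10^{-8}$) is on by default:
  the classifier consumes shape, not absolute microvolt scale, and unscaled
  inputs destabilize optimization.

Each stage can be disabled independently, since public-corpus recordings
arrive already conditioned to an unknown degree.

## The synthetic artifact generator

`generate_dataset()` exists so that the entire pipeline — preprocessing,
training, evaluation — is exercisable with no access to clinical
recordings. Each class is given a morphology that reproduces the signatures
a neurophysiologist would name, over a 1/f ("pink") background EEG with an
8–12 Hz alpha component (relative power 0.3, RMS 15 µV nominal):

| class | morphology | default rate (Hz) | nominal peak (µV) |
|-------|------------|-------------------|--------------------|
| EYEM  | 0.5–2 Hz half-sine deflections, random polarity | 1.0 | 150 |
| BLINK | stereotyped biphasic transient (200–400 ms) repeating in a 1–3 Hz train | 2.0 | 150 |
| CHEW  | 20–60 Hz EMG bursts, onsets jittered ±30% of the period | 1.5 | 80 |
| RC    | the same bursts with strictly periodic onsets | 2.0 | 80 |
| MUSC  | sustained broadband 20–80 Hz noise | — | 80 |
| ELEC  | step, impulse ("pop") or flat-line dropout, subtype uniform | — | 300 |
| SHIV  | ~10 Hz sinusoidal bursts | 1.0 | 60 |

The zero jitter of RC versus the ±30% jitter of CHEW is the operational
definition of "rhythmic": the published distinction is clinical, not
quantitative, so these waveform parameters are plausible stand-ins, not
claims about clinical data. Artifacts are scaled to the requested
signal-to-background ratio (`snr_db`); amplitudes above set the within-class
morphology. Per-segment seeds are an integer hash of (master seed, class,
index), so any subset of a dataset regenerates identically. The separability
of the taxonomy is itself tested: a fixed band-power/envelope-periodicity
decision rule classifies ≥ 90% of segments at 10 dB, which guarantees the
learning task the generator defines is solvable.

What the generator does **not** emulate: volume-conduction mixing across
channels, non-stationary background (sleep stages, drowsiness), co-occurring
artifacts, electrode-dependent spectra, and the enormous within-class
variability of real clinical data. A model that learns these synthetic
classes has demonstrably learned the intended spectral/temporal contrasts —
nothing more. Accuracies on this data say nothing quantitative about
performance on clinical corpora.

## Training protocol and evaluation

`stratified_kfold()` deals each class's shuffled indices round-robin into
5 folds; each fold's train:test split is then exactly 8:2, which is the one
reading under which a fixed "8:2 ratio" and "five-fold cross-validation"
are consistent — there is no additional held-out set. Within a fold's
training portion, 10% is held out for epoch selection: training runs Adam
(2e-4, 0.9, 0.999) over seeded shuffled mini-batches and restores the
weights of the epoch with the lowest held-out loss. Early stopping is
controlled by `early_stop_patience`; metrics follow the one-vs-rest
convention: per-class Accuracy $=(TP+TN)/(TP+TN+FP+FN)$, Recall
$=TP/(TP+FN)$, F1 $=2TP/(2TP+FP+FN)$, macro-averaged across classes, plus
overall (multi-class) accuracy. Zero-denominator metrics are reported as 0
with a warning.

### The reference desk-scale experiment

The package's standing end-to-end experiment — the one the acceptance
script and the acceptance tests re-run — uses the 6-class private-style
vocabulary (CHEW, MUSC, ELEC, EYEM, RC, BLINK) at 4 s, 250 Hz and 10 dB,
with 16 segments per class, 5-fold CV, batch size 8 and 8 epochs per fold.
These sizes are the package's chosen configuration for a single-CPU run:
the dual-domain model performs attention over 1464 tokens in 6 layers for
every sample, so sample-steps are expensive, and 16×6 segments over 8
epochs is the point where the full cross-validation completes in roughly a
quarter of an hour while reliably converging on the synthetic task. The
batch size is necessarily smaller than the nominal 200 of the full-scale
protocol because a desk-scale training fold only contains ~77 segments.
All other protocol elements (optimizer, learning rate, split geometry,
metrics) are unchanged. The same experiment defines the ablation
comparison: the five seeded fold models of the full network versus the
CNN-only variant trained under the identical protocol on the identical
splits. The comparison checks the *direction* of the ablation effect, not
its published magnitude — desk-scale accuracies on synthetic data are not
comparable to corpus-scale accuracies on clinical data, and both models
must be trained to convergence for the comparison to be meaningful (an
undertrained dual-domain model loses to the fast-converging CNN baseline).

Determinism: with fixed seeds the whole chain — generation, splits,
initialization, shuffling, dropout, training arithmetic — is bit-exact on
a given platform, and the suite verifies that re-running a CV fold
reproduces its metrics identically.

## Known limitations

- Single-channel: no spatial (montage) modeling.
- The synthetic generator's realism limits, listed above.
- Training throughput is bounded by single-threaded dense algebra over
  1464-token attention; corpus-scale replication of the published
  experiments is out of reach on one CPU and out of scope.
- Checkpoints store weights in double precision RDS; inference after
  reload is bit-identical, but optimizer state is not preserved across
  save/load (checkpoints are for inference and evaluation, not for
  resuming training).
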