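---
title: "Simulating nanopore current signals with a trainable BiGRU filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nanopore current signals with a trainable BiGRU filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigglesim)
```

## The simulation model

Oxford Nanopore devices read DNA by measuring the ionic current through a
pore while a motor protein ratchets the strand through it. At any instant
the current level is set mainly by the six bases occupying the pore, so a
*6-mer pore model* — a table mapping each of the $4^6 = 4096$ 6-mers to an
expected current level in pA — converts a nucleotide sequence
$X = x_1,\dots,x_T$ into its expected signal $Y = y_1,\dots,y_{T-5}$, one
level per overlapping 6-mer window.

The strand translocates at roughly 450 bases/s while the current is sampled
at 4 kHz, so each 6-mer is measured 8–9 times on average. The number of
samples per 6-mer (the *repeat time* or dwell) fluctuates with the motor
protein; empirically it follows a mixture of alpha distributions. Repeating
each $y_i$ for its sampled dwell produces the square-wave *ground-truth
signal*. Real pores do not produce square waves: the measured signal is
rounded at level transitions and buried in noise. The package therefore
post-processes the ground truth in one of two ways before adding i.i.d.
Gaussian noise (default sd 2 pA, uncorrelated in time):

* **Low-pass baseline** — convolution with a Blackman-windowed sinc kernel
  (129 taps, 950 Hz cutoff at 4 kHz). This is the classical approach; it
  attenuates *all* content above the cutoff, including structure that real
  signals retain.
* **BiGRU filter** — a three-layer bidirectional GRU with a per-time-step
  fully connected head, trained on aligned (ground-truth, real) signal
  pairs, which learns *where* to smooth instead of smoothing everywhere.

## The GRU cell as implemented

With hidden state $h$ and input $x$ (concatenation order $[h, x]$):

$$z_t = \sigma(W_z[h_{t-1}, i_t] + b_z), \quad
  r_t = \sigma(W_r[h_{t-1}, i_t] + b_r)$$
$$h'_t = \tanh(W[r_t \circ h_{t-1}, i_t]), \quad
  h_t = (1 - z_t) \circ h_{t-1} + z_t \circ h'_t$$

Two details are worth calling out because they differ from the GRU found in
the major deep-learning frameworks. First, the update gate $z_t$ here
weights the **candidate** state, with $1 - z_t$ on the previous state (the
framework convention is the reverse); the two parameterisations are
equivalent up to relabelling, and we keep this form because it is the form
the model is defined in. Second, the candidate path has **no bias term**.
The `candidate_bias` switch (default off) restores the framework-standard
bias for users who want it; both variants are covered by the oracle tests.

The bidirectional layer runs the cell left-to-right and right-to-left from
zero initial states and concatenates the two hidden states at each step,
$h_t = h^f_t \,\|\, h^r_t$, so each output value sees the whole read. Three
such layers are stacked (layer 1 reads the scalar signal, layers 2–3 read
the $2d$-wide states), and a fully connected head maps each final state to
one output sample, preserving length exactly.

The hidden size is not fixed by the model definition; the constructor
default is $d = 64$ per direction, and the desk-scale experiments in the
test suite use $d = 16$, which is already enough to learn
transition-localised smoothing.

## Training

Training pairs $(I, R)$ — normalized ground truth and its aligned real (or
synthetic target) signal — are cut into non-overlapping windows of 512
samples (a final remainder shorter than 256 samples is discarded, longer
remainders are zero-padded under a mask), shuffled, and grouped into
batches of 128. The loss is Log-Cosh, $\sum_i \log\cosh(o_i - r_i)$:
quadratic near zero, linear in the tails (asymptotically $|x| - \log 2$),
computed overflow-safely. The optimizer is Adam with learning rate $10^{-4}$
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$); weights start
from Xavier-uniform draws bounded by $\sqrt{6/(n_i + n_o)}$ and biases from
zero. "Iterations" count optimizer steps, not epochs; the per-batch loss is
the *mean* over valid (unmasked) positions so that the window length does
not rescale the learning rate, while `log_cosh_loss()` itself exposes the
plain sum. Backpropagation through time is hand-derived and verified
against central finite differences to ~$10^{-10}$ in the test suite; the
whole loop is deterministic given the seed.

## Signal labeling

Supervised pairs for real data require mapping each raw sample onto the
expected signal. `label_read()` does this with classical dynamic time
warping under local cost $|a_i - b_j|$ (steps diagonal/down/right, ties
broken diagonal-first, then toward consuming the raw signal), both signals
z-scored first. Because the raw signal's per-read statistics weight each
level by its dwell, independently z-scored signals differ by a small affine
error; one refinement pass re-estimates the affine map from the first
alignment by least squares and re-warps, which removes boundary slippage
(noise-free expansions are then recovered exactly, and ~96% of positions
under noise of sd 0.1 in normalized units). When a raw sample matches
several expected positions, the first is kept — a declared convention, as
is the diagonal-first tie-break, both needed for reproducible pairs. For
very long reads (over 50k samples) the warp is restricted to a Sakoe–Chiba
band of radius 1000 around the length-scaled diagonal; at desk scale the
exact dynamic program is used. The multi-scale seeding used by
continuous-wavelet DTW implementations for very long reads is intentionally
out of scope. Note that `label_read()` assumes the matching sequence
fragment is known; basecalling and genome alignment, which provide it for
real reads, are external steps.

## Evaluation measures

Two similarity measures compare simulated to target signals:

* **Normalized DTW**: total warp cost divided by the number of path steps.
  Path-length normalization is the convention that makes reads of different
  lengths comparable; signals are z-scored internally, so the measure is
  affine-invariant.
* **CWT spectrum correlation**: magnitudes of a Morlet ($\omega_0 = 6$)
  continuous wavelet transform over 64 log-spaced scales spanning pseudo-
  frequencies from $f_s/N$ to $f_s/2$ (Torrence–Compo frequency-domain
  evaluation), compared by Pearson correlation — overall and split into
  low- and high-frequency halves at 450 Hz, the base-translocation rate,
  separating level-transition content from within-level content. The split
  frequency, scale grid and normalization are declared package choices.

## The synthetic data generator

`make_dataset()` substitutes for real sequencing runs so the whole pipeline
is testable offline. Per read: a uniform random sequence (default 500
bases), a synthetic pore model (all 4096 6-mers, levels uniform in 60–120
pA — pseudo-random stand-ins, not measured currents), dwell counts from the
default mixture-alpha model, and a target built by smoothing the normalized
square wave *only at transitions* (triangular kernel, default 5 taps) plus
Gaussian noise (default sd 0.15 in normalized units, so difficulty is
independent of the pore-model scale). Transition-only smoothing encodes the
qualitative way real signals differ from the square wave and is precisely
what a global low-pass filter cannot reproduce — which is what gives the
trained network a measurable advantage and makes the comparison testable
synthetically.

The default dwell mixture (weights 0.7/0.3; shapes 4 and 3, locations 1 and
2, scales 28 and 18; counts rounded half-to-even and clamped to $[1, 40]$)
was calibrated once to a clamped-rounded mean of ~8.7 samples per 6-mer —
the 450 bp/s / 4 kHz regime — with a right-skewed dwell distribution
(median 8, 99th percentile ~20). An alpha variate is drawn exactly as
$\mathrm{loc} + \mathrm{scale}/(a - Z)$ with $Z$ standard normal truncated
below $a$ via inverse-CDF.

What the generator does **not** emulate: per-6-mer heteroscedastic noise,
baseline drift, stalls, adapter signal, or real pore chemistry. Passing the
synthetic end-to-end test shows the machinery (labeling, training,
evaluation) works and that the network can learn transition-localised
structure; it does not certify accuracy on real flowcell data, which
requires training on real (ground-truth, raw) pairs prepared with
`label_read()`.

## Desk-scale experiment sizes

The test suite's end-to-end experiment uses 250 synthetic reads of 500
bases (200 train / 50 held out), hidden size 16 and 300 Adam steps — sizes
chosen so the full suite runs comfortably on a single CPU while leaving the
qualitative conclusions intact: training loss falls by an order of
magnitude, the held-out loss beats both the copy baseline and 0.6× the
initial loss, and the trained network's output is closer to the target in
normalized DTW than the raw ground truth on every held-out read, with its
corrections concentrated at 6-mer transitions.

## Numerical and design notes

* Repeat-count rounding is nearest-integer with ties to even; clamping
  bounds guard the alpha distribution's heavy upper tail (its mean is
  otherwise undefined).
* Z-score normalization is per read; constant signals are rejected rather
  than silently passed through. The BiGRU simulation path denormalizes its
  output with the ground-truth signal's statistics.
* The low-pass kernel is normalized to unit sum (exact DC gain), and edge
  effects are handled by replicating the first/last sample, so constants
  are fixed points of the filter. The half-gain frequency of the default
  kernel sits within a few Hz of the 950 Hz design cutoff, as windowed-sinc
  theory predicts.
* DTW ties are resolved deterministically, so labeled pairs are bit-stable.
* All randomness flows through explicit `seed` arguments that save and
  restore the caller's RNG state; identical seeds give bit-identical
  datasets, fits and simulations.
* Ambiguity codes (N, IUPAC) are rejected rather than sampled.
* Checkpoints are versioned JSON — plain text, diffable, and exact to
  double precision.
* Signal files are written as TSV (one float per line with `# key=value`
  headers). A fast5-style HDF5 writer is not provided.

## Limitations

The package trains and evaluates at whatever scale the supplied pairs
support, but the shipped defaults are desk-scale. Reproducing
flowcell-grade simulation additionally needs a real ONT pore-model table
(the synthetic stand-in is reproducible but not physical), real raw reads
with their sequence fragments, and a correspondingly larger network and
iteration count. Read-level error profiling through a basecaller is out of
scope.
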