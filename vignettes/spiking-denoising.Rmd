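---
title: "Denoising images with a fully spiking network and bit-plane spike coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising images with a fully spiking network and bit-plane spike coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtsnn)
```

## The model

Spiking neural networks communicate through binary events over discrete time
steps, which makes them attractive for low-power hardware but awkward for
image reconstruction: pixel intensities must become spike trains and spike
trains must become pixels again, and most codings lose information in the
round trip. This package implements the *virtual temporal* approach: a static
n-bit image is expanded into its n binary bit planes, ordered from most to
least significant, and that ordered stack is treated as a spike sequence — a
temporal dimension manufactured from significance rather than from real event
timing.

**Codec.** `uweEncode()` performs the bit-plane expansion by successive
subtraction of powers of two (the exact digital behaviour of a
successive-approximation ADC); `uwdDecode()` contracts the plane dimension
with the weight vector $(2^{T-1}, \dots, 2^0)$ via the tensor n-mode product
(`nModeProduct()`). The pair is exactly lossless for every integer image —
the package's central invariant, tested exhaustively. Two lossy comparison
codecs are included: time-to-first-spike (`ttfsEncode()`), which maps
intensity to spike latency and collides distinct values once latencies are
quantised to $T < 2^n$ steps, and membrane-potential decoding
(`mpdDecode()`), a geometrically weighted ($\theta = 0.8$) spike sum squashed
through $\tanh$, bounded in $(-1,1)$ and therefore never exact.

**Neurons.** `neuronStep()` implements discrete integrate-and-fire dynamics:
charge ($u \leftarrow u + x$ for IF, $u \leftarrow u + (x-u)/\tau$ for LIF),
fire where $u \ge V_{th}$, then *soft reset* ($u \leftarrow u - V_{th}$ on
spiking units). Three conventions deserve a note:

* **Heaviside tie-break.** A potential exactly at threshold fires
  ($h(0)=1$). This is stated once and used everywhere, including the
  identity-initialised head described below, which depends on it.
* **Leak form.** The multiplicative gate formulation
  $u_{t+1} = u_t\,g(o_t) + x_{t+1}$ with $g=\tau$ (IF) or
  $g = \tau e^{-o/\tau}$ (LIF) *amplifies* the carried potential whenever
  $\tau > 1$, which contradicts the notion of a leak; we therefore implement
  the standard discrete forms above and keep the multiplicative gate behind
  `neuronConfig(literalGate = TRUE)` for forward-only study.
* **Surrogate argument.** The surrogate derivative
  $1/(1 + (\pi v)^2)$ is evaluated at $v = u - V_{th}$, so it peaks exactly
  at the firing boundary; training uses a single surrogate factor per layer
  in the chain rule.

**Network.** `buildUVTSNN()` assembles a shallow U-net in which *every*
nonlinearity is a spiking neuron and every convolution is bias-free, so all
inter-layer traffic is binary. Down-sampling is a stride-2 convolution (a
pooling layer would also work, but a strided convolution keeps the whole
network learnable and spike-in/spike-out); up-sampling is nearest-neighbour
— the only interpolation that preserves binarity — followed by a convolution
and neuron; skips concatenate spike planes rather than adding them, since
addition could produce non-binary values outside a neuron's charging path.
Body neurons use $V_{th} = 1.0$; the 1×1 head uses $V_{th} = 0.077$, a
deliberately low threshold that lets output spikes form readily. The default
(depth 2, 16 base channels) has 115,360 parameters, close to the 0.12 M
operating point used for the energy accounting; exact reference channel
widths are not recoverable, so the architecture is calibrated to that
parameter count and fully configurable.

**Input skip and identity initialisation.** The raw input plane is
concatenated onto the last decoder features (`inputSkip = TRUE`), and the
head's skip weight is initialised to exactly $V_{th}$ of the head neuron with
zero feature weights. An input spike then charges the head to precisely
$V_{th}$, fires (by the $h(0)=1$ tie-break) and the soft reset clears the
full charge — the untrained network reproduces its input bit-for-bit at
every step. Training therefore starts from the identity reconstruction and
learns corrections, the standard shortcut design for denoising networks.
The constant must be $V_{th}$, not 1: a unit weight leaves a residual
$1 - V_{th}$ above threshold after the soft reset and the head would keep
firing on its own momentum.

## Training regimes

Two loss/backpropagation regimes are implemented in `trainStep()`:

* **ITBP (independent-temporal).** The clean label is bit-plane *encoded*
  and the loss is the significance-weighted squared error
  $\frac1N\sum_{s} 2^{s}\lVert o_s - \hat o_s\rVert_F^2$ (`itbpLoss()`).
  Gradients flow through the spatial path of each time step only: the
  membrane state carried between steps is treated as a constant. The test
  suite verifies this *defining* property against an independent oracle that
  recomputes every step in isolation from stored states with naive
  convolutions — agreement to below $10^{-6}$ relative error.
* **STBP (spatio-temporal).** The output stack is decoded by the
  (differentiable) weighted sum, the loss is the plain MSE against the clean
  image (`stbpLoss()`), and gradients flow through both space and time —
  through the carried potentials and the soft-reset path.

Optimisation uses Adam at learning rate 0.001 with the standard published
moment defaults, batch shuffling from the training seed, and no
learning-rate schedule. All computation is CPU-deterministic: a fixed
`TrainConfig` seed reproduces loss trajectories bit-for-bit.

Codec and regime vary independently: `trainConfig(inputCodec = "ttfs")`
spike-codes the noisy input by latency instead of bit planes, and
`trainConfig(stbpDecoder = "mpd")` swaps the STBP loss decoder for the
tanh-squashed geometric readout (compared against the clean image on the
unit scale, with gradients through the tanh). Evaluation always follows the
inference pipeline — bit-plane encode, forward, weighted-sum decode — which
is also how the independent-temporal regime is used at test time: labels are
encoded only during training, outputs are decoded only during testing.

## Synthetic data

`generateSynthetic()` draws 8-bit images with the gross statistics of
handwritten-glyph datasets: a dark background crossed by 2–4 bright strokes
(line segments and circular arcs of ~1–1.6 px Gaussian cross-section,
intensities 180–255), lightly smoothed and re-quantised. Noise follows the
protocol of the denoising study: i.i.d. zero-mean Gaussian noise of standard
deviation $\eta$ on the unit scale, clipped to $[0,1]$ and re-quantised to
8 bits (`addGaussianNoise()`). We read $\eta$ as a standard deviation rather
than a variance: as a variance, $\eta = 0.8$ would mean $\sigma \approx 0.9$
— pure noise — inconsistent with any reported reconstruction quality at that
level.

What the generator does *not* emulate: the class structure, stroke topology
and centring of real handwritten digits, texture, or natural-image
statistics. Passing the desk-scale study below therefore shows that the
pipeline trains and denoises structured images under the stated protocol; it
does not certify accuracy figures on any real dataset.

## The desk-scale study

The package's self-contained study (run by `scripts/acceptance.R` and
mirrored in the test suite) trains the *tiny* configuration — depth 1,
8 base channels, IF neurons, $T = 8$, 5,840 parameters — on 500 synthetic
28×28 images at $\eta = 0.2$ for 5 epochs, then evaluates on 100 held-out
images. Batch size is 10: the reference protocol's batch of 50 is tuned to a
60,000-image corpus, and keeping roughly the same updates-per-image ratio on
500 images calls for a proportionally smaller batch. Both regimes run under
an identical budget, and the study reports the mean PSNR of the noisy
inputs, of the ITBP reconstruction, and of the STBP reconstruction. These
sizes keep a full study within a few minutes on one CPU core while remaining
large enough for the PSNR ordering to be stable under the fixed seed.

## Numerical choices and degenerate inputs

* Integer images are validated, never clipped: out-of-range or fractional
  pixels raise errors (silently clipping would break the lossless claim).
* TTFS latency $t = (\max x - x)/\max x \cdot T$ is non-integer; the default
  rounding is `floor` (configurable to `nearest`), and a rounded latency
  $\ge T$ falls outside the window and emits no spike. The all-zero image
  has no defined maximum-relative latency: it encodes to no spikes, with a
  warning.
* PSNR uses peak $2^n - 1$; identical images report `Inf` rather than a
  division error.
* Energy accounting reports in units of $10^{-7}$ J with two-decimal
  rounding, and the headline ANN/SNN ratio is taken between the *rounded*
  energies, the printable quantities; the spiking slot count is the total
  number of neuron-time slots, so spiking energy is
  slots × rate × 0.9 pJ.
* The spatial size must be divisible by $2^{\text{depth}}$; the forward pass
  refuses other sizes with a suggestion to pad, rather than silently
  resampling.

## Known limitations

* Training is CPU-bound R/BLAS; desk-scale corpora (hundreds of images)
  train in minutes, but full 60,000-image datasets require patience or a
  port of the convolution kernels to a GPU framework.
* Multi-channel input is supported structurally (`inChannels`), but the
  bundled data tooling is grayscale-first.
* The energy model is the standard event-driven idealisation: it prices
  activation events only, excludes convolution MACs on both sides, and
  assumes zero cost for silent slots; it is a comparative, not an absolute,
  measure.
```
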