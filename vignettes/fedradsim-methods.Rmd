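---
title: "Methods: federated learning simulation for multi-institutional radiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated learning simulation for multi-institutional radiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedradsim)
```

# The problem this package models

Multi-institutional radiological AI faces a three-way tension: models need
diverse training data, regulations forbid pooling patient images, and the
parameter updates that federated learning exchanges instead of images are
themselves an attack surface. `fedradsim` is a self-contained laboratory for
this tension. Everything — data, training, attacks, scoring — runs in
seconds on one CPU, so every claim the package makes is re-derivable by
running it.

This vignette documents the models and their assumptions, the tunable
parameters, what the synthetic generator does and does not emulate, the
numerical choices, and the design decisions taken where the design was
genuinely open.

# The federation model

The protocol is a synchronous star: at round $t$ the server broadcasts the
global parameters $w_t$; each client $k$ runs $E$ local epochs of Adam on
its own training split; the parameter deltas travel back; the server
aggregates. Three aggregation rules are implemented.

**Sample-size weighting (FedAvg).**
$w_{t+1} = \sum_k \frac{n_k}{n} w_k^{(t+1)}$, the reference rule.

**Proximal regularization (FedProx).** Clients minimize
$F_k(w) + \frac{\mu}{2}\lVert w - w_t \rVert^2$, tethering local iterates to
the current global model; useful when clients drift under heterogeneity.
Default $\mu = 0.01$.

**Confidence weighting.** The server computes
$w_{\mathrm{global}} = \frac{\sum_i \alpha_i c_i w_i}{\sum_i \alpha_i c_i}$
with $\alpha_i = n_i / n$ the data-quantity weight. Two sources for the
confidence $c_i$ are provided and never combined implicitly:

- `confidence_source = "softmax"` (default): per-round weights
  $\omega_k \propto \exp(\mathrm{AUC}_k / \tau)$ from each client's local
  validation AUC. The temperature $\tau$ (default 0.5) interpolates between
  hard selection of the best client ($\tau \to 0$) and plain uniform
  averaging ($\tau \to \infty$); both limits are asserted in the tests.
- `confidence_source = "composite"`:
  $c_i = \omega_1\,\mathrm{acc}_i + \omega_2\,\mathrm{div}_i +
  \omega_3\,\mathrm{qual}_i$ with the component weights optimized
  server-side. During a warm-up (rounds 1–10) the weights stay uniform at
  $1/3$; afterwards each round takes one projected-gradient step
  $\omega \leftarrow \Pi_{\Delta}(\omega - \eta_\omega \nabla L_{val})$ with
  $\eta_\omega = 0.01$, the gradient estimated by central finite differences
  along simplex-tangent directions, and $\Pi_\Delta$ the exact
  sorting-based Euclidean projection onto the probability simplex.

How the diversity metric $\mathrm{div}_i$ should be computed is not a
settled question; the package uses the Shannon entropy of the node's label
distribution normalized to $[0,1]$ and exposes it as a pluggable statistic.
The quality metric $\mathrm{qual}_i$ defaults to 1 and can be attached to a
node (attribute `quality`) by pipelines that estimate, e.g., annotation
consistency.

The `centralized` method pools all training data into a single node and
runs the same loop with the same gradient-step budget, so the $K = 1$
federated run reduces to it exactly — a deliberate construction that turns
the single-client sanity check into an identity. Adam moments are reset at
each round on the client (optimizer state never travels); this makes one
full-batch FedAvg round on identical clients exactly one centralized
full-batch step, the second identity the tests verify to 1e-10.

**Local learner.** The default learner is multi-label logistic regression on
flattened, bilinearly-downsampled image features (default 16×16 = 256
features). This choice is deliberate: it is convex, exactly reproducible,
fast enough for multi-seed experiments, and sufficient for every
protocol-level claim (aggregation algebra, privacy directionality,
heterogeneity robustness), which concern the *federation*, not the backbone.
The tiny convolutional model (below) is used where spatial structure
matters.

**Defaults.** $E = 5$ local epochs, $T = 50$ rounds, Adam with learning rate
$3\times10^{-4}$ and $(\beta_1, \beta_2) = (0.9, 0.999)$, batch size 32,
weight decay $10^{-4}$, cosine-annealed learning rate, $\tau = 0.5$. The
desk-scale experiments in the tests and the acceptance script shrink $T$ to
12–15 rounds and raise the learning rate to 0.05, appropriate for the small
convex learner; the vignette states these sizes as the package's chosen
desk-scale conditions.

**Convergence detection.** No single convention exists for "rounds to
convergence"; the package uses a plateau rule: the first round whose global
validation AUC is within `tol = 0.001` of the maximum over the following
`window = 5` rounds, falling back to the last round for curves still
rising. A flat curve converges at round 1; a strictly rising curve never
does.

**Communication accounting.** Each round counts one upload per client
(`bytes_sent`) and one broadcast (`bytes_broadcast`), logged separately
because total-bandwidth figures conventionally count uploads only:
`comm_cost(94.3, 47, 4)` gives 94.3 MB/round and 17.7 GB total. A 4:1
gradient-compression ratio is applied when the payload is given
uncompressed.

# Losses

The composite segmentation loss is
$L_{seg} = \lambda_1 L_{BCE} + \lambda_2 L_{Dice} + \lambda_3 L_{prior}$
with default weights $(0.3, 0.5, 0.2)$.

- $L_{BCE}$ is the pixel-wise binary cross-entropy summed over the $A$
  structure channels and normalized by $H \cdot W$. The printed form of this
  loss in the literature shows the $1/(HW)$ normalizer without a channel
  sum; summing over channels keeps the $\lambda$ weights meaningful for any
  $A$ and reduces to the textbook form at $A = 1$.
- $L_{Dice} = 1 - \frac{2\sum S\hat S + \epsilon}{\sum S + \sum \hat S +
  \epsilon}$ with $\epsilon = 10^{-6}$, robust to the extreme
  foreground/background imbalance of small structures.
- $L_{prior} = \frac{1}{HW}\sum_{ij} \lVert \hat S_{ij} \odot (1 - P_{ij})
  \rVert^2$ penalizes confident predictions exactly where the anatomical
  atlas $P$ assigns low probability. The atlas is the per-pixel frequency of
  each structure over a reference set of cases (`build_prior_atlas()`).

Classification uses the focal loss
$-\mathrm{mean}_m\, w_m (1 - p_t)^\gamma \log p_t$ with $\gamma = 2$ and
inverse-class-frequency weights $w_m$ normalized to mean 1; absent classes
are capped at ten times the largest observed weight rather than producing
infinities. At $\gamma = 0$ with unit weights this is exactly the mean
binary cross-entropy, which the convex experiments use.

All probabilities entering a logarithm are clamped to
$[10^{-7}, 1 - 10^{-7}]$. Every loss ships with an analytic gradient
verified against central finite differences at $10^{-4}$ relative
tolerance.

# The tiny model and explainability

The differentiable backbone is intentionally minimal: two 3×3 convolution
stages (widths 4 and 8) with a 2×2 average pool between them, a
classification head, and a 1×1-convolution segmentation head with bilinear
×2 upsampling, sigmoid everywhere. The full backward pass is hand-derived
and finite-difference checked.

Three design points deserve explanation, because each was forced by an
observed failure of the obvious choice:

**Log-sum-exp spatial pooling.** A classification head over globally
*average*-pooled features cannot detect a small focal finding: a ~4-pixel
blob is diluted 30:1 against the anatomy. A global *max* head fails
differently — on near-identical positive/negative pairs the max sits at the
same (uninformative) pixel for both, and its gradients cancel. The head
therefore scores every position with a 1×1 linear map and pools the score
map with log-sum-exp (sharpness 8), the standard construction in weakly
supervised chest-radiograph localization: gradient mass concentrates
exactly on the positions where activations differ.

**Structured initialization.** A randomly initialized two-layer trunk does
not express "locally bright region within a dark field" discriminably, and
200 optimization steps cannot make it do so. The default initialization is
therefore a fixed-feature trunk in the scattering-network spirit:
Gaussian-blur filters with a ladder of negative biases (smoothed intensity
thresholds after rectification) in stage one, identity and center-surround
(Laplacian) pass-throughs in stage two. Heads are random $N(0, 0.1)$.
`init = "random"` remains available.

**Group standardization is a shortcut channel.** Per-group feature
standardization (group size 32, capped at the layer width; batch statistics
are never used) stabilizes end-to-end training at small local batch sizes.
But it also couples every activation to image-global statistics: in our
localization experiments a high-capacity head learned to separate classes
by reading border pixels whose values shift with the global normalizer —
0/15 pointing-game hits, versus 10/15 with standardization disabled, under
otherwise identical training. Standardization is kept (default on) but
exposed as `normalize`; spatial-attribution experiments disable it and
train the heads on the frozen trunk. This is a small, reproducible instance
of shortcut learning worth knowing about when interpreting any saliency
result.

Grad-CAM weights each last-stage feature map by the spatially averaged
gradient of the target-class logit (which for the LSE head equals
$\mathrm{cls\_w}_{ck}/H'W'$ exactly), rectifies the sum at zero, upsamples
bilinearly, and min–max normalizes; an all-zero map is returned unchanged.
Localization is scored by Attention IoU (heatmap binarized at 0.5,
configurable) and the pointing game (argmax pixel, first in row-major order
on ties, inside the annotation).

Channel dropout ($p = 0.3$) applies to the trunk features before the
classification head at train time only, with inverted-dropout scaling.

# Differential privacy and the attack battery

Local DP follows DP-SGD mechanics: each example's gradient is clipped to L2
norm $C$ (default 1.0), the lot mean is taken, and a single Gaussian draw
with per-coordinate sd $\sigma C$ (noise multiplier $\sigma$, default 1.1)
is added per lot — the literal reading of the canonical update, with the
noise outside the $1/L$ average. For the logistic learner the per-example
clipping is computed in closed form, so DP training is vectorized.

The accountant reports both basic composition $(T\varepsilon, T\delta)$ and
the advanced bound
$\varepsilon' = \varepsilon\sqrt{2T\ln(1/\delta')} +
T\varepsilon(e^\varepsilon - 1)$, with the tighter value as headline.
The classical Gaussian-mechanism calibration
$\sigma = \sqrt{2\ln(1.25/\delta)}\,\Delta/\varepsilon$ (valid for
$\varepsilon < 1$) is provided separately. Published configurations pair
$\sigma = 1.1$ with differing $(\varepsilon, \delta)$ claims; the package
treats all of these as configuration inputs and always reports the
$\varepsilon$ it computes, never an asserted pairing.

Two attacks are implemented, both standard literature baselines chosen
because the attack procedures behind published defended/baseline tables are
typically unspecified:

- **Loss-threshold membership inference**: split member and non-member sets
  into calibration and evaluation halves, pick the loss threshold
  maximizing balanced accuracy on calibration, report balanced accuracy (%)
  on evaluation. A non-overfit model sits at chance (50%); an overfit one
  is readable.
- **Gradient-matching reconstruction** (gradient-leakage / model-inversion
  family): Adam on a dummy image (and continuous dummy label) minimizing the
  squared distance between its gradient and an observed single-example
  gradient. For the logistic learner the matching gradient has a closed
  form (`logistic_matching_grad()`), making multi-seed experiments cheap;
  a finite-difference fallback covers arbitrary models. Reconstruction
  quality is scored by SSIM (7×7 Gaussian window, $\sigma = 1.5$,
  $K_1 = 0.01$, $K_2 = 0.03$, dynamic range 1, valid-window mean) against
  the true input.

Risk reduction is reported as $100(\text{baseline} -
\text{defended})/\text{baseline}$, one decimal.

# The synthetic cohort generator

Each case is rendered from a jittered parametric anatomy — two lung
ellipses, a heart ellipse, a tracheal band, a diaphragm band, an aortic
knob, and the costophrenic angles (six structure channels on the image
grid, row-major, origin top-left). Positive pathology labels perturb the
image in label-specific, localized ways (focal bright opacity, enlarged
heart silhouette, basal effusion-like layer, apical lucent band, small
nodule; effect types cycle beyond five classes) and write the perturbed
region into the case's explainability mask, which is nonzero exactly when
some label is positive. Institutional domain shift — gain, bias, Gaussian
noise, effective resolution — applies last, with clipping to $[0,1]$.

Label structure: with probability `p_normal` (default 0.35) a case carries
no finding; otherwise a primary finding is drawn from the institution's
label prior and co-occurring secondary findings are drawn with probability
proportional to that prior (0.3 × prior, capped at 0.5), so rare classes
stay rare and severe imbalance (≥ 1:100, as real cohort tables report) is
reachable under skewed priors. Non-IID structure across nodes comes from
per-node label priors drawn from a symmetric Dirichlet (`dirichlet_beta`;
small values give strong skew) plus the photometric profile. Splits are
train/validation/test at 70/10/20 by default with per-label stratification
and exact `round`-based counts (112,120 cases give exactly 78,484 training
cases). An uncertain label code (−1) is mapped to negative at train time.
Training-time augmentation (horizontal flip p = 0.5, rotation ±10°,
brightness/contrast factors 0.8–1.2, Gaussian blur σ ∈ [0.1, 2] with
p = 0.2) is provided and never applied at evaluation.

**What passing tests do and do not show.** The generator emulates the
*statistical* structure of multi-institutional imaging — label skew,
photometric shift, class imbalance, localized findings with ground-truth
regions — not the appearance of radiographs. Positive results here show
that the federation, privacy, and evaluation machinery behaves as the
theory predicts under controlled conditions; they do not show that any
particular backbone would achieve any particular AUC on real chest X-rays.
Conversely, the machinery's failure modes found here (e.g. the
normalization shortcut) are real phenomena that would only be harder to see
on real data.

# Desk-scale experiment sizes

The test suite and the acceptance script use: cohorts of 120–2000 cases at
32×32 pixels over 2–4 nodes; 16×16 = 256 logistic features; 12–15
communication rounds of 2 local epochs for federation experiments; 2000
gradient-matching iterations on 8×8 inputs for reconstruction; 10,000 draws
for the DP noise-law test; 5 seeds for every median-based directional
claim. The heterogeneity experiment uses the full 2000-case desk profile
because each node's validation split must be large enough (~35 cases) for
the client AUC driving the softmax weights to carry signal — at 100 cases
per node the confidence mechanism is correctly wired but statistically
blind.

# Numerical choices and degenerate inputs

- Probability clamp $10^{-7}$ for all logarithms; clamped coordinates get
  zero gradient (the loss is flat there).
- Dice and atlas smoothing $\epsilon = 10^{-6}$; group-standardization
  $\epsilon = 10^{-5}$.
- Softmax weights use max-subtraction; aggregation denominators below
  $10^{-12}$ are an error, not a silent zero.
- The simplex projection is the exact sorting algorithm; the tests verify
  it against exhaustive active-set enumeration.
- Empty heatmaps: min–max normalization leaves an all-zero map at zero;
  Attention IoU of two empty regions is 1; the pointing game on a uniform
  heatmap resolves ties to the first pixel in row-major order and is
  documented as such.
- AUC uses the rank (Wilcoxon) statistic with ties counted 0.5; fairness
  macro averages report the sample standard deviation.
- BLEU's brevity penalty uses the closest reference length with ties toward
  the shorter reference; CIDEr treats n-grams unseen in the corpus as
  document-frequency one; text metrics share one fixed tokenization
  (lowercase, punctuation stripped, whitespace split).
- Checkpoints and the atlas are raw little-endian float32 with JSON
  sidecars; parameters are exchanged as flat vectors with a shape registry
  and finiteness is enforced at construction.

# Known limitations

- The local learners are small by design; no claim about deep-backbone
  behavior (normalization interactions, fine-tuning dynamics) transfers.
- The privacy accountant implements the two documented composition bounds,
  not subsampled-RDP numerics; its $\varepsilon$ values are conservative.
- The transport layer is simulated in-process; encryption, authentication,
  and asynchronous or dropout-tolerant protocols are out of scope, as are
  property-inference and attribute-recovery attacks (no reproducible
  procedure to implement) and trained language models for report
  generation — the text metrics operate on token sequences supplied by the
  user.
- `resolution_scale` degrades and restores images through bilinear
  resampling, a crude model of detector resolution.
- The composite-confidence mode estimates its gradient by finite
  differences, which costs six extra aggregations per round; at desk scale
  this is negligible, at real scale it would not be.
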