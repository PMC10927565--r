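---
title: "Models and methods behind meister"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meister}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meister)
```

This vignette explains the models implemented in **meister**, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## 1. The FT-ICR signal model

A transient is modeled as a sum of exponentially damped cosines plus
white Gaussian noise,

$$s(t) \;=\; \sum_i A_i\, e^{-t/\tau_i} \cos(\omega_i t) \;+\;
\varepsilon(t), \qquad \varepsilon(t) \sim \mathcal N(0, \sigma^2)
\;\; \text{i.i.d.},$$

where $A_i$ is the initial amplitude of ion $i$ (arbitrary intensity
units), $\tau_i$ the collisional damping constant (seconds) and
$\omega_i = 2\pi f_i$ its cyclotron frequency. Frequencies and m/z are
linked by the unperturbed cyclotron relation

$$f = K\,B_0 \,/\, (m/z), \qquad K = 1.535611\times 10^7
\;\text{Hz·Da·charge}^{-1}\text{T}^{-1},$$

a deliberate simplification: space-charge and trapping-field shifts are out
of scope, so the relation is exactly invertible (`frequency_from_mz()` /
`mz_from_frequency()`). The theoretical resolving power
$m/\Delta m = 1.274\times10^7\, z B_0 T_{aqn} / m$ is proportional to the
acquisition time $T_{aqn}$, which is the entire motivation for
reconstructing long transients from short ones.

**Isotopic fine structure.** `isotope_pattern()` computes the aggregated
isotopologue distribution of a molecular formula by exact convolution of
elemental isotope polynomials (repeated squaring per element, convolution
across elements), grouping isotopologues by nominal mass shift and
reporting abundance-weighted centroid masses. Any exact aggregated method
is equivalent here; the test suite checks the output against brute-force
multinomial enumeration to $10^{-9}$ absolute in probability. Isotope
masses and abundances come from an embedded IUPAC/CIAAW table; peaks below
`min_abundance = 1e-3` of the base peak are dropped by default. Adducts add
fixed cation masses (H$^+$ 1.007276, Na$^+$ 22.989218, K$^+$ 38.963158 Da,
electron mass included), singly charged only.

## 2. The simulated MSI study

`simulate_msi()` builds a ground-truthed dataset:

* a seeded Voronoi partition of the pixel grid into `n_regions` (default 8)
  pseudo-tissue regions, standing in for an anatomical annotation volume;
* a panel of 30 lipid-like formulas (phosphatidylcholines, sphingomyelins,
  ceramides, hexosylceramides, cholesterol, ...); each region draws
  `formulas_per_region = 10` of them, every formula is used somewhere, and
  every formula contributes all three adducts and all retained
  isotopologues;
* per-formula, per-region base amplitudes drawn log-uniformly from
  `amplitude_range = c(0.5, 1.5)`, multiplied by fixed adduct efficiencies
  (H 1, Na 0.4, K 0.2) and the isotopologue abundances — this resolves an
  open modeling choice (amplitudes could equally vary per formula only) in
  favor of region-level variation, which is what gives regions distinct
  spectral fingerprints;
* a per-pixel log-normal brightness factor (`pixel_sdlog = 0.2`) emulating
  matrix/section variation, and i.i.d. Gaussian noise `noise_sigma = 1`
  (in the units where base amplitudes are ~1; neither the sampling rate nor
  the noise level of such simulations is standardized, so both are explicit
  parameters with these defaults chosen once as a realistic regime — the
  resulting raw peak SNRs at the default scale are in the tens, typical of
  single-scan FT-ICR pixels).

The default timebase is 16,384 points at 1.368 MHz — the sampling rate at
which one million points last 0.731 s — i.e. the packaged studies are
deliberately *scaled down* (by 16x in transient length and ~10x in pixel
count) from a full-scale acquisition so that simulation, training and
evaluation run in minutes on one CPU. The acceptance study uses a 50×50
grid (2,500 pixels); unit tests use smaller grids.

What the phantom does **not** emulate: frequency drift, space charge,
apodization/phase effects, correlated (pink) noise, chemical background,
and anatomically realistic region shapes. Passing tests therefore show the
pipeline is correct and self-consistent under the stated model, not that it
is robust to every artifact of real instruments.

## 3. The reconstruction model

The deep autoencoder maps a full transient of $N_T$ samples through fully
connected ReLU layers 512 → 256 → 64 into a linear 32-dimensional latent
layer and back through the mirrored decoder; training minimizes the mean
squared reconstruction error with an L2 penalty applied through the
optimizer (Adam, `weight_decay = 1e-5`). The regressor mirrors the encoder
(input $N_{T'}$ → 512 → 256 → 64 → 32) and is trained to predict the
latent coordinates of full transients from their leading $N_{T'}$ samples.
Schedules follow the standard settings: 20 epochs for the autoencoder, 50
for the regressor, batch size 128 for tissue pixels (64 for single cells).
Inputs are normalized per transient by their maximum absolute value, with
the scale reapplied on output; for a cosine ensemble the maximum sits at
$t \approx 0$, so the prefix scale is a faithful proxy for the full-length
scale at reconstruction time.

**Initialization.** Three fully-connected layers of a 16k-dimensional
input are far too many parameters to fit from random weights in the few
optimizer steps a small training ensemble yields, so the package uses a
data-dependent initialization (in the same spirit as NNDSVD for NMF):

1. the training block is spectrally denoised — the spectral support is
   detected on the block-averaged magnitude spectrum at
   `median + 6·MAD` and all other frequency bins are zeroed — which is
   appropriate for resonant signals whose spectra are sparse; when the
   detected support holds less than half of the spectral energy (dense
   spectra, e.g. arbitrary non-resonant data) the denoising step is
   skipped automatically;
2. the truncated SVD of the denoised block is embedded *exactly* into the
   ReLU network through a signed-pair construction
   ($x = \mathrm{relu}(x) - \mathrm{relu}(-x)$ carried through the hidden
   layers), so the network starts as the rank-32 linear-subspace solution;
3. components whose singular values lie in the noise bulk (below twice the
   median singular value) start with zero decoder output — hard
   singular-value thresholding — and can be recruited during training;
4. the regressor starts from the embedded ridge-regression solution
   (`ridge_lambda = 1e-3` relative to the mean Gram diagonal).

Training then fine-tunes from this starting point; the default learning
rate is accordingly small (`1e-5`), because the starting point is already
near a good solution and aggressive steps only let the network memorize
the training noise realization, which re-contaminates the decoder and
erodes the denoising benefit. The returned parameters are those of the
epoch with the lowest full-data loss (including the initial model), which
also makes training on degenerate inputs (exactly low-rank, or identical
transients) numerically safe. Early stopping on a validation set is
deliberately not used: epoch counts are fixed.

The linear-subspace baseline (`fit_subspace()`) is the top-$r$ right
singular basis of the training block ($r = 32$ by default, matching the
latent dimension); `subspace_reconstruct()` fits per-row least-squares
coefficients on the first $N_{T'}$ columns and expands with the full
basis, warning and returning the minimum-norm solution when
$N_{T'} < r$.

**Evaluation.** `evaluate_reconstruction()` converts blocks to magnitude
spectra, extracts intensities at a common centroid list (picked from the
mean reference spectrum unless supplied — the simulation studies pick
centroids from the mean *noiseless* spectrum, since ground truth is
available), and reports per-pixel peak correlations, per-feature
(ion-image) spatial correlations, and per-peak SNR, defined as mean peak
intensity over the noise standard deviation estimated in a signal-free
spectral window (by default the top 5% of the m/z axis, i.e. the lowest
frequencies, where neither the simulated lipids nor real lipid signals
occur; the window is widened automatically on short axes so it always
holds at least ~60 samples). The SNR gain is
$20\log_{10}(\mathrm{SNR}_{recon}/\mathrm{SNR}_{ref})$ per peak.

## 4. Spectral processing

Spectra are magnitude-mode Fourier transforms with no apodization by
default (a Hann window is available by flag); absorption-mode phasing is
out of scope. Peak picking takes local maxima above `snr_threshold = 3`
times the noise standard deviation and refines centroids by a quadratic
fit through the apex and its two neighbors. For "3-ppm binning" the
package adopts greedy clustering over the pooled, m/z-sorted peaks — a
peak joins the current bin iff it is within 3 ppm of the bin's *first*
member, otherwise it opens a new bin — rather than a fixed log-spaced
grid; the choice is deterministic, idempotent on its own output, and never
merges peaks more than twice the width apart. TIC normalization scales
each nonzero row to unit sum. imzML export writes processed-mode files
(per-pixel m/z and intensity arrays; m/z as 64-bit, intensities as 32-bit
floats, little endian) with the binary data in the `.ibd` sidecar headed
by the UUID echoed in the XML; the reader resolves the external offsets
and re-bins when per-pixel axes differ.

## 5. Registration

`fit_parametric_embedding()` is a parametric UMAP: a fuzzy neighbor graph
(smooth-kNN bandwidths calibrated so the effective neighbor count is
$\log_2 k$, symmetrized as $v_1 + v_2 - v_1 v_2$) is built on a random 10%
pixel subset, and an encoder (features → 256 → 128 → 64 → 3) is trained to
minimize the cross-entropy

$$C = \sum_{i \ne j} v_{ij}\log\frac{v_{ij}}{w_{ij}} +
(1-v_{ij})\log\frac{1-v_{ij}}{1-w_{ij}},$$

with embedding similarities $w_{ij} = (1 + a d_{ij}^{2b})^{-1}$
($a = 1.577$, $b = 0.895$, the standard values fitted for
`min_dist = 0.1`), estimated by positive-edge attraction plus 5 sampled
negatives per edge, jointly with a mirrored decoder minimizing
reconstruction MSE. Because the map is parametric, all sections embed into
one shared space, so feature images of identical sections are identical.
Feature images min-max scale the three embedding dimensions as RGB and
collapse them with the luminance weights (0.299, 0.587, 0.114); the
luminance projection can in principle cancel contrast between two regions
whose embedding difference is luminance-balanced — a known limitation of
any 3-to-1 channel reduction.

`register_pair()` aligns a moving grayscale image to a fixed reference in
two stages, both maximizing mutual information on a 32-bin *partial
volume* joint histogram (each sample spreads linearly over the two nearest
bins per axis, which makes the MI landscape smooth enough for gradient
ascent; hard binning exhibits interpolation artifacts that systematically
bias affine estimates):

1. **Affine.** Initialization from image moments (intensity centroid and
   per-axis spread), followed by a coarse integer translation sweep around
   two linear-part hypotheses (the moment scales and the identity — the
   moment estimates are biased whenever content leaves the field of view),
   then two independent refiners from the best swept start — analytic
   gradient ascent on the partial-volume MI and Nelder–Mead — keeping
   whichever ends higher.
2. **B-spline.** A multilevel cubic B-spline free-form deformation with
   control-point spacings of 1/2, 1/4 and 1/8 of the image extent,
   optimized coarse-to-fine by backtracking gradient ascent (up to
   `max_iter = 200` steps per level), with a small L2 penalty on control
   displacements (`lambda = 0.002`) discouraging implausible deformations
   such as mapping a region onto an equally-bright neighbor. Steps are
   only accepted when they improve the objective, so the reported MI trace
   is non-decreasing across stages.

The synthetic "anatomical reference" used in tests and the pipeline is a
Gaussian-smoothed region phantom; the manual step of picking the matching
anatomical slice in a real atlas is out of algorithmic scope, as is
section-to-volume registration. Registration quality is scored by the Dice
index $2|A\cap B|/(|A|+|B|)$ per region (empty ∩ empty defined as 1).
Region profiles are per-region mean feature vectors; differential features
use the two-sided Wilcoxon rank-sum test with Benjamini–Hochberg
adjustment.

## 6. Single-cell integration

`cross_annotate()` treats the tissue feature list as the search database:
each cell peak is assigned to its nearest tissue feature within a 3-ppm
window (ties broken toward the lower m/z, a documented arbitrary rule);
features seen in under 5% of cells, then cells carrying under 5% of the
retained features, are dropped. `cluster_cells()` TIC-normalizes, takes 40
principal components, builds a cosine 30-nearest-neighbor graph and
partitions it with Leiden at resolution 0.25 (the `min_dist = 0.5`
parameter that usually accompanies these settings controls only UMAP
*visualization*, not the partition, and is therefore not part of the
clustering here). Per-cluster dictionaries are learned by NMF
(multiplicative updates on the Frobenius loss, NNDSVD initialization with
zeros replaced by the matrix mean, 500 iterations / relative-change
tolerance $10^{-5}$ by default, `k = 20` items); the union matrix stacks
the $D^{(l)}$ in cluster order, and `uoss_fit()` solves, independently per
pixel (the objective is row-separable),

$$C = \arg\min_{C \ge 0} \lVert Y - CU \rVert_F^2$$

by active-set non-negative least squares. Contribution maps take the
Euclidean norm of each cluster's coefficient block per pixel. When single
cells and tissue come from different intensity scales both sides should be
TIC-normalized before fitting, making the coefficients relative;
parameter-recovery studies instead fit on the generator's native scale so
the recovered maps are directly comparable to the ground truth.

`synth_multiscale()` generates the integration testbed: `L = 3` clusters
with `k = 4` dictionary items over 60 features (cluster-specific dominant
feature blocks over a faint exponential background), 200 cells per cluster
with gamma-distributed weights, and a 24×24 tissue grid whose per-cluster
mixing maps are smooth Gaussian blobs; 5% relative Gaussian noise, clipped
at zero, is the default. It does not emulate cell-segmentation errors,
ion suppression, or extracellular compartments — the known failure modes
that produce negatively correlated features in real fits are only
representable here by construction (see `evaluate_fit()`).

## 7. Problem sizes, determinism and limitations

All randomness flows through explicit integer seeds; fixed seed plus fixed
data reproduces models bit-for-bit, and model checkpoints round-trip
exactly through `save_model()`/`load_model()`. The packaged study sizes —
2,500 pixels × 16,384 samples for the reconstruction study, 900 pixels for
the pipeline example, 600 cells / 576 pixels for integration, 64×64
phantoms for registration — were chosen so each study completes in minutes
on a single CPU while keeping every qualitative feature of the full-scale
problem (multi-region structure, isotopic fine structure, realistic peak
SNR). Known limitations: the cyclotron relation ignores space charge; the
simulator's low intrinsic rank (regions × amplitude variation) favors
subspace-style models more than heterogeneous real tissue would; MI-based
registration of label-derived phantoms can in principle latch onto
equally-bright region permutations (mitigated, not eliminated, by the
deformation penalty); and the NMF/UoSS coefficients are identifiable only
up to the usual factorization ambiguities, which is why recovery is
assessed on per-cluster contribution maps rather than on individual
dictionary items.
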