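---
title: "Resolving and identifying hidden chromatographic peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving and identifying hidden chromatographic peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaspec)
```

## The problem

A liquid chromatograph with a broadband UV–vis detector records an
absorbance surface $A(t, \lambda)$ rather than a single trace. For mixtures
of chemically similar analytes — polycyclic aromatic hydrocarbons being the
motivating class, with dozens of isomeric species of near-identical
chromatographic behaviour — this extra dimension is what makes analysis
possible at all: species that co-elute, or that never produce an apex of
their own, can still be counted, resolved, and identified from their
absorption spectra. Identification by spectral shape is also robust to
matrix effects, which shift retention times unpredictably in field samples
and defeat retention-time lookup.

This vignette documents the models and the numerical and design choices
behind each stage. The package's tests and its acceptance script compute
every empirical number referred to here; nothing below is asserted from
memory of any particular instrument.

## Bilinear mixing model

Everything rests on Beer–Lambert linearity: for $k$ species,

$$ D = C S^\top + E, \qquad C \ge 0,\; S \ge 0, $$

with $D$ the $n_t \times n_\lambda$ window of the absorbance surface,
column $j$ of $C$ the elution profile of species $j$, and column $j$ of $S$
its absorption spectrum. Elution profiles are modelled as Gaussians
$a_j \exp(-(t - R_{t,j})^2 / 2\sigma_j^2)$; the retention time $R_{t,j}$
and width $\sigma_j$ are physical properties of the species–column pair and
therefore *cannot depend on the detection wavelength* — an observation the
hidden-peak diagnostic turns into a tool.

The synthetic generator (`simulate_chromatogram()`, `make_library()`,
`hidden_peak_scenario()`, `multi_species_scenario()`) draws data from
exactly this model: unit-area Gaussian concentration profiles (so the
configured `amount` has AU·min area semantics), species spectra built as
sums of Gaussian absorption bands, additive iid Gaussian noise, and an
optional linear baseline drift, constant across wavelength — the simplest
structure the derivative step of the classifier must cancel.

### What the generator does and does not emulate

Synthetic spectra have one broad short-wavelength band (centre 215–245 nm,
width 8–15 nm, relative height 0.3–0.7), which every aromatic chromophore
possesses and which makes a 230 nm detection channel universal, plus 1–5
narrower bands in 200–450 nm carrying the species fingerprint. Reference
libraries add replicate spectra with independent noise and sub-nanometre
wavelength shifts, emulating digitisation from heterogeneous literature
sources. Not emulated: lamp pulse and shot noise, flow-rate jitter,
photodegradation, stray light, or asymmetric (tailing) peak shapes.
Passing tests therefore demonstrate the *statistical* machinery under the
model's assumptions, not robustness to every instrumental artefact.

### Study conditions

Two canonical congested-elution conditions are frozen in
`hidden_peak_scenario()`:

* **three** — peaks at 5.82 / 6.00 / 6.18 min, $\sigma = 0.15$ min
  (1.2 $\sigma$ spacing), amounts 1.0 / 0.65 / 1.0. The middle species
  never exceeds a 40% share of any time point's signal: it is fully
  hidden.
* **five** — peaks at 8.2 / 8.695 / 8.745 / 9.3 / 9.95 min,
  $\sigma = 0.10$ min. The central pair is separated by 0.05 min
  ($0.5\sigma$) — a single apex, unresolvable chromatographically.

Peak widths follow the 0.05–0.15 min scale of compact-column instruments;
the pair gap of 0.05 min matches the reported behaviour of real
co-eluting pairs on such systems. Noise is 1% of the noiseless surface
maximum. Grids are desk-scale ($\Delta\lambda$ 1 nm over 190–500 nm,
$\Delta t$ 0.2 s); the full detector resolution (180–890 nm at 0.217 nm)
remains available through `sim_config()`, and the classifier grid uses
0.217 nm by default.

## Stage 1 — peak detection

`detect_peaks()` works on a single extracted channel (`extract_channel()`,
mean over a ±2 nm window; the mean keeps the trace scale-free across
window widths). The baseline is the median of the lowest decile of the
trace; noise is $1.4826 \times$ the median absolute deviation of the
first-difference detrended trace. Candidate maxima must clear `min_snr`
in both height *and* topographic prominence — without the prominence
requirement, noise ripples riding on a broad flank register as peaks.
Each peak carries its 10%-of-apex crossing times, found by walking
outward with linear interpolation; for a Gaussian these sit at
$R_t \pm \sigma\sqrt{2\ln 10}$, which the tests verify against the closed
form.

## Stage 2 — how many species?

Spectra inside a congested window are scaled to unit Euclidean norm (so
clustering reflects spectral *shape*, not concentration), embedded with
PCA, and clustered by K-means for $k = 1..8$ with 10 restarts.

Three design choices deserve justification:

* **Elbow criterion.** The raw second difference of the WCSS curve is
  dominated by the $k = 1 \to 2$ drop on *any* convex curve and nearly
  always answers 2. We instead take the point of maximal curvature of the
  log-WCSS curve — the $k$ maximising the vertical distance to the chord
  joining its endpoints. This is invariant to rescaling the scores, and
  ties break toward smaller $k$.
* **Embedding dimension.** `pca_embed()` defaults to two components (the
  natural visual convention), but `count_species()` retains every
  component above a 0.5% explained-variance floor (at most 6): five
  species directions cannot generically embed in two dimensions, and in
  the five-species condition the coincident pair's contrast routinely
  falls in the third or fourth component.
* **Rank cap.** Unit-norm spectra of $k$ mixing species span $k - 1$
  contrast directions after centring, so the number of structured
  eigenvalues bounds the species count. The noise tail of the eigenvalue
  spectrum decays by factors of 1.1–1.5 per component; a drop of $\ge 3$
  marks the structure/noise boundary, and $k$ is capped at that rank plus
  one. The cap reins in the elbow's tendency to over-segment the smooth
  mixture arc produced by two nearly coincident species.

A single window's $k$ estimate near the decision boundary is noisy; where
a stable answer matters (the acceptance script), the modal $k$ over
replicate runs is reported, mirroring replicate-injection practice.

## Stage 3 — elution modelling and the hidden-peak diagnostic

`fit_gaussian_sum()` fits $b + \sum_j a_j e^{-(t-R_{t,j})^2/2\sigma_j^2}$
by bounded Levenberg–Marquardt ($a_j \ge 0$, $\sigma_j$ between the
sampling step and half the window). The baseline $b$ is a free parameter:
the lowest-decile median sits about 1.6 noise-sd below the true baseline
and would bias the peak parameters if subtracted and frozen. With more
components than visible apexes the least-squares surface is multimodal, so
the optimiser runs from several starting layouts (detected maxima,
signal-mass quantiles, even spacings at two widths) and keeps the best.
On exact single-Gaussian input the fit is accurate to $10^{-6}$ relative;
at 2$\sigma$ separation and 1% apex noise, retention times are recovered
with mean error below $0.02\sigma$, at the information-limited floor for
the sampling density.

`rt_consistency_diagnostic()` operationalises the physical constraint
above: independent $k$-component fits on channels spanning 240–400 nm (the
region where species-specific band structure lives — below ~245 nm the
common aromatic band makes all channels look alike) must agree on every
$R_t$. Channels below 20:1 signal-to-noise are excluded, as are
components stuck at the window edge or blown to the width bound (failed
fits, not evidence). The spread tolerance is $0.05\,\hat\sigma$: measured
single-species spreads are two orders of magnitude smaller, while an
unmodelled species drags the fitted $R_t$ by a sizeable fraction of
$\sigma$ as the wavelength weighting changes. Notably, an underspecified
$k$ often fits any *single* channel to within the noise — goodness of fit
alone cannot reject it; the wavelength dependence of $R_t$ is the
evidence.

`fit_shared_rt()` then fits all channels jointly with shared $R_t$ and
$\sigma$ (free per-channel amplitudes), and with the elution model frozen
refits amplitudes at every wavelength by exact non-negative least squares,
yielding unit-area concentration profiles and a full amplitude spectrum
per component.

## Stage 4 — curve resolution

`mcr_ar()` alternates exact non-negative least squares — $C$ given $S$,
then $S$ given $C$ — until the relative change in lack-of-fit
($100\sqrt{\sum E^2 / \sum D^2}$, %) falls below $10^{-8}$. Each
half-step is an exact constrained minimisation, so the lack-of-fit is
monotone non-increasing; the tests assert this from rough random starts.
The inner solver (`nnls_multi()`) enumerates all $2^k - 1$ candidate
active sets and picks the feasible one with the smallest directly-computed
residual — exact for the small $k$ of curve resolution and vectorised over
thousands of right-hand sides. Scale ambiguity is fixed by unit-max
spectra columns; the intrinsic rotational ambiguity is what the
initialisation and constraints manage:

* **Initial spectra** come from the measured flanks: the first species'
  estimate at its rising 10%-of-apex time, the last at its trailing 10%
  time, and interior (hidden) species at their fitted $R_t$. At the 10%
  flank the signal is a tenth of the apex, so the sampled spectrum
  averages $\pm 3$ rows ($\pm 0.6$ s, negligible against peak widths) and
  is lightly Savitzky–Golay smoothed in wavelength.
* **Unimodality** of each concentration profile (a monotone-envelope
  projection, idempotent, consistent with Gaussian elution) is available
  in `mcr_ar()` and enabled inside `deconvolve_window()`: with
  non-negativity alone, unfavourable spectral geometries let the hidden
  component absorb features of its neighbours.
* **Component order**: by default output components match the initial
  spectra by maximal correlation (so permuting the initialisation permutes
  the result identically). The hidden-peak procedure instead orders by the
  apex time of the concentration profiles — its initial spectra are
  elution-ordered by construction, and a hidden species' *convolved*
  initial spectrum can resemble a neighbour more than itself.

Spectrum similarity is reported as the squared Pearson correlation (scale-
and offset-free) and the discrete Fréchet distance computed after
normalising wavelength to $[0,1]$ over the common support and each curve
to unit maximum. Absolute Fréchet values depend on this convention and are
comparable only within it. The dynamic-programming implementation is
verified against a brute-force recursion over all monotone couplings and
against the metric axioms.

## Stage 5 — fingerprint classification

`featurize()` resamples a spectrum onto the common 200–450 nm grid
(0.217 nm), smooths (Savitzky–Golay, order 5, ±4.5 nm — exact on
polynomials to degree 5, so genuine band structure survives),
differentiates (cancelling any constant baseline offset between
instruments), restricts to the common window, imputes missing support as
zero *after* the derivative (zero-filling absorbance would fabricate band
edges), and scales to unit norm. Coverage below half the window is
rejected.

With thousands of wavelength features and tens of reference spectra, raw
LDA is singular; features are projected onto the principal components
carrying at least 0.5% of training variance each (never more than
$n - n_{classes}$) before the discriminant is fitted. Using the full
$n - n_{classes}$ span was observed to overfit (confident wrong labels);
the variance floor removes that failure while preserving perfect
leave-one-out and fresh-query accuracy on 24- and 16-class panels.
Classes with a single reference spectrum are kept — the pooled covariance
covers them — and an exactly singular within-class scatter (identical
replicates) falls back to a deterministically-jittered regularised fit,
with a warning.

Shared-covariance posteriors saturate at 0/1 even for out-of-distribution
queries, so inconclusiveness is declared when the top posterior is below
0.95, the top-two margin below 0.25, *or* the query sits far from every
class in discriminant coordinates (squared distance above 25× the 99.9%
$\chi^2$ quantile — calibrated so clean single-species queries at the
percent noise level never trigger, while convolved mixture spectra sit an
order of magnitude beyond). The tiebreak compares the top three candidates
by mean r² on the smoothed *zeroth-derivative* spectra (similarity scores
are conventionally quoted on absorbance curves, not derivatives) and the
highest mean wins. Retention time is never consulted.

## The assembled pipeline

`run_pipeline()` detects peaks, groups those whose 10% extents overlap
into regions, and treats a region as congested when it holds more than one
apex or the $R_t$-consistency diagnostic flags it. Congested regions go
through counting → shared-$R_t$ fit (initialised at the K-means cluster
time centroids — each cluster dwells around one species' elution) → flank
initialisation → constrained MCR; clean regions contribute their apex-time
spectrum directly. Every recovered spectrum is classified, and a failed
region is marked `unresolved` rather than aborting the run. All
randomness flows from one seed; a fixed seed and fixed inputs give an
identical peak table.

## Problem sizes and limitations

The test suite and acceptance script run desk-scale problems: windows of
300–900 time points × ~310 wavelengths, 20 replicate deconvolutions,
24-species chromatograms of ~3700 × 311, all in a few minutes on one CPU.
Known limitations: symmetric Gaussian elution only (no exponentially
modified tailing); linear baseline drift only; the elbow/rank counting
assumes the congested window holds at most `k_max` species; MCR is run
per window, not across runs (no augmented-matrix multiset resolution);
and classification quality is bounded by library coverage — a species
absent from the library is assigned its nearest spectral neighbour, with
the r² and Fréchet columns of the peak table as the audit trail.
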