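---
title: "Quantifying false-positive nuclear RNA foci: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying false-positive nuclear RNA foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociscope)
```

## The problem

Fluorescently tagged guide RNAs expressed from plasmids can accumulate in
discrete nuclear puncta that are indistinguishable, by eye, from genuine
genomic loci. Quantifying this false-positive foci formation — counting foci
per cell against a negative-control baseline, measuring two-channel
colocalization, and characterizing the liquid-droplet behaviour of the
puncta — requires a small set of image-analysis procedures that this package
implements as tested, reusable functions, together with a synthetic-scene
generator that provides ground truth for every one of them.

## The spot statistic and its empirical null

The central statistic is the signal-to-background ratio of a candidate
punctum on the maximum-intensity projection (MIP) of a 3D stack:

$$\mathrm{SBR} = \frac{F_{\text{candidate spot}}}{F_{\text{nucleus}}}$$

where $F_{\text{candidate spot}}$ is the maximum spot intensity and
$F_{\text{nucleus}}$ the mean nucleoplasmic intensity outside spots. The
decision threshold is not parametric: it is the **maximum SBR observed among
candidate spots in mock (focus-free) control cells** — an empirical-null
extreme. A candidate in a sample cell is called a focus only when its SBR is
*strictly greater* than this mock maximum; the null extreme itself must not
be called. Two consequences follow by construction and are enforced as
tests:

* re-applying a calibration to its own mock set calls exactly zero foci;
* the statistic is invariant under any global gain applied to the image.

One consequence follows from the rank argument and is worth stating plainly:
with candidates pooled from $M$ mock cells, a *held-out* null cell exceeds
the calibrated maximum with probability about $1/(M+1)$ per candidate-set —
roughly 0.02 false foci per cell at the 50 mock cells used here. This is an
intrinsic property of max-of-null calibration, not an implementation defect;
the held-out mock rate is checked against a 0.1 foci/cell ceiling, and the
recovery tests compare detected counts net of an independently estimated
null-exceedance rate.

Where $F_{\text{nucleus}}$ would in manual practice be a hand-drawn
nucleoplasmic region, we use the whole nucleus mask minus all candidate spot
masks dilated by 2 px — a reproducible surrogate with a configurable margin.
Candidates are pooled across all mock cells (a single global extreme) rather
than per-cell maxima; the alternative is available by calibrating on
per-cell maxima lists, but pooling is the default reading of a single
reported mock maximum.

## Candidate detection

No candidate-finding operator is prescribed by the quantification protocol
itself, so the package uses a deterministic Laplacian-of-Gaussian detector
at the PSF scale: local response maxima above a robust threshold (3.5 MADs
of the in-nucleus response), a 3 px minimum separation with ties broken by
lexicographic position, and connected spot masks from a relative local
threshold (30% of peak-above-background, keeping the masked fraction of a
Gaussian spot amplitude-independent). Two guards matter in practice:

* an absolute response floor removes FFT ripple maxima on noise-free
  images;
* candidate centres must sit at least 3 px inside the nucleus boundary,
  where the nucleus/background intensity step otherwise produces strong
  spurious blob response.

The threshold is deliberately permissive: mock nuclei must still yield
noise candidates, because the empirical null is calibrated from them.

## The synthetic-scene generator

The generator emulates the imaging conditions the pipeline quantifies:
nuclei (perturbed ellipses, non-overlapping by rejection sampling with
bounded retries) on a dark field, per-cell focus counts drawn
Poisson($\lambda$), foci rendered as anisotropic 3D Gaussians on a flat
nucleoplasmic background, and Poisson shot noise plus additive Gaussian read
noise — the standard EMCCD approximation. Defaults, chosen once as the
simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.13 um | 100x objective, ~13 um camera pixels |
| z-step | 0.25 um | standard fine z-sampling for these stacks |
| PSF sigma (lateral, axial) | 0.2, 0.5 um | diffraction-limited puncta with modest aberration |
| nucleus radius | 4.5 ± 0.4 um | epithelial-line nuclei at this magnification |
| background | 30 photons | dim nucleoplasmic probe background |
| focus amplitude | 250 ± 50 photons | bright FISH/deconvolved-class puncta (see below) |
| read noise | 3 photons | back-illuminated EMCCD class |
| min focus separation | 0.8 um | condensates closer than this would have coalesced |
| coloc jitter | 0.1 um | chromatic/localization error between channels |

The amplitude default deserves a note. The nominal SNR
(amplitude/$\sqrt{\text{background}}$, reported by `config_snr()`) is well
above the detection floor of 5. That choice is driven by the colocalization
readout, not by detection: co-labelled bright foci in real two-channel data
of this kind give nuclear-crop Pearson correlations around 0.9, and pixel
correlation at that level is only reachable when focus signal variance
dominates shot noise. Foci rendered at the detection margin would be
trivially countable against this calibration yet would depress pixel
correlation far below what the corresponding experiments show. Detection
difficulty is retained where it matters — the empirical-null calibration
operates on pure noise either way — and the amplitude scale is
config-exposed.

Per-cell focus counts are plain Poisson (the simplest null; overdispersion
is a config extension, not a default). Focus positions are uniform over the
eroded nucleus interior with a minimum mutual separation of 0.8 um —
without such a separation, genuinely coincident puncta are unresolvable by
*any* detector and per-cell counts would be biased low for reasons
unrelated to the pipeline.

What the generator does **not** emulate: chromatin texture and nonuniform
nucleoplasmic background, cytoplasmic probe signal, optical aberrations
beyond a Gaussian PSF, camera gain/EM-register statistics, and z-dependent
nucleus shape (nuclei are treated as cylinders across the stack). Passing
tests therefore demonstrate correctness of the procedures under a clean
generative model, not robustness to every artefact of real microscopy.

## Two-channel colocalization

Pixel level: Pearson correlation over *all* pixels of equal-sized nuclear
crops of the two channel MIPs (the bounding box of the nucleus mask, applied
identically to both channels), with no intensity thresholding. Object level:
one-to-one greedy matching of called spots by ascending centre distance
among pairs within 0.5 um — the radius follows the observation that
genuinely separate structures in these experiments sit more than 500 nm
apart; it is configurable. Greedy matching is deterministic and, at these
spot densities, agrees with optimal assignment (tests verify this against an
exhaustive oracle on small instances). Cohort summaries divide by cells
containing spots in both channels; a cell can contribute to both the
colocalized and the uncolocalized percentage.

The per-cell colocalized/uncolocalized classification replaces a visual
determination with the explicit radius rule; the contract is algorithmic
reproducibility, not agreement with any particular human rater. In the
fully co-labelled simulated regime the median nuclear-crop Pearson r
exceeds 0.9; with independently placed foci in the two channels (both
channels well populated, as in the corresponding separated-structure
experiments) it falls to ~0.24. Note the floor is not zero: the shared
nucleus-shaped background step correlates the two channels even with no
shared foci, exactly as in real crops.

## Condensate liquid-property readouts

**Circularity** is $4\pi A / P^2$ on the 2D MIP mask, clamped to 1 —
"sphericality" operationalized in 2D because the underlying evidence is 2D
imagery; 3D sphericity is out of scope. Rasterized discs score near 1,
bars score low, and the measure is scale-invariant up to discretization.

**Fusion tracking** links detected spots frame-to-frame by nearest
neighbour with a maximum step of 3 PSF sigma per frame, declaring a merge
when both partner tracks are claimed by one detection. Intensities are
measured by fixed-radius (2.5 sigma) aperture photometry against the
nucleoplasmic median background, with analytic pairwise deblending: the
spill of a Gaussian spot into a neighbouring aperture at distance $d$ is
$P\left(\chi^2_2(d^2/\sigma^2) \le r^2/\sigma^2\right)$, so the pair of raw
aperture sums is solved for the two true fluxes. Threshold-mask photometry
was rejected here: for puncta a few pixels across, subpixel alignment makes
the masked fraction fluctuate by several percent, which is material when the
conservation contract is 5%.

In the generator, two approaching foci coalesce when their centre distance
falls below a contact distance of 4 lateral PSF sigma (config
`merge_distance_um`) — the two optical-size (~2 sigma radius) droplets
touching. Placing the merge at or below ~2 sigma would make the truth
unobservable: two Gaussians closer than that render as a single intensity
maximum, so no detector could agree with the ground-truth merge frame. At 4
sigma every rendered two-spot frame is resolvable and the detected merge
frame equals the truth merge frame by construction. The merged amplitude is
the sum of the partners, so combined background-subtracted intensity is
conserved across the merge — exactly in the noise-free rendering, and
within 5% through the full detection/photometry path. Photobleaching is
simulated as a global per-frame multiplicative decay applied before noise,
and corrected by whole-nucleus mean normalization: assumption-free and
exact for any global multiplicative decay, unlike an exponential fit.
Whether real bleaching correction should be global or per-structure is
undecidable from a single reported series; global is used and noted in
reports.

**Condition comparisons** mirror the reporting conventions of the
experiments: per-cell focus counts and pooled per-focus intensities as mean
± SEM per arm; two arms compared by a two-tailed Welch t-test; three or
more by one-way (Welch) ANOVA followed by Dunnett-T3-style pairwise
comparisons against the designated control — pairwise Welch statistics with
per-pair Satterthwaite degrees of freedom and a Sidak-type family
correction (numerically stable via `expm1` for very small p). Exact
studentized-maximum-modulus critical tables are not re-derived; the
contract is the documented correction formula. Type-I error of the two-arm
path is verified by simulation (1000 identical-arm replicates) to sit at
the nominal 5% within binomial error.

## Numerical and degenerate-input conventions

* Stacks are `(y, x, plane)` arrays, 1-based, matching native R matrix
  layout; physical positions are micrometres from the centre of voxel
  (1,1,1).
* Intensity TIFFs are written as 16-bit integers (photon counts round-trip
  exactly); label images as 16-bit label TIFFs; ground truth and configs as
  JSON.
* Degenerate inputs error loudly: empty stacks, zero-variance crops
  (undefined Pearson), zero background means, spot masks covering a whole
  nucleus, masks under 4 px for circularity, nuclei that cannot be placed
  in the field.
* Determinism: generators set their RNG state from the config seed and
  restore the caller's state; scene-level sub-seeds are derived by a
  counter scheme (`derive_seed`), so multi-scene workflows are reproducible
  independent of iteration order. Identical config + seed gives
  bit-identical scenes and byte-identical report bodies.

## Problem sizes used in validation

The validation studies simulate cohorts of 25-cell fields: 100 cells for
the high-rate (plasmid-like, 15.8 foci/cell) regime, 300 cells for the
marginal (cassette-like, 0.09 foci/cell) regime with 50 mock cells for
calibration and 50 held out, 30 two-channel cells for the colocalization
readout, 25-frame fusion series, and 1000 replicate pairs (30 cells/arm,
ground-truth counts) for the type-I calibration of the comparison test.
These sizes match the cell counts reported for the corresponding
experiments while keeping the whole suite comfortably reproducible on a
single CPU.

## Known limitations

* Counting operates on MIPs; axially stacked foci project onto each other
  (mitigated here by the minimum-separation prior, present in real
  condensates but not guaranteed in all samples).
* The empirical-null threshold inherits sampling noise from the mock set;
  with few mock cells the held-out false-call rate is overdispersed around
  its $1/(M+1)$ expectation.
* Greedy matching is near-optimal, not provably optimal, at high spot
  density.
* Dunnett's T3 is approximated by Sidak-corrected pairwise Welch tests;
  for small samples the approximation is mildly conservative.
* The fusion tracker is designed for the two-spot geometry of a fusion
  event, not for dense multi-particle tracking.
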