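---
title: "Quantifying tumor vascular response: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor vascular response: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdtvasc)
```

Vascular-targeted therapies such as photodynamic therapy act, in large
part, by shutting down the tumor's blood supply. Quantifying that shutdown
requires combining modalities: DCE-MRI reports perfusion and permeability
in vivo over the whole tumor; intravital fluorescence reports the
microscopic distribution of the therapeutic agent; histology reports the
resulting perfusion loss and necrosis at cellular resolution. `pdtvasc`
implements the quantitative chain for all three, and validates it against a
digital phantom with known ground truth. This vignette explains the models,
the tunable parameters, and the choices made where the design was genuinely
open.

## 1. DCE-MRI pharmacokinetic chain

### Signal model and T1 mapping

Both the pre-contrast T1 measurement and the dynamic scan use a spoiled
gradient-echo (FLASH) sequence, whose steady-state signal is

$$S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1 \cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

The default `scan_protocol()` encodes a 7 T small-animal protocol: VFA
series at TR = 20 ms with flip angles 2, 3, 5, 7, 10, 13, 20°, and a 15 min
dynamic series (257 frames at 3.5 s) at TR = 3 ms, flip angle 7°, with the
contrast bolus injected 2 min after the scan start.

`fit_t1_vfa()` estimates (M0, T1) per voxel in two stages. The linearized
DESPOT1 form $S/\sin\alpha = E_1 \cdot S/\tan\alpha + M_0(1-E_1)$ gives a
closed-form initial estimate; a vectorized Levenberg–Marquardt refinement
of the exact model follows, because the linear estimator is biased under
noise (the regression error is heteroscedastic in $S$). T1 is constrained
to [0.05, 10] s — generous bounds whose only role is to exclude non-tissue
solutions. Voxels with all-zero signal or a non-physical linearized slope
($E_1 \notin (0,1)$) are flagged invalid and **excluded** downstream, never
carried as zeros: a zero T1 would silently corrupt every later stage,
whereas an excluded voxel is visible in the reported counts.

### Concentration conversion

With $R_1 = 1/T_1$ and relaxivity $r_1 = 3.53\ \mathrm{s^{-1}mM^{-1}}$
(gadoterate at 7 T), the agent concentration follows from
$R_1(t) = R_{1,\text{pre}} + r_1 C(t)$. `signal_to_concentration()`
calibrates an effective $M_0$ per voxel from the mean of all pre-injection
frames together with the fitted $R_{1,\text{pre}}$ (the mean over the full
baseline maximizes baseline SNR), then inverts the SPGR equation per frame:

$$E_1(t) = \frac{M_0\sin\alpha - S(t)}{M_0\sin\alpha - S(t)\cos\alpha},
\qquad R_1(t) = -\ln E_1(t) / TR.$$

Numerical choice: $C(t)$ is referenced against the mean of the *inverted*
baseline $R_1$ rather than the T1-map value directly. The two agree to
floating-point precision by construction of the calibration, but the
measured reference keeps a flat baseline at exactly zero concentration;
referencing the T1-map value instead leaves ±1-ulp residuals whose sign is
arbitrary, which matters for the degenerate branch of the enhancement rule
below. Frames whose signal falls outside the invertibility range are
carried as missing (`NA`) and excluded from medians, SDs and integrals —
at realistic SNR this is rare, and dropping frames is preferable to
fabricating concentrations.

### Enhancement classification

A voxel is non-enhanced when the median of the concentration curve at and
after the injection time is smaller than twice the SD of the pre-injection
concentrations. Decisions taken here, where the rule's verbal statement
leaves room:

* "before injection" means $t < t_0$ and "after" means $t \ge t_0$; the
  ~5 s injection duration is ignored, as the rule names only the injection
  time;
* the baseline SD is the sample (n−1) SD (switchable to population);
* the degenerate case SD = 0 (noiseless data, or a dead channel) is
  resolved as: non-enhanced iff the post-injection median is ≤ 0, judged
  with a 1e−12 mM absolute tolerance so floating-point residuals cannot
  flip the branch;
* the SD is computed on concentration rather than signal units — the
  comparison is approximately scale-invariant either way, and
  concentration is the quantity the rule is about.

### Tofts–Kermode fitting

Enhanced voxels are fitted with the standard (two-parameter) Tofts–Kermode
model. With the bi-exponential AIF the convolution has the closed form

$$C_t(t) = K^{trans}\sum_{i=1,2} A_i\,
\frac{e^{-(t-t_0)/\tau_i} - e^{-k_{ep}(t-t_0)}}{k_{ep} - 1/\tau_i},$$

with the analytic limit $A_i K^{trans}(t-t_0)e^{-k_{ep}(t-t_0)}$ taken when
$|k_{ep} - 1/\tau_i| < 10^{-8}\,\mathrm{s^{-1}}$ — the switch tolerance
avoids catastrophic cancellation near the degenerate point while being far
below the scale at which the two expressions differ detectably
(validated against a dt = 0.01 s numerical convolution to < 1e−4 mM).

Units: the package stores times in seconds and concentrations in mM
throughout, but reports Ktrans and kep in min⁻¹, the field convention;
conversion happens inside the model evaluation only.

The fit is bounded least squares (Ktrans ∈ [0, 5] min⁻¹,
ve ∈ [10⁻³, 1]) with analytic gradients. Because the RSS surface is
multimodal at low SNR, the optimizer starts from a 3 × 3 grid
(Ktrans ∈ {0.01, 0.1, 0.5} min⁻¹ × ve ∈ {0.1, 0.3, 0.6}); the best-RSS
winner — RSS ties broken toward the smallest Ktrans — is then re-polished
at tight tolerance, which keeps per-start cost low without sacrificing
final precision. `kep` is always the derived ratio Ktrans/ve, never an
independent parameter. Non-converged voxels carry their parameters with
`converged = FALSE`; non-enhanced voxels carry `NA`, deliberately distinct
from Ktrans = 0.

The standard model (no plasma-volume term), a population-fixed AIF, no
per-voxel bolus-arrival estimation and no water-exchange correction are
deliberate scope choices matching the analysis the package reproduces.

### ROI summaries

Muscle reference ROIs are 5×5-pixel in-plane blocks in the four central
tumor slices ("central" operationalized as the middle four of the tumor's
slice extent, ties toward smaller indices), each placed at the feasible
position nearest the light-beam axis with at least one pixel spacing to
the tumor border; placement is an exhaustive search over all candidate
blocks (summed-area table), so the reported position is optimal by
construction. Compartment means of Ktrans cover enhanced-and-converged
voxels only, in muscle as in tumor — whether the original muscle averages
included non-enhanced voxels is not documented, and the enhanced-only
convention mirrors the tumor analysis. The AUC integration window defaults
to injection-to-scan-end.

## 2. The digital phantom

`phantom_truth()` builds a 64×64×17 grid (configurable) containing an
ellipsoidal tumor with a concentric non-enhancing core (Ktrans = 0 —
the stand-in for post-therapy vascular shutdown; 30% of the tumor volume
by default) and a muscle slab under the tumor along the beam direction.
Within the enhancing rim, Ktrans spans [0.01, 1] min⁻¹ and ve spans
[0.1, 0.6] as smooth deterministic spatial fields, covering the
physiological range a fit must handle. T1 defaults (tumor 1.9 s, necrotic
core 2.2 s, muscle 1.5 s; M0 = 1000) are typical 7 T tissue values.

`simulate_study()` chains AIF → tissue curve → $R_1(t)$ → SPGR signal per
voxel, producing both the VFA and the dynamic series, then adds noise.
Rician noise (magnitude MRI) is the default; Gaussian is available for
linear-regime checks. The dynamic series is assumed to be in steady state
from the first frame — the protocol's dummy cycles are not simulated.

What the phantom deliberately does **not** emulate: k-space sampling and
Bloch dynamics, B1 inhomogeneity, motion, partial-volume mixing,
per-animal AIF variability, and bolus dispersion. Parameter-recovery tests
on the phantom therefore demonstrate the correctness and noise robustness
of the *inversion chain*, not robustness to those acquisition artifacts;
on real data the corresponding errors add on top.

Problem sizes used in the shipped validation: the noiseless round trip
runs the full 64×64×17 phantom (~10⁴ fitted voxels); the SNR-20 noise
study uses a 48×48×9 phantom whose enhancing rim holds ~560 voxels at a
single operating point (Ktrans = 0.25 min⁻¹, ve = 0.4), with SNR defined
against the baseline dynamic-scan signal of an M0 = 1000, T1 = 1.9 s
voxel. Unit tests use a 24×24×7 phantom for speed.

## 3. Intravital fluorescence statistics

Integrated density (not mean intensity) is the ROI measure, because
receptor-specific binding makes the signal spatially heterogeneous; it is
normalized to a 5000 µm² reference area. The correction order is dark
current → area normalization → reference-standard division →
autofluorescence subtraction:

$$ID_{corr} = \frac{5000}{n_{px}A_{px}}\sum_{ROI}(I - I_{dark})
\Big/ f_{ref} - AF.$$

The subtract-then-scale arithmetic is the package's documented choice (the
correction steps are standard, their exact composition is not); negative
corrected densities are clipped to zero and flagged. The autofluorescence
slot expects a per-animal pre-injection measurement, already normalized
per 5000 µm².

Group values are SD-weighted: $w_i = 1/sd_i^2$, $\bar x_w = \sum w_i
x_i/\sum w_i$. "Weighted mean ± SD" is ambiguous between the uncertainty
of the weighted mean, $\sqrt{1/\sum w_i}$, and the weighted sample SD; the
former is the default and the latter is available via `spread = "sample"`.
Zero SDs (degenerate single-pixel ROIs) would carry infinite weight and
are capped at the smallest positive SD in the set. Tumor-to-normal ratios
propagate uncertainty to first order (delta method).

Colocalization between the probe and tumor-cell (GFP) channels is
Spearman's rank correlation over the ROI after dark-current subtraction,
with average ranks for ties and no intensity threshold (none was
specified; the statistic is rank-based and needs none). A constant channel
has no defined rank correlation and yields `NA`. The synthetic two-channel
generator (`simulate_coloc_pair()`) shares a smooth membrane-like
structure between channels with a tunable weight, giving a monotone
ground-truth ordering against which the statistic is tested.

## 4. Histology fractions

Perfusion classification is a manually selected global threshold on the
Hoechst 33342 image within the tumor mask (`hoechst >= threshold`); an
Otsu helper exists for exploration but is never applied implicitly,
because the original classification is explicitly manual. Necrosis masks
are manual inputs. Fractions are plain set counts; the overlap statistic
is referenced to the necrotic area, i.e. the share of necrosis that is
also non-perfused — the natural reading when necrosis is the smaller,
biologically primary set; the denominator is documented in
`perfusion_stats()` so the alternative (tumor-referenced) reading cannot
be confused with it. Adjacent-section registration is out of scope; masks
are assumed pre-registered.

## 5. Reproducibility

`run_pipeline()` executes the whole chain from a `run_config()`; identical
configuration and seed give byte-identical summary outputs, and every run
writes a provenance record (config, seed, package version, exclusion
counts). All simulation randomness flows through explicit integer seeds,
and noise generation restores the caller's RNG state. The interface is the
exported functions plus `run_pipeline()`; file formats go through the
standard packages (RNifti for NIfTI-1 with the affine carried untouched,
tiff for TIFF, yaml/jsonlite for config and provenance).

## 6. Known limitations

* The phantom validates the inversion chain, not acquisition physics
  (see §2); reported recovery errors are lower bounds for real data.
* The AIF is population-fixed; individual AIF variation biases Ktrans
  multiplicatively and is not modelled.
* The enhancement rule is a per-voxel marginal test; it does not exploit
  spatial continuity, and at very low SNR its false-non-enhancement rate
  grows.
* Muscle ROI placement assumes the beam axis and tumor mask are in the
  same voxel grid; no registration is performed.
* Histology statistics assume pre-registered masks and a single global
  Hoechst threshold per section.
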