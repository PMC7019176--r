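# pdtvasc

Quantitative imaging analysis of tumor vascular response, built for studies
of vascular-targeted therapies (such as photodynamic therapy, PDT) in small
animals. The package covers the three quantitative readouts such studies
combine:

1. **DCE-MRI pharmacokinetics** — variable flip angle (VFA) T1 mapping,
   conversion of the dynamic spoiled gradient-echo signal to gadolinium
   contrast-agent concentration, voxelwise enhancement classification, and
   Tofts–Kermode model fitting with a fixed bi-exponential arterial input
   function (AIF);
2. **Intravital fluorescence microscopy** — background-corrected integrated
   densities per 5000 µm², SD-weighted means, tumor-to-normal ratios, and
   Spearman rank colocalization between channels;
3. **Histology** — Hoechst-33342-threshold perfusion classification and
   necrosis/perfusion fraction statistics.

Because studies of this kind rarely deposit raw animal data, the package
ships a synthetic digital phantom with known ground truth
(`phantom_truth()`, `simulate_study()`): an ellipsoidal tumor with a
non-enhancing core (emulating vascular shutdown after therapy) and a muscle
reference slab. Every analysis stage is validated by recovering the known
parameters from simulated acquisitions.

## The model

The spoiled gradient-echo (SPGR/FLASH) steady-state signal is

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha}, \qquad
E_1 = e^{-TR/T_1},$$

fitted over multiple flip angles α to map the pre-contrast T1
(`fit_t1_vfa()`). During contrast influx the relaxation rate follows
$R_1(t) = R_{1,\text{pre}} + r_1 C(t)$ with relaxivity
$r_1 = 3.53\ \mathrm{s^{-1}mM^{-1}}$ (gadoterate), so inverting the SPGR
equation frame by frame yields the tissue concentration $C(t)$
(`signal_to_concentration()`). Voxels are **non-enhanced** when the median
of $C(t)$ after injection is smaller than twice the baseline SD. Enhanced
voxels are fitted with the standard Tofts–Kermode model

$$C_t(t) = K^{trans} \int_0^t C_p(\tau)\,
e^{-k_{ep}(t-\tau)}\,d\tau, \qquad k_{ep} = K^{trans}/v_e,$$

driven by the population bi-exponential AIF
$C_p(t) = A_1 e^{-(t-t_0)/\tau_1} + A_2 e^{-(t-t_0)/\tau_2}$ with
$A_1 = 5.36$ mM, $A_2 = 1.27$ mM, $\tau_1 = 5.36$ s, $\tau_2 = 915$ s. The
convolution is evaluated in closed form, with an analytic limit at the
degenerate point $k_{ep} = 1/\tau_i$ (`fit_tofts()`, `pk_map()`).

## Worked example

Simulate a noisy (Rician, SNR ≈ 26 at baseline) phantom acquisition and run
the full chain:

```r
library(pdtvasc)
truth <- phantom_truth(dim = c(32, 32, 9))
sim   <- simulate_study(truth, noise = noise_spec("rician", sigma = 1, seed = 7))
r1    <- fit_t1_vfa(sim$vfa)
conc  <- signal_to_concentration(sim$dce, r1)
fit   <- pk_map(conc)
rois  <- place_muscle_rois(truth$tumor_mask, truth$beam_axis)
summarize_study(fit, conc, rois, truth$tumor_mask)
```

```
Study summary
  tumor: 29.9% non-enhanced (345 voxels); mean Ktrans 0.685 min^-1 over 232 enhanced
  muscle ROI: 0.0% non-enhanced (100 voxels); mean Ktrans 0.0795 min^-1
  mean tumor AUC 170 mM*s
```

The tumor's non-enhanced fraction (29.9%) recovers the constructed
non-enhancing core (30% of the tumor volume, the phantom's stand-in for
post-therapy vascular shutdown); the muscle reference ROIs — four 5×5-pixel
blocks in the central tumor slices, one pixel clear of the tumor border and
centered on the light-beam axis — remain fully enhanced with their true low
perfusion (Ktrans = 0.08 min⁻¹).

The single-curve interface follows the classic R modelling idiom:

```r
tt  <- dce_times(scan_protocol())
cv  <- tissue_concentration(tt, ktrans = 0.25, ve = 0.4, t0 = 120)
fit <- fit_tofts(cv + rnorm(length(tt), sd = 0.02), tt, t0 = 120)
coef(fit)
```

```
   ktrans        ve       kep
0.2532158 0.4015857 0.6305398
```

`print()`, `predict()`, `residuals()` and `plot()` methods are available on
the returned `tofts_fit` object.

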