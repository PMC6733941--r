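---
title: "Resolving vesicle solubilization into swelling and lysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving vesicle solubilization into swelling and lysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesolv)
```

## The scientific problem

When a non-ionic detergent such as Triton X-100 (TX-100) is injected onto
sub-micron lipid vesicles, the membrane is not destroyed in one step. The
widely used three-state picture is: detergent monomers first partition into
the bilayer (the vesicle swells), mixed detergent-lipid micelles then form
within the membrane, and finally the membrane breaks down and lipid is
released into solution. For large unilamellar vesicles (LUVs, 100-200 nm)
these steps are faster than, and invisible to, conventional diffraction-
limited microscopy.

`vesolv` implements the analysis by which the two kinetic steps can be
separated with single-vesicle FRET (svFRET): vesicles carry a
donor/acceptor membrane-dye pair (DiI/DiD) tuned so the apparent FRET
efficiency sits near 0.5. Swelling increases the mean inter-dye distance,
so the efficiency falls while the total emission stays constant; lysis
removes lipid (and dye), so the total emission falls while the efficiency
stays constant. Two orthogonal observables, two half-lives: a swelling
half-life $t_E$ and a lysis half-life $t_L$. The package complements the
trajectory analysis with three supporting assays: ensemble FRET titrations
(Hill analysis of the detergent dose-response), fluorescence correlation
spectroscopy (FCS; vesicle sizing through diffusion times), and QCM-D
(quartz-crystal microbalance with dissipation; mass gain and loss at a
sensor surface).

Because raw instrument data for this experiment class are rarely deposited,
every analysis stage is paired with a synthetic-data generator that embodies
the forward mechanism. All claims the package makes about itself are
therefore checked by parameter recovery: generate at known truth, analyze,
compare.

## The forward trajectory model

For a vesicle injected at time $t_0$, with $s = t - t_0$:

$$E(t) = E_p + (E_0 - E_p)\, 2^{-s/t_E}, \qquad
I_{tot}(t) = I_0 \left(1 - f_{loss}\,(1 - 2^{-s/t_L})\right),$$

with $E(t) = E_0$ and $I_{tot} = I_0$ before injection. Expected channel
intensities are $I_D = (1-E)\,I_{tot}$ and $I_A = E\,I_{tot}$; observed
frames are independent Poisson draws about expectation plus background.
Half-lives are used directly as base-2 exponents, so $t_E$ and $t_L$ are
true half-lives with no $\ln 2$ ambiguity; `halflife_to_tau()` converts for
comparison with e-folding conventions.

Defaults are the observed values for 200 nm PC:PS (65:35) vesicles:
$E_0 = 0.46$, $E_p = 0.22$, ~50% total-intensity loss, 50 ms frames, and
injection at $t_0 = 90$ s (the pre-injection acquisition length shown in the
single-vesicle recordings). The fast no-cholesterol condition at doubled
detergent uses $t_E = 1.2$ s and $t_L = 17.6$ s.

## Fitting the donor trajectory: why two fit forms

Only the donor channel is fitted (it rises during swelling and falls during
lysis, so both half-lives are encoded in one trace). Two parameterizations
are offered:

* **Mechanistic (default).** The forward model's donor expectation is the
  *product* of a saturating rise and a decay,
  $I_D = b\,[1 + (\rho-1)(1-2^{-s/t_E})]\,[1 - f(1-2^{-s/t_L})]$,
  because swelling acts only on the efficiency and lysis only on the total
  intensity. This form recovers noise-free synthetic trajectories to
  machine precision, which makes the generator-fitter round-trip a strict
  correctness oracle.
* **Additive.** The conventional sum of a rise and a decay exponential,
  $I_D = b + A_r(1-2^{-s/t_E}) + A_d(2^{-s/t_L}-1)$. A sum cannot represent
  the rise x decay cross term, so on forward-model data it carries a small
  bias (negligible relative to shot noise when $t_E \ll t_L$) and it is the
  appropriate form when rise and decay really are independent additive
  components.

Both report the same fields (`baseline`, `A_rise`, `A_decay`, `offset`,
half-lives, standard errors); a literal rise exponential of the form
$A e^{t/t_E}$ diverges and is not implemented. Fits use `nls` (port
algorithm) with half-lives bounded to `[frame_dt, 10 x window]`; a
half-life pinned at a bound, or a vanishing decay amplitude, is flagged
rather than silently reported (`t_L` is unidentifiable when there is no
lysis signal). Fitting only constrains, and segmentation only interprets;
phase windows are placed at three half-lives (~88% completion), a constant
chosen for noise robustness rather than optimality.

Injection-time detection (when $t_0$ is not recorded) uses a rolling-mean
change point: the first 10-frame mean departing more than 5 rolling-mean
standard deviations from the expanding pre-window mean, with the per-frame
noise scale estimated robustly from first differences so slow drifts do not
inflate it. A trace whose change point sits at the very first frame returns
the first frame time; a constant trace is an error, not a guess.

## Titration: the Hill model and one deliberate interpretation

Ensemble efficiencies are computed from the 565 nm (donor) and 665 nm
(acceptor) emission bands, and the dose-response is fitted with

$$E(c) = A + (B - A)\,\frac{c^n}{k^n + c^n}.$$

The reference parameter set is $A = 0.43$, $B = 0.12$, $k = 0.39$ mM,
$n = 2.0$. Note the *interpolating* form: $A$ and $B$ are the measured
start and end points of the titration, so the curve runs from $A$ at zero
detergent to $B$ at saturation. A variant sometimes written as
$A + B\,c^n/(k^n+c^n)$ would instead saturate at $A + B$ (0.55 with these
numbers), contradicting the measured endpoint near 0.13; since $B$ is
defined as the measured end-of-titration efficiency, the interpolating form
is the only self-consistent reading and is the one implemented.

## FCS: correlator, model, calibration, sizing

Count traces are correlated with a standard multi-tau scheme (16 lags per
level, bin width doubling per level) using the estimator
$G(\tau) = \langle I(t)I(t+\tau)\rangle / (\langle I_h\rangle\langle
I_t\rangle)$ with symmetric normalization, so uncorrelated signals give
$G = 1$ exactly. The estimator is verified against a brute-force $O(n^2)$
loop implementation to $10^{-12}$. (A published shorthand of the
correlation definition with a "+" in the numerator is constant in $\tau$
and cannot be the fitted quantity; the standard product form is what any
correlator computes.)

Curves are fitted with the open 3D Gaussian-volume diffusion model with an
optional triplet factor,

$$G(\tau) = 1 + b_0 + \frac{1}{N}\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{\tau}{\Omega^2\tau_D}\right)^{-1/2}
\left(1 + A_T e^{-\tau/\tau_T}\right),$$

with weights proportional to the number of averaged lag products
(per-lag standard deviation $\propto n^{-1/2}$), $b_0$ fixed at zero unless
requested, and a small multi-start over the triplet time, which is
otherwise prone to a degenerate minimum at the lower bound. Calibration
with a reference dye of known $D$ (Rhodamine 123,
$D = 4.6\times10^{-10}\,\mathrm{m^2 s^{-1}}$) gives
$\omega_{xy} = \sqrt{4 D \tau_D} = 0.27$ um and the effective focal volume
$V = \pi^{3/2}\,\Omega\,\omega_{xy}^3$. The structure parameter is not
separately reported in the reference experiment; back-solving
$V = 0.53\ \mathrm{um^3}$ with $\omega_{xy} = 0.27$ um under this volume
formula gives $\Omega \approx 4.84$, which is the package default and
should be treated as inferred, not measured. Sizes follow from
Stokes-Einstein, $R_h = k_B T/(6\pi\eta D)$, with water viscosity from a
Vogel-type correlation (the 50 mM Tris buffer is treated as water-like) and
all coefficients reported at 25 C.

The Brownian-dynamics generator moves particles with per-axis step variance
$2 D\, \Delta t$ through a periodic box of half-width
$8\,\omega_{xy}$ (and $8\,\omega_z$ axially) -- large enough that edge
effects are negligible -- and draws Poisson counts from the 3D Gaussian
detection profile. The particle number is set so the mean occupancy of $V$
equals `mean_N`, which fixes the amplitude relation $G(0)-1 = 1/N$ and the
mean count rate at $2^{-3/2}\,\mathrm{brightness} \times N$. Triplet
blinking is a two-state telegraph process; because a joint
diffusion-plus-triplet run at 1 us binning is computationally prohibitive,
the telegraph process is validated in isolation on an immobile emitter,
whose correlation must be exactly $1 + A_T e^{-\tau/\tau_T}$. The inner
loop is compiled (Rcpp) but draws from R's RNG, so seed determinism is
preserved end to end.

## QCM-D: Sauerbrey masses and phase percentages

Frequency shifts convert to areal mass via the Sauerbrey relation
$\Delta m = -C\,\Delta f/n$ with $C = 17.7\ \mathrm{ng\,Hz^{-1}\,cm^{-2}}$
and odd overtone $n$ (7 in the reference experiment). The phase detector
takes the vesicle-layer mass from a pre-injection baseline window, the peak
mass from a 5-point median-filtered post-injection maximum, and the final
mass from a terminal window. Two conventions had to be fixed because
percentages are meaningless without a reference: **gain is referenced to
the vesicle-layer mass, loss to the peak mass**. These choices make the
generator round-trip exact and are configurable in the result fields. A
gain phase is only declared when the peak clears the baseline by three
baseline noise standard deviations, so a vesicle-free control sensor
reports no phases. The synthetic trace uses ramps that are truncated
exponentials renormalized to complete exactly at their phase boundary, plus
a plateau between gain and loss (the window where intact vesicles
rearrange without mass transfer); the plateau also means the median filter
preserves the exact peak, keeping the noiseless round-trip at machine
precision. Sauerbrey assumes a rigid film; vesicle layers are soft, so a
dissipation-to-frequency ratio above $4\times10^{-7}$ per Hz triggers a
warning that the Sauerbrey mass is a lower bound. No viscoelastic (Voigt)
modeling is attempted.

## What the generators do and do not emulate

The generators reproduce: the biphasic mean structure and its Poisson shot
noise; spot images as 2D Gaussians with exact discrete flux and per-pixel
Poisson noise; Brownian transits through a 3D Gaussian focus with optional
triplet blinking; QCM-D gain/plateau/loss mass phases with Gaussian
frequency noise. They deliberately do not emulate: vesicle-to-vesicle
parameter heterogeneity (each generated ensemble is homogeneous at truth),
EMCCD excess noise and gain calibration, spectral crosstalk between
channels, stage drift, vesicle fusion, aggregate transits (except as
injected test artifacts), or viscoelastic sensor response. A green
recovery test therefore establishes estimator correctness and absence of
bias under the stated noise model -- not robustness to every instrumental
pathology of real recordings.

## Numerical choices and degenerate inputs

* All generators draw from a single seeded RNG per call and restore global
  RNG state; identical parameters and seed give identical output.
* `apparent_fret` returns `NA` (not an error) for frames with non-positive
  total intensity, so trajectories keep their time base; negative
  background-corrected intensities are clipped to zero with a warning.
* `distance_from_fret` rejects $E \in \{0, 1\}$ (infinite/zero distance);
  the Foerster radius is a required user input with the literature DiI/DiD
  default of 5.3 nm -- it is not measured by this package.
* Spot detection runs on the time-averaged pre-injection donor image
  (maximal SNR, immobilized vesicles, no tracking); a numerically flat
  image returns zero spots rather than thresholding floating-point wobble.
* Contour matrices normalize every occupied time column to unit mass, so
  columns are comparable occupancy distributions regardless of how many
  vesicles survive to that time.
* Outlier correlation curves are rejected on occupancy (3 MAD from the
  batch median, with a floored MAD so identical noise-free batches still
  reject a deviator) and on relative chi-square (the weighted chi-square
  has no absolute scale when per-lag variances are known only up to a
  constant); batches of two or fewer disable rejection with a warning.

## Known limitations

Gamma-corrected FRET is accepted as a parameter but defaults to 1 (the
DiI/DiD quantum yields are similar enough that apparent and true efficiency
coincide); no orientation-factor or crosstalk modeling. The FCS stage
emulates the two-detector beamsplitter arrangement as a single effective
autocorrelation and does not parse vendor photon-arrival formats. TIFF
support covers exactly the uncompressed 16-bit grayscale subset the
synthetic stacks need. Condition comparisons report means, SEMs and percent
changes; no hierarchical modeling of vesicle heterogeneity is attempted.
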