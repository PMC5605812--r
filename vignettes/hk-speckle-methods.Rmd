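---
title: "Methods: homodyned-K modeling of ultrasonic speckle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homodyned-K modeling of ultrasonic speckle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model family and its assumptions

Ultrasonic speckle arises from coherent interference of echoes from
scatterers far smaller than the resolution cell. When the cell holds many
diffuse scatterers the envelope amplitude is Rayleigh; a periodically
organized structure adds a coherent component (Rician); few effective
scatterers give the heavy-tailed K law; and the homodyned-K (HK) model

$$P(A) = \int_0^\infty A\,u\,J_0(u\varepsilon)\,J_0(uA)\,
  \bigl(1 + u^2\sigma^2/2\bigr)^{-c}\,du$$

covers the whole continuum with a coherent component $\varepsilon$, a
diffuse component $\sigma$ and a clustering degree $c$. The three single
models are its limits: K as $\varepsilon \to 0$ (with shape $m = c$ and
scale $\sqrt{2}/\sigma$), Rician as $c \to \infty$ at fixed
$\sigma^2 c$, Rayleigh as both. All fitting assumes i.i.d. amplitude
samples; see "Analysis window" for how the pipeline approximates that.

The HK law is equivalently a compound model: the per-component variance is
$\sigma^2 w$ with $w \sim \Gamma(c, 1)$ and
$A = \sqrt{(\varepsilon + x)^2 + y^2}$, $x, y \sim N(0, \sigma^2 w)$. This
representation supplies the sampler, the intensity SNR

$$\mathrm{SNR} = \frac{\varepsilon^2 + 2\sigma^2 c}
  {2\sigma\sqrt{\varepsilon^2 c + 2\sigma^2 c + c^2\sigma^2}},$$

whose numerator and denominator are the mean and standard deviation of
$A^2$ under the compound form, and the default density evaluator.

## Numerical evaluation of the HK density

The literal oscillatory integral is ill-suited to tight absolute
tolerances at small $c$: its integrand decays only as $u^{-2c}$ and the
$J_0^2$ product does not change sign on average, so truncation error falls
off as $U^{1-2c}$; adaptive Gauss–Kronrod with 20,000 subdivisions still
reports $\sim 10^{-3}$ error at $c = 1$. The default evaluator therefore
integrates the mathematically identical compound form in the variable
$v = \sqrt{w}$ — the substitution removes the $w^{c-3/2}$ endpoint
singularity that appears for $c$ near 1 — on a composite Gauss–Legendre
grid with panels refined geometrically toward $v = 0$ where the coherent
ridge $\exp(-(A-\varepsilon)^2 / 2\sigma^2 v^2)$ turns on. Against adaptive
quadrature the default rule is accurate to well below $10^{-8}$; a lighter
130-node rule (relative error $< 10^{-5}$) serves the likelihood hot loop.
The literal Bessel-integral route remains available
(`hk_pdf(method = "bessel")`) as an independent cross-check and raises a
diagnostic error rather than silently truncating when its interval budget
cannot meet the tolerance. Bessel functions are evaluated in log space;
$\log I_0$ switches to its Hankel expansion above $x = 50$ (where the
exact routine becomes slow and overflow-prone), and $\log K_\nu$ to a
Debye uniform expansion when the scaled routine overflows. Densities are
floored at $10^{-300}$ inside likelihoods.

## Maximum likelihood and model selection

Fitting follows a cyclic Newton–Raphson scheme on the score equations:
each parameter is updated in turn by a damped Newton step (central finite
differences with relative step $10^{-5}$; updates capped at 50% relative
change; one-sided differences at parameter bounds), and the update feeds
the next score equation. Iteration stops when
$\sum_i |\Delta s_i| \le 10^{-8}$, which sets the `converged` flag, or at
the sweep budget. Because the coordinate scheme zigzags on the
$\sigma^2 c$ ridge — likelihood gains fall below $10^{-9}$ per sweep long
before the parameter rule fires — a likelihood-plateau exit hands over to
a bounded Nelder–Mead direct search (logistic reparametrization of the
box), and the better of the two solutions is kept.

Bounds mirror the evident clamps of published fits: $c \in [1, 100]$,
$\varepsilon \in [0.01, 10]$, $\sigma \in [10^{-3}, 10]$,
$m \in [0.05, 500]$. Initialization is moment-based; notably
$\varepsilon_0^2 = \max(0,\, 2\bar A^2 - \overline{A^2})$, the coherent
level implied by the amplitude mean/power pair.

Models are compared by BIC, $-2\mathcal{L} + m\log n$; the best of
K/Rayleigh/Rician ("OKRR") is the baseline against the HK fit and ties go
to the model with fewer parameters. In the fully developed regime the
data carry no information on $c$ beyond "large", so $\hat c$ saturating at
its bound is expected behaviour, not a solver failure; the same flatness
makes $\hat\varepsilon$ weakly identified at small
$k = \varepsilon/\sigma$, which is exactly what the bias study measures.
The ratio $k$ follows the convention $k = \varepsilon/\sigma$ throughout.

## The synthetic world

**Phantoms.** Scatterer organization is a 1D gamma renewal process —
spacings $\Gamma(\alpha, \beta)$ with $\bar d = \alpha\beta$; $\alpha < 1$
clustered, $\alpha = 1$ Poisson, $\alpha > 1$ regular — lifted
isotropically into a cube along a 3D Hilbert curve by arc length, with
$N = \mathrm{round}(\rho\,(\mathrm{side}/\lambda)^3)$ scatterers and
i.i.d. $N(0,1)$ strengths. Two construction choices matter and were set
after explicit failure analysis:

- *The renewal walk is conditioned to span the curve exactly* ($N+1$
  spacings rescaled to the total length). Unconditioned, the walk end
  over/undershoots by $O(L/\sqrt{N})$, leaving an anomalous end region
  that a $\chi^2$ uniformity test detects. Conditioned, the $\alpha = 1$
  phantom is exactly a uniform order-statistics scatter.
- *The curve order defaults to 9.* Axis-aligned curve segments quantize
  two thirds of the depths onto a lattice of one segment pitch; at order 6
  that pitch (62.5 µm in a 4 mm cube) leaves only ~3 coherent depth planes
  inside an axial resolution cell, so the envelope is a sum of a handful
  of phasors at any density and Rayleigh statistics can never emerge. At
  order 9 the pitch is side/512, far below the wavelength, and a
  uniform-scatterer control and the Hilbert phantom agree.

A cautionary note on nearest-neighbor summaries: clustering collapses NN
distances toward zero, shrinking both their mean and their variance, so
"high spatial variance" intuitions about clustered patterns do not
transfer to NN-distance variance. Organization is therefore quantified by
the variance-to-mean ratio of counts in wavelength-sized cells, which
decreases strictly along $\alpha \in \{0.01, 0.1, 1, 10, 100\}$.

**Pulse-echo stand-in.** Imaging is linear convolution: a
Gaussian-windowed cosine at 5 MHz (2 cycles), sampled at 100 MHz at
1540 m/s; 20 beam lines across the cube face with separable Gaussian beam
weights. Beam widths derive from the stated array geometry: 64 active
elements of 0.154 mm pitch focused at 30 mm give f/3, hence lateral FWHM
$3\lambda \approx 0.92$ mm; the 5 mm element height is unfocused in
elevation, so the elevational FWHM defaults to 5 mm. Envelope detection is
the magnitude of the FFT analytic signal. Omitted physics: diffraction,
depth-dependent focusing, attenuation, element directivity, nonlinear
propagation, and true specular "total reflection" — the section-IV label
is a configuration rule ($\alpha \ge 1 \wedge \rho \ge 50$), not simulated
physics. Consequently a green pipeline test establishes that *organization
and resolution-cell population* drive the selected model the way the
reference analysis describes, not that any published table value is
reproduced; published parameter tables are explicitly out of reproduction
scope, except for the closed-form SNR surface which is exact.

**Analysis window.** The histogram (256 equal-width bins on [0, 1] of the
max-normalized envelope) is built from the image center: the top and
bottom 10% of the phantom depth are excluded, and the window is subsampled
at half the PSF FWHM in both axes. Full pooling of the oversampled
envelope (16× axially) repeats each speckle grain many times and
systematically inflates BIC evidence for the more flexible model;
full-FWHM strides leave only ~100 desk-scale samples, too few for stable
three-parameter fits. Half-FWHM strides (~520 samples, residual neighbor
correlation ~0.5) are the documented compromise; published BIC magnitudes
(~10²) imply reference histograms of the same order.

**Scales.** Desk scale (default): 4 mm cube, scatterer count capped at
$2\times 10^5$, 3×3 grid, 5 realizations. Full scale: 12 mm cube, 4×5
grid, 30 realizations. The bias study draws raw samples
($n = 1000$ by default, $\sigma$ fixed at 1) and excludes $k = 0$, where
the ratio $\hat\varepsilon/\hat\sigma$ is pinned at an unidentifiable
boundary.

## Known limitations

- The clustering-degree contrast across $\alpha$ is only identified at low
  density: with the stated 5 mm elevational slice, every organization at
  $\rho \ge 10$ yields fully developed speckle, and the sparse-clustered
  K shape bottoms out near $\hat m \approx 3.4$ rather than below 3.
- Raw-sample HK fits cost seconds each (the reference method reports
  minutes); histogram fits are ~1 s. Budget-sensitive callers should fit
  histograms.
- The stopping rule $\sum|\Delta s| \le 10^{-8}$ is honored when reached,
  but on ridge-shaped HK likelihoods the direct-search fallback usually
  finishes the job; `converged = FALSE` with `method = "nelder-mead"` is
  the normal outcome there and the local-optimum property is tested
  instead.
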