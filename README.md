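# hkspeckle

First-order statistical modeling of ultrasonic speckle with the
homodyned-K (HK) distribution, for quantitative-ultrasound researchers who
want to ask: *which envelope statistic does my tissue or phantom actually
follow, and what do the fitted parameters say about its scatterer
organization?*

## The models

The envelope amplitude `A >= 0` of coherently interfering sub-resolution
echoes is described by four nested models:

- **Rayleigh** `P(A) = (A/d²) exp(−A²/2d²)` — many diffuse scatterers,
  no coherent component;
- **Rician** `P(A) = (A/g²) exp(−(A²+l²)/2g²) I₀(Al/g²)` — adds a coherent
  level `l` from periodically organized structure;
- **K** `P(A) = (2a/Γ(m)) (aA/2)^m K_{m−1}(aA)` — few effective scatterers
  per resolution cell (shape `m`);
- **homodyned-K**
  `P(A) = ∫₀^∞ A u J₀(uε) J₀(uA) (1 + u²σ²/2)^(−c) du` — coherent
  component `ε`, diffuse component `σ`, and clustering degree `c`, nesting
  K (`ε→0`), Rayleigh (`ε→0, c→∞`) and Rician (`c→∞`).

The package provides numerically robust densities and samplers for all
four, the closed-form HK intensity SNR
`(ε² + 2σ²c) / (2σ √(ε²c + 2σ²c + c²σ²))`, maximum-likelihood fitting by a
cyclic Newton–Raphson scheme with BIC model selection (the HK fit is
compared against the best of the three single models, "OKRR"), a synthetic
3D scatterer-phantom generator whose organization moves continuously from
clustered through random to regular (gamma-renewal spacings lifted into a
cube along a Hilbert space-filling curve), a linear convolution pulse-echo
simulator, and an assessment pipeline over an (α, ρ) organization–density
grid.

## Worked example

```r
library(hkspeckle)

# amplitudes from a homodyned-K truth, fitted by all four models
a <- speckle_sample("hk", hk_params(epsilon = 0.54, sigma = 0.16, c = 5.69),
                    n = 5000, seed = 1)
h <- amplitude_histogram(a, n_bins = 256, range = c(0, max(a)))
cmp <- compare_hk_okrr(h)
cmp
#> <model comparison: HK BIC = 2585.41 vs OKRR (RI) BIC = 2606.49; rel diff 0.82%>
cmp$hk$par
#>   epsilon     sigma         c
#> 0.5443479 0.1525681 6.1689476

hk_intensity_snr(0.54, 0.16, 5.69)
#> [1] 1.092679
```

The fitted HK parameters recover the truth (ε = 0.54, σ = 0.16, c = 5.69)
within sampling error; the selected single model is the Rician — expected,
since at `c ≈ 6` the HK law is already close to its Rician limit — and the
relative BIC difference between HK and OKRR is below 1%, meaning both
describe these data comparably well (with a small edge to HK). The
intensity SNR ≈ 1.09 summarizes the same cell: above 1 indicates a
coherent contribution on top of fully developed speckle.

A phantom-to-fit pipeline run:

```r
g <- run_grid(grid_spec(alphas = c(0.1, 1, 100), rhos = c(1, 10, 100),
                        n_realizations = 5, base_seed = 1))
g$cells[, c("alpha", "rho", "okrr_label", "section", "c_mean", "snr")]
```

Clustered sparse cells (α = 0.1, ρ = 1) select the K model with a low
clustering degree; random dense cells select Rayleigh/Rician with large
`ĉ`.

There is also a command line:

```sh
Rscript exec/hkspeckle phantom --alpha 0.1 --rho 5 --side-mm 4 --seed 7 --out phantom.csv
Rscript exec/hkspeckle fit --input amplitudes.csv --models all --out fits.json
Rscript exec/hkspeckle snr-table --from-params inst/extdata/table1_means.csv --out snr.csv
```

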