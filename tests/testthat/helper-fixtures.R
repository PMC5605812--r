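# Shared fixtures and small oracles used across test files.

# numeric normalization oracle: integrate a density over (0, Inf)
integrate_pdf <- function(f, rel.tol = 1e-9) {
  integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = 1e-10,
            subdivisions = 1000L, stop.on.error = FALSE)$value
}

# reference table of published per-cell HK means and SNR values
ref_means <- reference_hk_means()

# small HK sample reused by CLI tests
hk_fixture_sample <- function(n = 400) {
  speckle_sample("hk", hk_params(0.5, 0.2, 3), n, seed = 123)
}
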