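# shared fixtures: default parameters, rest state, small configs

defaultP <- modelParams()
restDefault <- findRestState(defaultP)

# tiny lattice config for fast structural tests
tinyConfig <- function(duration = 0.5, seed = 1, n = 12, record = "full",
                       noise = FALSE, warmup = 0, dims = 2, ...) {
  simConfig(duration = duration, warmup = warmup, gridN = n,
            domainLength = n * 2 / 64, seed = seed, noise = noise,
            dims = dims, record = record, ...)
}

# analytic heat-kernel solution for a Gaussian bump under pure diffusion
gaussianBump <- function(n, dx, sigma, centre = (n + 1) / 2) {
  x <- ((seq_len(n)) - centre) * dx
  outer(x, x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
}
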