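# Shared small fixtures, built in code at test time.

# A small quiet phantom for unit tests: no bone, no noise, no texture —
# the analytically simplest configuration.
quiet_spec <- function(dims = c(24, 24, 24), ...) {
  phantom_spec(dims = dims, noise_sd = 0, bone = FALSE,
               parenchyma_texture_sd = 0, ...)
}

test_grid <- function(n = 16, spacing = 0.15) {
  list(dims = rep(as.integer(n), 3), spacing = spacing, origin = c(0, 0, 0))
}

# Uniform inflation about the grid center.
scale_field <- function(s, grid) {
  ctr <- grid$origin + (grid$dims - 1) / 2 * grid$spacing
  analytic_field("affine", matrix = diag(3) * s, center = ctr)
}

# An 11-sample synthetic ventilator CSV written to a temp file.
write_trace_csv <- function(path, n = 11) {
  tr <- simulate_ventilator_trace(0.325, 8, hysteresis_width = 0.2,
                                  n_points = n)
  write_ventilator_trace(tr, path)
  tr
}
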