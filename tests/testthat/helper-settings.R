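# Reduced-length settings for unit tests: shorter transients and
# recording windows than the analysis defaults, enough for the strongly
# contracting orbits exercised here.
fast_settings <- function(transient_periods = 300L, record_periods = 64L, ...) {
  run_settings(transient_periods = transient_periods,
               record_periods = record_periods, ...)
}

# central finite differences of the vector field in state, forcing frozen
fd_jacobian <- function(t, state, p, f, h = 1e-6) {
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    up <- state; dn <- state
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (vector_field(t, up, p, f) - vector_field(t, dn, p, f)) / (2 * h)
  }
  J
}
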