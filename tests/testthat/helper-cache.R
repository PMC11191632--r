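# Expensive shared fixtures, computed once per test session.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) assign(name, force(expr), .test_cache)
  get(name, .test_cache)
}

# single-scattering expected-S3 curve at the baseline relative index
single_sweep_curve <- function() {
  cached("single_sweep", sweep_expected_s3(1.195, seq(1, 30, 0.05)))
}

# reflection/transmission MC sweep over the trough-rich X window
mc_sweep_troughs <- function() {
  cached("mc_troughs", sweep_mc_s3(seq(6, 14, 0.5), photons = 20000L, seed = 1L))
}

# coarse MC sweep over the forward-scattering-dominated X range
mc_sweep_wide <- function() {
  cached("mc_wide", sweep_mc_s3(seq(10, 30, 1), photons = 40000L, seed = 11L))
}
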