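# Shared fixtures: phantoms are generated in code (no stored data) and cached
# per session so several test files can reuse the same build.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# small, fast, clean phantom: no motion, no noise, mild shading
tiny_spec <- function(...) {
  phantom_spec(image_size = 48, aif_size = c(24, 18), n_frames = 40, ...)
}

tiny_phantom <- function() {
  cached("tiny", function() build_phantom(tiny_spec(), seed = 42))
}

# one-condition variant for detection tests (stress only, faster)
tiny_stress_phantom <- function() {
  cached("tiny_stress",
         function() build_phantom(tiny_spec(conditions = "stress"), seed = 7))
}

# moderately realistic: motion + noise, stress only
moving_phantom <- function() {
  cached("moving", function()
    build_phantom(tiny_spec(motion_max_px = 3, noise_snr = 20,
                            conditions = "stress"), seed = 11))
}

as_norm_curve <- function(t, c) {
  structure(list(t = t, c = c, baseline_value = 0),
            class = "NormalizedCurve")
}

# painted tissue curve in concentration units for a target MBF, matching the
# phantom's residue convention (used as the forward-model oracle)
oracle_tissue <- function(mbf, aif, fermi, tgrid, dt) {
  amp <- mbf * (1 + exp(-fermi$k * fermi$w))
  irf <- fermi_irf(fermi_irf_params(amp, fermi$k, fermi$w, fermi$tau_d), tgrid)
  synthesize_tissue_curve(aif, irf / 60, dt)
}

expect_pq_error <- function(expr, class) {
  expect_error(expr, class = class)
}
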