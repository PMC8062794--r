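# Shared fixtures, built in code. Datasets are cached per test run because
# generation + calibration is deterministic for a given seed.

.cache <- new.env(parent = emptyenv())

cached_dataset <- function(probe = "2nbdg", params = forward_params()) {
  key <- paste(probe, params$mode, params$seed, params$noise_rel, sep = "_")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- calibrate_dataset(generate_design(probe, params))
  .cache[[key]]
}

noiseless_powerlaw <- function(probe = "2nbdg", p = 5.96, q = -6.44, seed = 5)
  forward_params(mode = "powerlaw", powerlaw_p = p, powerlaw_q = q,
                 noise_rel = 0, seed = seed)
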