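# Shared phantom pipeline results, built once per test run. The two
# end-to-end NNLS pipelines dominate the suite's runtime, so every test
# that needs them reuses the same cached result (seeds fixed).

.tractgr_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .tractgr_cache)) {
    assign(key, builder(), envir = .tractgr_cache)
  }
  get(key, envir = .tractgr_cache)
}

get_crossing_case <- function() {
  cached("crossing", function() {
    ph <- build_phantom(phantom_spec(seed = 1))
    res <- suppressWarnings(suppressMessages(run_phantom_pipeline(ph)))
    list(phantom = ph, result = res)
  })
}

get_single_case <- function() {
  cached("single", function() {
    ph <- build_phantom(phantom_spec(
      bundles = single_bundle(g = 0.65, total_csa = 0.008),
      seed = 3))
    res <- suppressWarnings(suppressMessages(run_phantom_pipeline(ph)))
    list(phantom = ph, result = res)
  })
}

get_calibration_case <- function() {
  cached("calibration", function() {
    ph <- calibration_phantom(seed = 1)
    list(phantom = ph, calib = calibrate_on_phantom(ph))
  })
}
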