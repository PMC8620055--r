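# Heavy phantom runs are computed once per test session and shared across
# test files.

.glomseg_test_cache <- new.env(parent = emptyenv())

default_phantom_run <- function() {
  if (is.null(.glomseg_test_cache$default)) {
    ph <- generate_phantom(phantom_spec())
    report <- run_pipeline(ph$stack)
    validation <- validate_detection(report, ph$truth)
    .glomseg_test_cache$default <- list(ph = ph, report = report,
                                        validation = validation)
  }
  .glomseg_test_cache$default
}

small_phantom_spec <- function(seed) {
  phantom_spec(shape = c(48L, 192L, 192L), glomerulus_count = 12L,
               tubule_count = 120L, large_tube_count = 3L, seed = seed)
}

small_phantom_run <- function(seed) {
  key <- paste0("small", seed)
  if (is.null(.glomseg_test_cache[[key]])) {
    ph <- generate_phantom(small_phantom_spec(seed))
    .glomseg_test_cache[[key]] <- list(ph = ph,
                                       report = run_pipeline(ph$stack))
  }
  .glomseg_test_cache[[key]]
}
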