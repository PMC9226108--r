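# The desk-scale phantom experiment is the study condition for the
# volume-recovery and decile-profile checks.  It is computed once per test
# run and shared between the test blocks that read different parts of it.
acceptance_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sonotkv::run_phantom_experiment(
        sonotkv::experiment_config(seed = 1))
    cache
  }
})
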