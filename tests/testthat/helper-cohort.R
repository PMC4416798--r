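# The default two-subject synthetic cohort, computed once and shared by
# the end-to-end acceptance checks (batch decoding, pseudo-online
# decoding, artifact QC). The final acceptance block releases it.

.cohort_env <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_env$batch)) {
    cfg <- default_config()
    .cohort_env$batch <- run_batch(cfg, seed = 1)
    .cohort_env$online <- run_pseudo_online(.cohort_env$batch, seed = 1)
  }
  .cohort_env
}

release_cohort <- function() {
  rm(list = ls(.cohort_env), envir = .cohort_env)
  invisible(gc())
}
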