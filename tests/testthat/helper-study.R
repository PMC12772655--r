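# The full default study is expensive (~180 lesion instances); it is run
# once per test session and shared by the acceptance blocks that need it.
.study_cache <- new.env(parent = emptyenv())

get_default_study <- function() {
  if (is.null(.study_cache$report))
    .study_cache$report <- suppressWarnings(run_study(study_config()))
  .study_cache$report
}
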