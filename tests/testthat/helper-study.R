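# The end-to-end synthetic study (training two networks and evaluating ten
# test subjects) is expensive, so it is run once and shared by the
# acceptance blocks that interrogate it.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_study(run_config(seed = 1L))
  }
  .study_cache$res
}

mean_cov_by_set <- function(metrics) {
  per_subject <- metrics[!duplicated(paste(metrics$subject,
                                           metrics$image_set)), ]
  vapply(split(per_subject$cov, per_subject$image_set), mean, 1.0)
}
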