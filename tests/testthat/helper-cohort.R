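# Lazily built, cached phantom cohorts shared by the heavier tests.

.cohort_cache <- new.env(parent = emptyenv())

# default study cohort: 144 benign + 62 malignant phantoms, seed 0
cohort_features <- function() {
  if (is.null(.cohort_cache$tab)) {
    cases <- generate_dataset(144, 62, seed = 0)
    .cohort_cache$truth <- phantom_truth(cases)
    .cohort_cache$tab <- features_from_cases(cases)
  }
  .cohort_cache$tab
}

cohort_truth <- function() {
  cohort_features()
  .cohort_cache$truth
}

cohort_svm_trace <- function() {
  if (is.null(.cohort_cache$svm_trace)) {
    .cohort_cache$svm_trace <- forward_select(
      cohort_features(), classifier_spec("svm", seed = 0), k = 10, seed = 0)
  }
  .cohort_cache$svm_trace
}
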