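# Shared fixtures, all generated in code.

# truth values as a named vector
truth_values <- function() {
  truth <- default_truth()
  est <- truth[truth$estimated, ]
  est <- est[order(est$index), ]
  setNames(est$value, est$name)
}

# parameter template with bounds a fixed factor around the truth values
# (the recovery-experiment design: calibration with informative ranges)
tight_template <- function(factor = 2) {
  tv <- truth_values()
  tmpl <- parameter_table()
  i <- tmpl$estimated
  tmpl$lower[i] <- tv[tmpl$name[i]] / factor
  tmpl$upper[i] <- tv[tmpl$name[i]] * factor
  tmpl
}

# noise-free single-replicate dataset under the packaged truth
noise_free_dataset <- function(seed = 1) {
  generate_dataset(default_truth(),
                   noise_model(sigma = 0, replicates = 1), seed = seed)
}

# tiny GA settings for fast unit tests
tiny_config <- function(seed = 1) {
  ga_config(generations = 12, population = 16, seed = seed)
}

# a hand-built 3-row dataset for exact-arithmetic objective checks
toy_dataset <- function(values = c(3, 1.5, 0.8)) {
  validate_dataset(tibble::tibble(
    condition = c("SX", "SX", "CX"),
    observable = c("Tumor", "CTL-P", "Tumor"),
    time_weeks = c(2.5, 5, 5),
    replicate_id = 1L,
    value = values
  ))
}
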