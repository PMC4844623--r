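# Shared fixtures, all generated in code.

default_acq <- acquisition_params()

# A hand-built schedule (bypassing the sampler) for oracle tests.
manual_schedule <- function(conditions, feedback_type = "NONE",
                            left_means = "UP", block_length = 12L,
                            display = if (feedback_type == "EoBF") 2L else 0L) {
  neurofb:::new_schedule(
    tibble::tibble(block = seq_along(conditions), condition = conditions,
                   length_trs = block_length, display_trs = display),
    feedback_type, direction_mapping(left_means),
    sum(conditions == "LEFT")
  )
}

quiet_subject <- subject_params(noise_sd = 0, drift_slope = 0)

# Independent full-convolution oracle (direct O(n*k) sum, no FFT).
conv_oracle <- function(x, k) {
  n <- length(x) + length(k) - 1
  out <- numeric(n)
  for (i in seq_along(x)) {
    out[i:(i + length(k) - 1)] <- out[i:(i + length(k) - 1)] + x[i] * k
  }
  out
}
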