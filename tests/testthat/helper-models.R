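# Shared model fixtures.
#
# default_model(): the typical melanoma-derived parameter set (b = 0.14,
# d = 0.13, d' = 0.17, u = 1e-9, n1 = n2 = 50, n12 = 1).
#
# amplified_model(): a scaled-down regime for simulator tests — mutation
# rate raised and lesion sizes lowered so that M*u products (which drive
# all resistance probabilities) stay in the informative range while runs
# take milliseconds instead of minutes.

default_model <- function(...) resistance_model(...)

amplified_model <- function(u = 1e-5, n1 = 10, n2 = 10, n12 = 1, ...) {
  resistance_model(u = u, n1 = n1, n2 = n2, n12 = n12, ...)
}

# 3-standard-error band check for a Monte-Carlo proportion
expect_within_3se <- function(observed, expected, n, label = NULL) {
  se <- sqrt(max(expected * (1 - expected), 1e-12) / n)
  expect_lt(abs(observed - expected), 3 * se + 1e-12, label = label)
}
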