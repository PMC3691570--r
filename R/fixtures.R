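# Synthetic-data generators emulating the clinical inputs of the analysis:
# longitudinal lesion measurements (for rate-estimation tests) and
# multi-lesion patient cohorts (for patient-level cure reports). All
# generators are deterministic given a seed.

#' Synthetic lesion measurement series
#'
#' Generates an exponentially growing or declining lesion trajectory with
#' multiplicative lognormal measurement noise:
#' `size(t) = size0 * exp(true_rate * t) * exp(noise)`,
#' `noise ~ N(0, noise_sigma^2)`. The true parameters are recorded as
#' attributes for recovery tests.
#'
#' @param true_rate net growth rate per day (negative for decline).
#' @param n_points number of measurements (`>= 2`).
#' @param noise_sigma standard deviation of the log-scale measurement noise.
#' @param size0 initial size in cells.
#' @param dt days between measurements.
#' @param phase phase label for all measurements.
#' @param lesion_id,patient_id identifiers.
#' @param seed optional integer seed.
#' @return A [lesion_series()] with attributes `true_rate`, `noise_sigma`.
#' @export
synth_lesion_series <- function(true_rate = 0.01, n_points = 2,
                                noise_sigma = 0.1, size0 = 1e9, dt = 60,
                                phase = "pre_treatment", lesion_id = "L1",
                                patient_id = "P1", seed = NULL) {
  if (n_points < 2) stop("invalid input: n_points must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  day <- seq(0, by = dt, length.out = n_points)
  size <- size0 * exp(true_rate * day) *
    exp(stats::rnorm(n_points, 0, noise_sigma))
  out <- lesion_series(day = day, size = size, phase = phase,
                       lesion_id = lesion_id, patient_id = patient_id)
  attr(out, "true_rate") <- true_rate
  attr(out, "noise_sigma") <- noise_sigma
  out
}

#' Synthetic cohort of on-treatment decline rates
#'
#' Draws per-lesion decline magnitudes from a lognormal whose median is
#' `median_rate` and whose spread is fitted jointly to the 10th/90th
#' percentile anchors `p10_rate`/`p90_rate`, then emits one measurement
#' series per lesion (rates are negative: sizes shrink).
#'
#' @param n_lesions number of lesions.
#' @param median_rate,p10_rate,p90_rate decline-rate magnitudes per day.
#' @param n_points,noise_sigma,dt passed to [synth_lesion_series()].
#' @param seed optional integer seed.
#' @return List of [lesion_series()] objects with attribute `true_rates`.
#' @export
synth_decline_cohort <- function(n_lesions = 68, median_rate = 0.03,
                                 p10_rate = 0.01, p90_rate = 0.07,
                                 n_points = 4, noise_sigma = 0.05, dt = 30,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z90 <- stats::qnorm(0.9)
  sigma <- (log(p90_rate / median_rate) + log(median_rate / p10_rate)) /
    (2 * z90)
  mags <- stats::rlnorm(n_lesions, log(median_rate), sigma)
  out <- lapply(seq_len(n_lesions), function(i)
    synth_lesion_series(true_rate = -mags[i], n_points = n_points,
                        noise_sigma = noise_sigma, dt = dt,
                        phase = "on_treatment",
                        lesion_id = sprintf("L%d", i)))
  attr(out, "true_rates") <- -mags
  out
}

#' Synthetic multi-lesion patient cohort
#'
#' Emulates a metastatic cohort: per patient, the number of metastases is
#' uniform on `mets_range`, the total burden is log-uniform on
#' `burden_range` (cells), and the burden is allocated across lesions by a
#' symmetric Dirichlet (concentration 1) broken-stick rule. Defaults match a
#' cohort with 1 to 30 metastases and total burdens between 9e8 and 3e11
#' cells.
#'
#' @param n_patients number of patients.
#' @param mets_range integer range (min, max) of metastases per patient.
#' @param burden_range range (min, max) of total burden in cells.
#' @param seed optional integer seed.
#' @return List of [patient()] objects.
#' @export
synth_cohort <- function(n_patients = 22, mets_range = c(1, 30),
                         burden_range = c(9e8, 3e11), seed = NULL) {
  if (any(mets_range < 1) || mets_range[1] > mets_range[2])
    stop("invalid input: mets_range must be positive and ordered")
  if (any(burden_range <= 0) || burden_range[1] > burden_range[2])
    stop("invalid input: burden_range must be positive and ordered")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_patients), function(i) {
    nles <- sample(seq(mets_range[1], mets_range[2]), 1)
    burden <- exp(stats::runif(1, log(burden_range[1]),
                               log(burden_range[2])))
    w <- stats::rgamma(nles, shape = 1)  # symmetric Dirichlet(1) weights
    sizes <- pmax(burden * w / sum(w), 1)
    patient(sprintf("S%02d", i), sizes)
  })
}
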