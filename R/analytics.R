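#' Expected intensity of surviving resistant lineages
#'
#' The quantity `mu = (u/s) log(M s)` governing the expected number of
#' surviving resistant lineages produced while a lesion grows to `M` cells,
#' where `s = 1 - d/b` is the single-cell survival probability and `u` the
#' point mutation rate. Clamped to 0 when `M s < 1`.
#'
#' @param model a [resistance_model()].
#' @param M lesion size (cells) at detection, `>= 1`.
#' @return Nonnegative dimensionless intensity, increasing in `M`.
#' @export
mu_intensity <- function(model, M) {
  model <- as_model(model)
  if (any(M < 1)) stop("invalid input: M must be >= 1 cell")
  s <- survival_probability(model)
  ifelse(M * s < 1, 0, model$u * log(M * s) / s)
}

#' Expected number of doubly resistant cells at detection
#'
#' For dual therapy, the expected number of cells resistant to both drugs in
#' a lesion of `M` cells at detection,
#' `X = M [ n12 mu + (n1 n2 + (n12/2)(n1 + n2 - n12)) mu^2 ]`.
#' With any cross-resistance (`n12 >= 1`) the one-step term `M n12 mu`
#' dominates; with none, `X = M n1 n2 mu^2` exactly.
#'
#' @inheritParams mu_intensity
#' @return Expected cell count (nonnegative).
#' @export
expected_dual_resistant <- function(model, M) {
  model <- as_model(model)
  if (model$k != 2L) stop("invalid input: requires a two-drug model")
  mu <- mu_intensity(model, M)
  n1 <- model$counts$n1; n2 <- model$counts$n2; n12 <- model$counts$n12
  M * (n12 * mu + (n1 * n2 + (n12 / 2) * (n1 + n2 - n12)) * mu^2)
}

#' Expected number of fully resistant cells under k-drug therapy
#'
#' With no cross-resistance classes, the expected number of cells resistant
#' to all `k` drugs is `M n1 n2 ... nk mu^k`.
#'
#' @inheritParams mu_intensity
#' @param counts numeric vector of per-drug resistance mutation counts
#'   (length `k >= 1`).
#' @export
expected_kdrug_resistant <- function(model, M, counts) {
  model <- as_model(model)
  if (length(counts) < 1L) stop("invalid input: empty mutation counts")
  if (any(counts < 0)) stop("invalid input: counts must be nonnegative")
  mu <- mu_intensity(model, M)
  M * prod(counts) * mu^length(counts)
}

#' Probability that dual resistance is present at detection
#'
#' Probability that a lesion of `M` cells harbours at least one surviving
#' doubly resistant lineage when it is detected, `pres = 1 - p1 p2`, where
#' `p1 = exp(M u n12 log(s) / (1 - s))` is the no-one-step-lineage
#' probability and
#' `p2 = exp(M u^2 (2 n1 n2 + n12 (n1 + n2)) log(s) log(M s) / (s (1 - s)))`
#' the no-two-step-lineage probability (the factor `2 n1 n2 + n12 (n1 + n2)`
#' counts the two-step mutational paths to dual resistance). Only the
#' pretreatment rates enter.
#'
#' @inheritParams mu_intensity
#' @return An object of class `resistance_at_detection`: list with `mu`,
#'   `expected_cells_X`, `p1`, `p2`, `pres`.
#' @export
resistance_at_detection <- function(model, M) {
  model <- as_model(model)
  if (model$k != 2L) stop("invalid input: requires a two-drug model")
  s <- survival_probability(model)
  if (s <= 0 || s >= 1)
    stop("invalid parameter: requires 0 < s < 1 (b > d > 0)")
  if (M * s < 1) stop("invalid input: requires M s >= 1")
  u <- model$u
  n1 <- model$counts$n1; n2 <- model$counts$n2; n12 <- model$counts$n12
  p1 <- exp(M * u * n12 * log(s) / (1 - s))
  p2 <- exp(M * u^2 * (2 * n1 * n2 + n12 * (n1 + n2)) *
              log(s) * log(M * s) / (s * (1 - s)))
  structure(list(mu = mu_intensity(model, M),
                 expected_cells_X = expected_dual_resistant(model, M),
                 p1 = p1, p2 = p2, pres = 1 - p1 * p2),
            class = "resistance_at_detection")
}

#' @export
print.resistance_at_detection <- function(x, ...) {
  cat(sprintf("Resistance at detection: pres = %.4g (p1 = %.4g, p2 = %.4g)\n",
              x$pres, x$p1, x$p2))
  cat(sprintf("  expected doubly resistant cells X = %.4g (mu = %.4g)\n",
              x$expected_cells_X, x$mu))
  invisible(x)
}

erad_factors <- function(M, n1, n2, n12, s, sp, u) {
  p1_up <- exp(-M * u * n12)
  p1_down <- exp(M * u * n12 * s / sp)
  A <- (sp - s) / (s * sp)  # > 0 when 0 < s < 1 and sp < 0
  p2_up <- exp(M * u^2 * A *
                 (n1 * (n2 + n12) * log(1 / (s * M) + u * (n2 + n12) * A) +
                  n2 * (n1 + n12) * log(1 / (s * M) + u * (n1 + n12) * A)))
  p2_down <- exp(-M * u^2 * (2 * n1 * n2 + n12 * (n1 + n2)) * s / sp^2)
  list(p1_up = p1_up, p1_down = p1_down, p2_up = p2_up, p2_down = p2_down)
}

#' Probability that therapy eradicates a lesion
#'
#' Four-factor closed form for the probability that simultaneous therapy
#' eradicates a lesion containing `M` cells at the start of treatment:
#' `perad = p1up * p1down * p2up * p2down`, the probabilities that no
#' one-step (cross-resistance) or two-step resistant lineage arises and
#' survives before (`up`) or during (`down`) treatment. Requires effective
#' therapy, i.e. `s' = 1 - d'/b' < 0`; otherwise `perad` is reported as 0
#' with a warning. For a one-drug model the monotherapy reduction is used
#' (only one-step factors, with `n` mutations).
#'
#' @inheritParams mu_intensity
#' @return An object of class `eradication_breakdown`: list with the four
#'   factors, `perad`, `failure = 1 - perad`, and `M`.
#' @export
eradication_probability <- function(model, M) {
  model <- as_model(model)
  if (any(M < 1)) stop("invalid input: M must be >= 1 cell")
  s <- survival_probability(model)
  sp <- treated_survival(model)
  if (sp >= 0) {
    warning("therapy ineffective (s' >= 0): eradication probability is 0")
    f <- list(p1_up = NA_real_, p1_down = NA_real_, p2_up = NA_real_,
              p2_down = NA_real_)
    return(structure(c(f, list(perad = 0, failure = 1, M = M)),
                     class = "eradication_breakdown"))
  }
  if (model$k == 1L) {
    f <- erad_factors(M, 0, 0, model$counts$n, s, sp, model$u)
  } else {
    f <- erad_factors(M, model$counts$n1, model$counts$n2, model$counts$n12,
                      s, sp, model$u)
  }
  perad <- f$p1_up * f$p1_down * f$p2_up * f$p2_down
  structure(c(f, list(perad = perad, failure = 1 - perad, M = M)),
            class = "eradication_breakdown")
}

#' Monotherapy eradication probability
#'
#' Reduction of the four-factor formula to a single drug with `n` resistance
#' mutations: `perad = exp(-M u n) exp(M u n s / s')`; the two-step factors
#' are identically 1.
#'
#' @inheritParams mu_intensity
#' @param n number of point mutations conferring resistance to the drug.
#' @export
monotherapy_eradication <- function(model, M, n = 50) {
  model <- as_model(model)
  mono <- resistance_model(b = model$b, d = model$d, b_treat = model$b_treat,
                           d_treat = model$d_treat, u = model$u, c = model$c,
                           n1 = n, n2 = NULL, n12 = NULL)
  eradication_probability(mono, M)
}

#' @export
print.eradication_breakdown <- function(x, ...) {
  cat(sprintf("Eradication probability for M = %g cells\n", x$M))
  cat(sprintf("  perad = %.4g   (failure = %.4g)\n", x$perad, x$failure))
  cat(sprintf("  factors: p1up = %.4g, p1down = %.4g, p2up = %.4g, p2down = %.4g\n",
              x$p1_up, x$p1_down, x$p2_up, x$p2_down))
  invisible(x)
}

#' Probability of curing a multi-lesion patient
#'
#' Lesions evolve independently, so the probability of eradicating all of a
#' patient's lesions is the product of the per-lesion eradication
#' probabilities.
#'
#' @param model a [resistance_model()].
#' @param pt a [patient()] (or a numeric vector of lesion sizes).
#' @return List with `perad` (cure probability), `failure`, and the vector of
#'   per-lesion eradication probabilities.
#' @export
patient_eradication <- function(model, pt) {
  if (is.numeric(pt)) pt <- patient("patient", pt)
  if (!inherits(pt, "patient")) stop("invalid input: expected a patient()")
  per <- vapply(pt$lesions,
                function(M) eradication_probability(model, M)$perad, 0)
  list(perad = prod(per), failure = 1 - prod(per), per_lesion = per)
}

#' Stem-cell effective-population parameter mapping
#'
#' Uses the number of cancer stem cells as the effective population size:
#' the effective `M` is `total_cells * stem_fraction`, the birth rate is the
#' rate of symmetric renewal, the rate of symmetric differentiation is added
#' to the death rate, and an effective stem-cell mutation rate replaces `u`.
#'
#' @param model a [resistance_model()] supplying the remaining parameters.
#' @param total_cells total cell count of the lesion.
#' @param stem_fraction fraction of cells that are cancer stem cells, in
#'   `(0, 1]`.
#' @param symmetric_renewal_rate rate of symmetric stem-cell self-renewal
#'   (per day); becomes the birth rate.
#' @param symmetric_differentiation_rate rate of symmetric differentiation
#'   (per day); added to the death rate.
#' @param effective_u effective stem-cell mutation rate (defaults to the
#'   model's `u`).
#' @return List with `M_eff` and the remapped `model`.
#' @export
stem_cell_effective_params <- function(model, total_cells, stem_fraction,
                                       symmetric_renewal_rate = model$b,
                                       symmetric_differentiation_rate = 0,
                                       effective_u = model$u) {
  model <- as_model(model)
  if (stem_fraction <= 0 || stem_fraction > 1)
    stop("invalid input: stem_fraction must lie in (0, 1]")
  eff <- update(model, b = symmetric_renewal_rate,
                d = model$d + symmetric_differentiation_rate,
                u = effective_u)
  list(M_eff = total_cells * stem_fraction, model = eff)
}

#' Model predictions at given lesion sizes
#'
#' @param object a [resistance_model()].
#' @param M lesion size(s) in cells.
#' @param type `"eradication"` for the cure probability, `"failure"` for its
#'   complement, `"resistance"` for the probability that resistance is
#'   present at detection, `"expected_resistant"` for the expected fully
#'   resistant cell count.
#' @param ... unused.
#' @return Numeric vector along `M`.
#' @export
predict.resistance_model <- function(object, M = 1e9,
                                     type = c("eradication", "failure",
                                              "resistance",
                                              "expected_resistant"), ...) {
  type <- match.arg(type)
  vapply(M, function(m) {
    switch(type,
           eradication = eradication_probability(object, m)$perad,
           failure = eradication_probability(object, m)$failure,
           resistance = resistance_at_detection(object, m)$pres,
           expected_resistant = expected_dual_resistant(object, m))
  }, 0)
}
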