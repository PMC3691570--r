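# Report generators and configuration plumbing: patient-level failure
# tables, the sequential-vs-simultaneous comparison experiment, and flat
# YAML/JSON parameter files. Rounding is applied only at the report layer.

#' Patient-level treatment-failure table
#'
#' For each patient, the probability that therapy fails to eradicate all
#' lesions (one minus the product of per-lesion eradication probabilities)
#' under three scenarios: monotherapy with `n` resistance mutations, dual
#' therapy with one cross-resistance mutation, and dual therapy with none.
#' Patients are sorted by total burden, descending; probabilities are
#' rounded to three decimals in the report only.
#'
#' @param patients list of [patient()] objects, or a data frame with columns
#'   `patient_id`, `lesion_id`, `cells`. Patients for whom only the total
#'   burden is known can be passed as single-lesion patients (a
#'   single-lesion approximation whose one-step factors are exact because
#'   they are additive in lesion size).
#' @param model a [resistance_model()] supplying rates; its mutation counts
#'   are overridden per scenario.
#' @param n_mono,n_single,n_cross mutation counts: monotherapy `n`, per-drug
#'   `n1 = n2`, and the cross-resistance count of the first dual scenario.
#' @param digits report rounding (`NULL` to disable).
#' @return Data frame with columns `patient_id`, `n_lesions`,
#'   `total_burden`, `failure_mono`, `failure_dual_n12_1`,
#'   `failure_dual_n12_0`.
#' @export
table1_report <- function(patients, model = resistance_model(),
                          n_mono = 50, n_single = 50, n_cross = 1,
                          digits = 3) {
  if (is.data.frame(patients)) {
    need <- c("patient_id", "lesion_id", "cells")
    if (!all(need %in% names(patients)))
      stop("invalid input: need columns ", paste(need, collapse = ", "))
    patients <- lapply(split(patients, patients$patient_id), function(d)
      tryCatch(patient(d$patient_id[1], d$cells), error = function(e) {
        warning("skipping patient ", d$patient_id[1], ": ",
                conditionMessage(e))
        NULL
      }))
    patients <- Filter(Negate(is.null), patients)
  }
  m_dual1 <- update(model, n1 = n_single, n2 = n_single, n12 = n_cross)
  m_dual0 <- update(model, n1 = n_single, n2 = n_single, n12 = 0)
  rows <- lapply(patients, function(pt) {
    if (any(pt$lesions < 1)) {
      warning("skipping patient ", pt$id, ": nonpositive lesion size")
      return(NULL)
    }
    data.frame(
      patient_id = pt$id,
      n_lesions = length(pt$lesions),
      total_burden = sum(pt$lesions),
      failure_mono = 1 - prod(vapply(pt$lesions, function(M)
        monotherapy_eradication(model, M, n = n_mono)$perad, 0)),
      failure_dual_n12_1 = patient_eradication(m_dual1, pt)$failure,
      failure_dual_n12_0 = patient_eradication(m_dual0, pt)$failure)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_burden), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(digits)) {
    for (cl in c("failure_mono", "failure_dual_n12_1", "failure_dual_n12_0"))
      out[[cl]] <- round(out[[cl]], digits)
  }
  out
}

#' Sequential vs simultaneous dual therapy experiment
#'
#' Simulates matched arms of dual therapy on single lesions: both drugs at
#' once versus one drug at a time with a switch at relapse. Reports the cure
#' fraction with binomial standard error and the failure-cause split per
#' arm.
#'
#' @param model a two-drug [resistance_model()].
#' @param M,N detection and relapse sizes (cells).
#' @param reps replicates per arm.
#' @param seed optional integer seed (one stream; the sequential arm follows
#'   the simultaneous arm).
#' @param exact_threshold,max_time passed to the simulator.
#' @return Data frame of class `fig_experiment` with one row per arm:
#'   `mode`, `cure`, `se`, `failure`, `preexisting`, `de_novo`, `n`.
#' @export
sequential_vs_simultaneous <- function(model, M = 1e9, N = M, reps = 1000,
                                       seed = NULL, exact_threshold = 1e4,
                                       max_time = 40000) {
  if (!is.null(seed)) set.seed(seed)
  arm <- function(mode) {
    cs <- simulate(model, nsim = reps, M = M, N = N, mode = mode,
                   exact_threshold = exact_threshold, max_time = max_time)
    s <- summary(cs)
    data.frame(mode = mode, cure = s$estimate, se = s$se,
               failure = 1 - s$estimate,
               preexisting = sum(cs$failure_cause == "preexisting",
                                 na.rm = TRUE) / reps,
               de_novo = sum(cs$failure_cause == "de_novo",
                             na.rm = TRUE) / reps,
               n = reps)
  }
  out <- rbind(arm("simultaneous"), arm("sequential"))
  class(out) <- c("fig_experiment", "data.frame")
  out
}

#' Read model parameters from a flat YAML or JSON config
#'
#' Accepts keys `b, d, b_treat, d_treat, u, c, n1, n2, n12, M, N` (all
#' optional; missing keys take the model defaults). Returns the model plus
#' the sizes.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param overrides named list overriding file values (e.g. from a command
#'   line).
#' @return List with `model` ([resistance_model()]), `M` and `N`.
#' @export
read_model_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  vals <- utils::modifyList(as.list(vals), overrides)
  known <- c("b", "d", "b_treat", "d_treat", "u", "c", "n1", "n2", "n12")
  args <- vals[intersect(names(vals), known)]
  model <- do.call(resistance_model, args)
  M <- if (is.null(vals$M)) 1e9 else as.numeric(vals$M)
  N <- if (is.null(vals$N)) M else as.numeric(vals$N)
  list(model = model, M = M, N = N)
}

#' Serialize an eradication breakdown as JSON
#'
#' @param x an `eradication_breakdown` or `resistance_at_detection`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
breakdown_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
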