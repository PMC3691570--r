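comp_labels <- function(k) {
  if (k == 1L) c("0", "1_pre", "1_post")
  else c("00", "10_pre", "10_post", "01_pre", "01_post",
         "11c_pre", "11c_post", "11s_pre", "11s_post")
}

genotype_of_comp <- function(k) {
  if (k == 1L) c("0", "1", "1")
  else c("00", "10", "10", "01", "01", "11", "11", "11", "11")
}

sim_config <- function(model, M, N, mode, threshold, max_time) {
  model <- as_model(model)
  if (M < 1 || N < 1) stop("invalid input: M and N must be >= 1 cell")
  if (threshold < 1) stop("invalid input: exact_threshold must be >= 1")
  seq_mode <- identical(mode, "sequential")
  if (seq_mode && model$k < 2L)
    stop("invalid input: sequential mode requires a two-drug model")
  cts <- model$counts
  list(k = model$k, b = model$b, d = model$d, b_treat = model$b_treat,
       d_treat = model$d_treat, u = model$u, c = model$c,
       n1 = if (model$k == 1L) cts$n else cts$n1,
       n2 = if (model$k == 1L) 0 else cts$n2,
       n12 = if (model$k == 1L) 0 else cts$n12,
       M = as.numeric(M), N = as.numeric(N), sequential = seq_mode,
       threshold = as.numeric(threshold), max_time = as.numeric(max_time))
}

cause_labels <- c("preexisting", "de_novo")

outcome_frame <- function(raw, cfg) {
  cause <- rep(NA_character_, length(raw$cause))
  known <- !is.na(raw$cause) & raw$cause > 0L
  cause[known] <- cause_labels[raw$cause[known]]
  data.frame(replicate = seq_along(raw$status),
             eradicated = raw$status == 0L,
             detection_time = raw$detection_time,
             relapse_time = raw$relapse_time,
             failure_cause = cause,
             first_relapse_time = raw$first_relapse_time,
             restarts = raw$restarts,
             timed_out = raw$status == 2L)
}

#' Simulate treatment courses of single lesions
#'
#' Runs the hybrid stochastic simulator: each replicate grows a lesion from a
#' single sensitive cell to the detection size `M` (extinct runs are
#' discarded and restarted, i.e. growth is conditioned on non-extinction),
#' then treats it until eradication, relapse at total burden `N`, or
#' `max_time` days. Subpopulations below `exact_threshold` cells are
#' simulated exactly; larger ones deterministically with stochastic mutant
#' seeding.
#'
#' @param object a [resistance_model()].
#' @param nsim number of replicate courses.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param M detection size starting treatment (cells).
#' @param N total burden declaring relapse (and triggering the drug switch in
#'   sequential mode); defaults to `M`.
#' @param mode `"simultaneous"` or `"sequential"` (two-drug models only).
#' @param exact_threshold subpopulation size above which dynamics are treated
#'   deterministically (both switching directions), in cells.
#' @param max_time simulation horizon in days.
#' @param record_trajectory record per-genotype counts every `trajectory_dt`
#'   days for every replicate (keep `nsim` small when enabled).
#' @param trajectory_dt trajectory sampling resolution in days.
#' @param ... unused.
#' @return A data frame of class `therapy_courses` with one row per
#'   replicate (`eradicated`, `detection_time`, `relapse_time`,
#'   `failure_cause`, `first_relapse_time`, `restarts`, `timed_out`), with
#'   the per-compartment states at detection, final states and any recorded
#'   trajectories as attributes.
#' @export
simulate.resistance_model <- function(object, nsim = 1, seed = NULL,
                                      M = 1e9, N = M,
                                      mode = c("simultaneous", "sequential"),
                                      exact_threshold = 1e4,
                                      max_time = 40000,
                                      record_trajectory = FALSE,
                                      trajectory_dt = 1, ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (treated_survival(object) >= 0)
    warning("therapy ineffective (s' >= 0): courses run until max_time")
  cfg <- sim_config(object, M, N, mode, exact_threshold, max_time)
  raw <- cpp_sim_courses(cfg, as.integer(nsim), FALSE, record_trajectory,
                         trajectory_dt)
  out <- outcome_frame(raw, cfg)
  labs <- comp_labels(object$k)
  colnames(raw$state_at_detection) <- labs
  colnames(raw$final_state) <- labs
  attr(out, "state_at_detection") <- raw$state_at_detection
  attr(out, "final_state") <- raw$final_state
  if (record_trajectory)
    attr(out, "trajectories") <- lapply(raw$trajectories, function(m) {
      colnames(m) <- c("time", labs)
      m
    })
  attr(out, "config") <- cfg
  attr(out, "mode") <- mode
  class(out) <- c("therapy_courses", "data.frame")
  out
}

#' @export
print.therapy_courses <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("%d simulated %s course(s), M = %g, N = %g\n",
              nrow(x), attr(x, "mode"), cfg$M, cfg$N))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more replicates\n")
  invisible(x)
}

#' @export
summary.therapy_courses <- function(object, ...) {
  n <- nrow(object)
  cured <- sum(object$eradicated, na.rm = TRUE)
  p <- cured / n
  out <- list(n = n, cured = cured, estimate = p,
              se = sqrt(p * (1 - p) / n),
              timed_out = sum(object$timed_out, na.rm = TRUE),
              cause = table(object$failure_cause),
              median_relapse = stats::median(object$relapse_time,
                                             na.rm = TRUE))
  class(out) <- "summary.therapy_courses"
  out
}

#' @export
print.summary.therapy_courses <- function(x, ...) {
  cat(sprintf("Cure fraction: %.4f (SE %.4f, %d/%d replicates)\n",
              x$estimate, x$se, x$cured, x$n))
  if (length(x$cause))
    cat("Failure causes:",
        paste(names(x$cause), x$cause, sep = " = ", collapse = ", "), "\n")
  if (!is.na(x$median_relapse))
    cat(sprintf("Median relapse time: %.0f days after detection\n",
                x$median_relapse))
  if (x$timed_out > 0)
    cat(x$timed_out, "replicate(s) hit the time cap (undecided)\n")
  invisible(x)
}

#' @param x a `therapy_courses` object simulated with
#'   `record_trajectory = TRUE`.
#' @param replicate which replicate's trajectory to draw.
#' @param log draw the cell-count axis on a log scale (default).
#' @rdname simulate.resistance_model
#' @export
plot.therapy_courses <- function(x, replicate = 1, log = TRUE, ...) {
  trajs <- attr(x, "trajectories")
  if (is.null(trajs))
    stop("no trajectories recorded; simulate with record_trajectory = TRUE")
  m <- trajs[[replicate]]
  k <- attr(x, "config")$k
  geno <- genotype_of_comp(k)
  labs <- unique(geno)
  agg <- sapply(labs, function(g)
    rowSums(m[, -1, drop = FALSE][, geno == g, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(NULL, labs))
  agg[agg < 1e-2] <- NA
  graphics::matplot(m[, "time"], agg, type = "l", lty = 1,
                    col = seq_along(labs), lwd = 2,
                    log = if (log) "y" else "",
                    xlab = "time (days)", ylab = "cells",
                    main = "Simulated lesion trajectory", ...)
  graphics::legend("topleft", legend = labs, col = seq_along(labs),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Grow a lesion to its detection size
#'
#' Runs only the pretreatment phase: exponential growth from a single
#' sensitive cell until the total population first reaches `M` cells,
#' conditioned on non-extinction (extinct runs restart and are counted).
#' Resistant subpopulations carry their pre-treatment origin tags.
#'
#' @inheritParams simulate.resistance_model
#' @param model a [resistance_model()].
#' @param nsim number of independent lesions to grow.
#' @return An object of class `tumor_state`: list with matrix `counts`
#'   (`nsim` rows, one column per compartment), `genotype_counts` aggregated
#'   over cost/origin classes, vectors `time` and `restarts`, and the
#'   configuration.
#' @export
grow_to_detection <- function(model, M = 1e9, nsim = 1, seed = NULL,
                              exact_threshold = 1e4, max_time = 40000) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(model, M, M, "simultaneous", exact_threshold, max_time)
  raw <- cpp_sim_courses(cfg, as.integer(nsim), TRUE, FALSE, 1)
  if (any(raw$status == 2L, na.rm = TRUE))
    stop("timeout: max_time exceeded before reaching detection size")
  counts <- raw$state_at_detection
  labs <- comp_labels(model$k)
  colnames(counts) <- labs
  geno <- genotype_of_comp(model$k)
  gc <- sapply(unique(geno), function(g)
    rowSums(counts[, geno == g, drop = FALSE]))
  if (nsim == 1L) gc <- matrix(gc, nrow = 1,
                               dimnames = list(NULL, unique(geno)))
  structure(list(counts = counts, genotype_counts = gc,
                 time = raw$detection_time, restarts = raw$restarts,
                 config = cfg, model = model),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("%d lesion(s) grown to M = %g cells (mean %.0f days, mean %.1f restarts)\n",
              nrow(x$counts), x$config$M, mean(x$time), mean(x$restarts)))
  cat("Mean genotype counts at detection:\n")
  print(colMeans(x$genotype_counts))
  invisible(x)
}

#' Treat a lesion from a given population state
#'
#' Continues a course from a detection-size state (see
#' [grow_to_detection()]): all genotypes sensitive to at least one
#' administered drug take the treated rates, fully resistant genotypes keep
#' the pretreatment rates, until eradication, relapse at `N`, or `max_time`.
#' In sequential mode the second drug replaces the first at the first
#' relapse.
#'
#' @param state a `tumor_state` from [grow_to_detection()] (its first row is
#'   used), or a named numeric vector of per-compartment counts.
#' @param model a [resistance_model()]; defaults to the model stored in
#'   `state`.
#' @inheritParams simulate.resistance_model
#' @return A list of class `course_outcome`: `eradicated`, `relapse_time`
#'   (days since treatment start, `NA` if eradicated), `failure_cause`
#'   (`"preexisting"`, `"de_novo"` or `NA`), `first_relapse_time`,
#'   `final_state`, and optionally `trajectory`.
#' @export
run_treatment <- function(state, model = NULL, N = NULL,
                          mode = c("simultaneous", "sequential"),
                          seed = NULL, exact_threshold = 1e4,
                          max_time = 40000, record_trajectory = FALSE,
                          trajectory_dt = 1) {
  mode <- match.arg(mode)
  if (inherits(state, "tumor_state")) {
    if (is.null(model)) model <- state$model
    init <- as.numeric(state$counts[1, ])
    if (is.null(N)) N <- state$config$M
  } else {
    init <- as.numeric(state)
    if (is.null(model)) stop("invalid input: supply a resistance_model")
    if (is.null(N)) N <- sum(init)
  }
  model <- as_model(model)
  if (length(init) != length(comp_labels(model$k)))
    stop("invalid input: state length does not match the model's compartments")
  if (!is.null(seed)) set.seed(seed)
  if (treated_survival(model) >= 0)
    warning("therapy ineffective (s' >= 0): course runs until max_time")
  cfg <- sim_config(model, max(sum(init), 1), N, mode, exact_threshold,
                    max_time)
  raw <- cpp_run_treatment(cfg, init, record_trajectory, trajectory_dt)
  out <- list(eradicated = raw$status == 0L,
              timed_out = raw$status == 2L,
              relapse_time = raw$relapse_time,
              failure_cause = if (is.na(raw$cause) || raw$cause == 0L)
                NA_character_ else cause_labels[raw$cause],
              first_relapse_time = raw$first_relapse_time,
              final_state = stats::setNames(raw$final_state,
                                            comp_labels(model$k)),
              time = raw$time, mode = mode)
  if (record_trajectory) {
    colnames(raw$trajectory) <- c("time", comp_labels(model$k))
    out$trajectory <- raw$trajectory
  }
  class(out) <- "course_outcome"
  out
}

#' @export
print.course_outcome <- function(x, ...) {
  if (isTRUE(x$eradicated)) {
    cat(sprintf("Course outcome: eradicated after %.0f days\n", x$time))
  } else if (isTRUE(x$timed_out)) {
    cat("Course outcome: undecided at the simulation time cap\n")
  } else {
    cat(sprintf("Course outcome: relapse at %.0f days (%s resistance)\n",
                x$relapse_time, x$failure_cause))
  }
  invisible(x)
}

#' Classify why a treatment course failed
#'
#' A failure is `"preexisting"` when the relapse-driving resistant
#' subpopulation descends from a lineage founded before the first treatment
#' start, and `"de_novo"` when it was founded during therapy.
#'
#' @param outcome a `course_outcome` from [run_treatment()], or a row of a
#'   `therapy_courses` frame.
#' @return `"preexisting"` or `"de_novo"`.
#' @export
classify_failure <- function(outcome) {
  cause <- if (inherits(outcome, "course_outcome")) {
    if (isTRUE(outcome$eradicated))
      stop("invalid input: cannot classify an eradicated course")
    outcome$failure_cause
  } else {
    if (any(outcome$eradicated))
      stop("invalid input: cannot classify an eradicated course")
    outcome$failure_cause
  }
  cause
}

#' Monte-Carlo estimate of the eradication probability
#'
#' Simulates `reps` full courses and returns the cure fraction with its
#' binomial standard error.
#'
#' @inheritParams simulate.resistance_model
#' @param model a [resistance_model()].
#' @param reps number of replicates (`>= 2`).
#' @return List of class `eradication_estimate`: `estimate`, `se`, `n`,
#'   and the `therapy_courses` frame in `courses`.
#' @export
estimate_eradication <- function(model, M = 1e9, N = M,
                                 mode = c("simultaneous", "sequential"),
                                 reps = 1000, seed = NULL,
                                 exact_threshold = 1e4, max_time = 40000) {
  mode <- match.arg(mode)
  if (reps < 2) stop("invalid input: reps must be >= 2")
  courses <- simulate(model, nsim = reps, seed = seed, M = M, N = N,
                      mode = mode, exact_threshold = exact_threshold,
                      max_time = max_time)
  s <- summary(courses)
  structure(list(estimate = s$estimate, se = s$se, n = reps,
                 courses = courses),
            class = "eradication_estimate")
}

#' @export
print.eradication_estimate <- function(x, ...) {
  cat(sprintf("Estimated eradication probability: %.4f (SE %.4f, n = %d)\n",
              x$estimate, x$se, x$n))
  invisible(x)
}

#' Extinction of a single-type birth-death lineage
#'
#' Exact event-driven simulation of a one-type birth-death process used as a
#' Monte-Carlo cross-check of the closed-form survival probability
#' `s = 1 - d/b`: a lineage is scored extinct if it dies out before reaching
#' `cap` cells.
#'
#' @param b,d birth and death rates per day.
#' @param n0 initial cell count.
#' @param reps number of lineages.
#' @param cap escape size at which a lineage is deemed established.
#' @param max_time horizon in days (lineages alive at the horizon count as
#'   surviving).
#' @param seed optional integer seed.
#' @return Logical vector: `TRUE` for extinct lineages.
#' @export
single_type_extinct <- function(b, d, n0 = 1, reps = 1000, cap = 1000,
                                max_time = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_single_type_extinct(b, d, n0, cap, max_time, as.integer(reps)) == 1L
}
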