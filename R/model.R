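#' Parametric model of tumor growth and drug resistance
#'
#' Constructs the parameter object shared by the closed-form calculators and
#' the stochastic simulator. Tumor cells follow a continuous-time multitype
#' branching process: before treatment every cell divides at rate `b` and dies
#' at rate `d` per day (supercritical, `b > d`); during treatment cells that
#' are sensitive to at least one administered drug divide at `b_treat` and die
#' at `d_treat`, while cells resistant to every administered drug keep the
#' pretreatment rates. At each division the offspring acquires, with
#' probability `u` per available point mutation, resistance to a drug subset:
#' `n1` (`n2`) mutations confer resistance to drug 1 (2) alone and `n12`
#' cross-resistance mutations confer resistance to both at once. Each carried
#' resistance mutation may reduce the net growth rate by a fraction `c`
#' (costly resistance), acting on the birth rate.
#'
#' Supplying only `n1` (leaving `n2` and `n12` `NULL`) defines a monotherapy
#' model with `n = n1` resistance mutations.
#'
#' @param b pretreatment birth (division) rate, per cell per day.
#' @param d pretreatment death rate, per cell per day; must satisfy `d < b`.
#' @param b_treat birth rate of treatment-sensitive cells during treatment.
#' @param d_treat death rate of treatment-sensitive cells during treatment.
#' @param u point mutation probability per base per division.
#' @param c fractional reduction of the net growth rate per carried resistance
#'   mutation, in `[0, 1)`; `0` means neutral resistance.
#' @param n1,n2,n12 nonnegative integer counts of point mutations conferring
#'   resistance to drug 1 only, drug 2 only, and to both drugs (cross
#'   resistance). Leave `n2` and `n12` `NULL` for a one-drug model.
#' @return An object of class `resistance_model`.
#' @examples
#' m <- resistance_model()          # defaults of the dual-therapy analysis
#' survival_probability(m)          # s = 1 - d/b = 1/14
#' eradication_probability(m, M = 1e9)
#' @export
resistance_model <- function(b = 0.14, d = 0.13, b_treat = b, d_treat = 0.17,
                             u = 1e-9, c = 0, n1 = 50, n2 = 50, n12 = 1) {
  for (nm in c("b", "d", "b_treat", "d_treat", "u", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("invalid parameter: '", nm, "' must be a single nonnegative number")
  }
  if (b == 0) stop("invalid parameter: birth rate b must be positive")
  if (b_treat == 0) stop("invalid parameter: b_treat must be positive")
  if (d >= b) stop("subcritical parameters: pretreatment requires b > d")
  if (u > 1) stop("invalid parameter: u must lie in [0, 1]")
  if (c >= 1) stop("invalid parameter: resistance cost c must lie in [0, 1)")
  k <- if (is.null(n2) && is.null(n12)) 1L else 2L
  counts <- if (k == 1L) list(n = n1) else
    list(n1 = n1, n2 = if (is.null(n2)) 0 else n2,
         n12 = if (is.null(n12)) 0 else n12)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop("invalid parameter: mutation count '", nm,
           "' must be a nonnegative integer")
  }
  ntot <- sum(unlist(counts))
  if (u * ntot > 1)
    stop("invalid parameter: u times total mutation count exceeds 1")
  structure(list(b = b, d = d, b_treat = b_treat, d_treat = d_treat,
                 u = u, c = c, k = k, counts = lapply(counts, as.numeric)),
            class = "resistance_model")
}

as_model <- function(x) {
  if (!inherits(x, "resistance_model"))
    stop("expected a 'resistance_model' object; see resistance_model()")
  x
}

#' @export
print.resistance_model <- function(x, ...) {
  cat("Multitype branching model of drug resistance (", x$k,
      if (x$k == 1L) " drug)\n" else " drugs)\n", sep = "")
  cat(sprintf("  pretreatment : b = %g, d = %g  (s = %.5f)\n",
              x$b, x$d, survival_probability(x)))
  cat(sprintf("  on treatment : b' = %g, d' = %g (s' = %.5f)\n",
              x$b_treat, x$d_treat, treated_survival(x)))
  cat(sprintf("  mutation     : u = %g, cost c = %g\n", x$u, x$c))
  cat("  resistance   :", paste(names(x$counts), unlist(x$counts),
                                sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.resistance_model <- function(object, ...) {
  c(b = object$b, d = object$d, b_treat = object$b_treat,
    d_treat = object$d_treat, u = object$u, c = object$c,
    unlist(object$counts))
}

#' Modify parameters of a resistance model
#'
#' @param object a [resistance_model()].
#' @param ... named parameters to replace, as in [resistance_model()].
#' @param evaluate ignored (present for compatibility with [stats::update()]).
#' @return A new `resistance_model`.
#' @export
update.resistance_model <- function(object, ..., evaluate = TRUE) {
  new <- list(...)
  args <- list(b = object$b, d = object$d, b_treat = object$b_treat,
               d_treat = object$d_treat, u = object$u, c = object$c)
  if (object$k == 2L) {
    args <- utils::modifyList(c(args, object$counts), new)
  } else {
    n1 <- object$counts$n
    if (!is.null(new$n)) { n1 <- new$n; new$n <- NULL }
    if (!is.null(new$n1)) { n1 <- new$n1; new$n1 <- NULL }
    two_drug <- any(c("n2", "n12") %in% names(new))  # upgrade to k = 2
    args <- utils::modifyList(args, new)
    args$n1 <- n1
    if (!two_drug) { args["n2"] <- list(NULL); args["n12"] <- list(NULL) }
  }
  do.call(resistance_model, args)
}

#' @export
summary.resistance_model <- function(object, M = 1e9, ...) {
  out <- list(model = object, M = M,
              s = survival_probability(object),
              s_treat = treated_survival(object),
              detection = if (object$k == 2L)
                resistance_at_detection(object, M) else NULL,
              eradication = eradication_probability(object, M))
  class(out) <- "summary.resistance_model"
  out
}

#' @export
print.summary.resistance_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nAt detection size M = %g cells:\n", x$M))
  if (!is.null(x$detection))
    cat(sprintf("  P(resistance present at detection) = %.4f  (E[cells] = %.3g)\n",
                x$detection$pres, x$detection$expected_cells_X))
  cat(sprintf("  P(eradication) = %.4f   P(failure) = %.4f\n",
              x$eradication$perad, x$eradication$failure))
  invisible(x)
}

#' Survival probability of a single-cell lineage
#'
#' Probability that the branching process initiated with a single cell with
#' the pretreatment rates avoids extinction, `s = 1 - d/b`.
#'
#' @param model a [resistance_model()], or a birth rate.
#' @param d death rate, only when `model` is given as a plain birth rate.
#' @return A probability in `[0, 1]`.
#' @export
survival_probability <- function(model, d = NULL) {
  if (inherits(model, "resistance_model")) {
    b <- model$b; d <- model$d
  } else {
    b <- model
  }
  if (!is.numeric(b) || b <= 0) stop("invalid parameter: b must be positive")
  if (d > b) stop("subcritical parameters: survival requires d <= b")
  1 - d / b
}

#' Net survival quantity of sensitive cells under treatment
#'
#' `s' = 1 - d'/b'` for treatment-sensitive cells. Negative values mean the
#' therapy is effective (sensitive populations decline).
#'
#' @param model a [resistance_model()], or a treated birth rate.
#' @param d_treat treated death rate when `model` is a plain rate.
#' @return A signed dimensionless quantity (`<= 1`).
#' @export
treated_survival <- function(model, d_treat = NULL) {
  if (inherits(model, "resistance_model")) {
    b <- model$b_treat; d <- model$d_treat
  } else {
    b <- model; d <- d_treat
  }
  if (!is.numeric(b) || b <= 0)
    stop("invalid parameter: b_treat must be positive")
  1 - d / b
}

#' Division rate of a cell carrying costly resistance mutations
#'
#' Each carried resistance mutation reduces the net growth rate by a factor
#' `1 - c` through the birth rate: a cell carrying `mutation_count` mutations
#' divides at rate `(b - d) (1 - c)^mutation_count + d` and dies at rate `d`.
#'
#' @param model a [resistance_model()].
#' @param mutation_count nonnegative integer number of resistance mutations
#'   carried by the cell.
#' @return Division rate per day; equals `b` when `c = 0` or
#'   `mutation_count = 0` and approaches `d` as `c` approaches 1.
#' @export
division_rate_with_cost <- function(model, mutation_count) {
  model <- as_model(model)
  if (any(mutation_count < 0) || any(mutation_count != round(mutation_count)))
    stop("invalid input: mutation_count must be a nonnegative integer")
  (model$b - model$d) * (1 - model$c)^mutation_count + model$d
}

#' One-division mutation channels of a genotype
#'
#' Genotypes are labelled by resistance bits, e.g. `"00"`, `"10"`, `"01"`,
#' `"11"` for two drugs (`"0"`, `"1"` for one). At each division the offspring
#' of a cell gains resistance to a drug subset with probability `u` times the
#' number of point mutations conferring exactly that subset; a fully resistant
#' cell breeds true.
#'
#' @param genotype genotype label (string of 0/1 of length `k`).
#' @param model a [resistance_model()].
#' @return Named numeric vector of per-division probabilities for each
#'   reachable target genotype (empty for the fully resistant genotype).
#' @export
mutation_channels <- function(genotype, model) {
  model <- as_model(model)
  bits <- genotype_bits(genotype, model$k)
  u <- model$u
  out <- numeric(0)
  subsets <- if (model$k == 1L) list(`1` = c(1L)) else
    list(`10` = 1L, `01` = 2L, `11` = c(1L, 2L))
  cnt <- function(nm) {
    if (model$k == 1L) model$counts$n
    else switch(nm, `10` = model$counts$n1, `01` = model$counts$n2,
                `11` = model$counts$n12)
  }
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    tgt <- bits
    tgt[s] <- 1L
    if (all(tgt == bits)) next  # no new resistance gained
    p <- u * cnt(nm)
    if (p == 0) next
    lab <- paste(tgt, collapse = "")
    out[lab] <- (if (lab %in% names(out)) out[[lab]] else 0) + p
  }
  if (sum(out) > 1)
    stop("invalid parameter: mutation channel probabilities exceed 1")
  out
}

genotype_bits <- function(genotype, k) {
  ch <- strsplit(as.character(genotype), "")[[1]]
  if (length(ch) != k || !all(ch %in% c("0", "1")))
    stop("invalid genotype label for a ", k, "-drug model: ", genotype)
  as.integer(ch)
}

#' Lesions, patients and treatment regimens
#'
#' A lesion is a cell count at the start of treatment; a patient is a named
#' collection of lesions (curing the patient requires eradicating all of
#' them). A regimen records which drugs are given, whether simultaneously or
#' sequentially, the burden `M` at which treatment starts and the burden `N`
#' at which regrowth is declared a relapse (triggering the drug switch in
#' sequential regimens).
#'
#' @param size_M lesion cell count(s) at treatment start (`>= 1`).
#' @return `lesion()` returns a numeric cell count; `patient()` a classed
#'   list with elements `id` and `lesions`; `regimen()` a classed list.
#' @export
lesion <- function(size_M) {
  if (!is.numeric(size_M) || any(!is.finite(size_M)) || any(size_M < 1))
    stop("invalid input: lesion size must be >= 1 cell")
  as.numeric(size_M)
}

#' @rdname lesion
#' @param id patient label.
#' @param lesions numeric vector of lesion sizes (cells).
#' @export
patient <- function(id, lesions) {
  lesions <- lesion(lesions)
  if (length(lesions) < 1L) stop("invalid input: a patient needs >= 1 lesion")
  structure(list(id = as.character(id), lesions = lesions), class = "patient")
}

#' @export
print.patient <- function(x, ...) {
  cat(sprintf("Patient %s: %d lesion(s), total burden %.3g cells\n",
              x$id, length(x$lesions), sum(x$lesions)))
  invisible(x)
}

#' @rdname lesion
#' @param mode `"simultaneous"` (all drugs from the start) or `"sequential"`
#'   (switch to the next drug at relapse).
#' @param start_size_M cells at first treatment.
#' @param relapse_size_N cells triggering relapse detection / drug switch.
#' @param drugs number of drugs in the regimen.
#' @export
regimen <- function(mode = c("simultaneous", "sequential"),
                    start_size_M = 1e9, relapse_size_N = start_size_M,
                    drugs = 2L) {
  mode <- match.arg(mode)
  if (start_size_M < 1 || relapse_size_N < 1)
    stop("invalid input: treatment and relapse sizes must be >= 1 cell")
  if (mode == "sequential" && drugs < 2L)
    stop("invalid input: sequential mode requires at least two drugs")
  structure(list(mode = mode, start_size_M = as.numeric(start_size_M),
                 relapse_size_N = as.numeric(relapse_size_N),
                 drugs = as.integer(drugs)), class = "regimen")
}
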