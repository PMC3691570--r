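# Simulator checks run in a scaled-down regime (small M, amplified u) so
# that resistance probabilities stay informative while runs take seconds;
# all stochastic assertions use 3-standard-error bands under fixed seeds.

test_that("without mutation, growth to detection yields only sensitive cells", {
  m0 <- update(default_model(), u = 0)
  st <- grow_to_detection(m0, M = 1e5, nsim = 5, seed = 101,
                          exact_threshold = 500)
  expect_true(all(st$counts[, "00"] >= 1e5))
  expect_true(all(st$genotype_counts[, c("10", "01", "11")] == 0))
  expect_true(all(st$time > 0))
})

test_that("pretreatment restarts reflect the extinction probability 1 - s", {
  m0 <- update(default_model(), u = 0)
  st <- grow_to_detection(m0, M = 1e4, nsim = 400, seed = 102,
                          exact_threshold = 500)
  attempts <- 400 + sum(st$restarts)
  expect_within_3se(400 / attempts, 1 / 14, attempts)
})

test_that("doubly resistant cells at detection match the analytic theory", {
  # The count of resistant cells is jackpot-dominated (rare early lineages
  # carry most of the mean), so the mean is checked only within a factor
  # band; the sharp check is distributional: pres, the probability that a
  # doubly resistant lineage is alive at the moment of detection, compared
  # with the closed form as a binomial proportion.
  m <- amplified_model(u = 1e-6)
  M <- 1e5
  nrep <- 2000
  st <- grow_to_detection(m, M = M, nsim = nrep, seed = 103,
                          exact_threshold = 500)
  x11 <- st$genotype_counts[, "11"]
  pres_hat <- mean(x11 > 0)
  pres <- resistance_at_detection(m, M)$pres
  expect_within_3se(pres_hat, pres, nrep)
  # factor-band consistency of the heavy-tailed mean
  m2 <- amplified_model()
  st2 <- grow_to_detection(m2, M = M, nsim = 4000, seed = 104,
                           exact_threshold = 500)
  mean11 <- mean(st2$genotype_counts[, "11"])
  X <- expected_dual_resistant(m2, M)
  expect_gt(mean11, X / 2.5)
  expect_lt(mean11, X * 2.5)
})

test_that("a fully sensitive lesion is always eradicated under effective therapy", {
  m0 <- update(default_model(), u = 0)
  cs <- simulate(m0, nsim = 30, seed = 104, M = 1e4, exact_threshold = 500)
  expect_true(all(cs$eradicated))
  expect_true(all(is.na(cs$relapse_time)))
  expect_true(all(is.na(cs$failure_cause)))
})

test_that("hybrid and fully exact simulation agree on the cure probability", {
  m <- resistance_model(u = 1e-4, n1 = 10, n2 = 10, n12 = 1)
  M <- 5e3
  hy <- estimate_eradication(m, M = M, reps = 300, seed = 105,
                             exact_threshold = 300)
  fx <- estimate_eradication(m, M = M, reps = 300, seed = 106,
                             exact_threshold = 1e18)  # everything exact
  se <- sqrt(hy$se^2 + fx$se^2)
  expect_lt(abs(hy$estimate - fx$estimate), 3 * se)
  expect_gt(fx$estimate, 0)  # regime is informative, not degenerate
})

test_that("simulated cure fraction matches the closed-form eradication probability", {
  m <- amplified_model()
  M <- 1e5
  est <- estimate_eradication(m, M = M, reps = 800, seed = 107,
                              exact_threshold = 500)
  expect_within_3se(est$estimate, eradication_probability(m, M)$perad, 800)
})

test_that("sequential therapy with a cross-resistance mutation fails in every replicate", {
  m <- amplified_model()
  cs <- simulate(m, nsim = 120, seed = 108, M = 1e5, mode = "sequential",
                 exact_threshold = 500)
  expect_true(!any(cs$eradicated))
  expect_true(all(!is.na(cs$failure_cause)))
  expect_true(all(cs$relapse_time >= 0, na.rm = TRUE))
})

test_that("costly resistance does not decrease the cure probability", {
  M <- 1e5
  cure <- sapply(c(0, 0.1), function(cost) {
    m <- amplified_model(c = cost)
    estimate_eradication(m, M = M, reps = 500, seed = 109,
                         exact_threshold = 500)$estimate
  })
  se <- sqrt(2 * 0.25 / 500)
  expect_gt(cure[2] - cure[1], -3 * se)
})

test_that("failures are preexisting when mutation is switched off during treatment", {
  m <- amplified_model()
  m_off <- update(m, u = 0)
  set.seed(110)
  causes <- replicate(30, {
    st <- grow_to_detection(m, M = 1e5, exact_threshold = 500)
    out <- run_treatment(st, model = m_off, exact_threshold = 500)
    if (out$eradicated) NA_character_ else out$failure_cause
  })
  expect_true(all(causes == "preexisting", na.rm = TRUE))
  expect_gt(sum(!is.na(causes)), 0)
})

test_that("failures without doubly resistant cells at detection are de novo", {
  m <- amplified_model(n12 = 0)
  cs <- simulate(m, nsim = 250, seed = 111, M = 1e5, exact_threshold = 500)
  x11 <- rowSums(attr(cs, "state_at_detection")[, 6:9])
  idx <- which(!cs$eradicated & x11 == 0)
  expect_gt(length(idx), 0)
  expect_true(all(cs$failure_cause[idx] == "de_novo"))
})

test_that("classify_failure rejects eradicated courses and labels failures", {
  m0 <- update(default_model(), u = 0)
  st <- grow_to_detection(m0, M = 1e4, nsim = 1, seed = 112,
                          exact_threshold = 500)
  out <- run_treatment(st, exact_threshold = 500)
  expect_true(out$eradicated)
  expect_error(classify_failure(out), "eradicated")
  m <- amplified_model()
  st2 <- grow_to_detection(m, M = 1e5, nsim = 1, seed = 113,
                           exact_threshold = 500)
  out2 <- run_treatment(st2, seed = 114, exact_threshold = 500)
  if (!out2$eradicated)
    expect_true(classify_failure(out2) %in% c("preexisting", "de_novo"))
})

test_that("fixed seeds reproduce simulations bit for bit", {
  m <- amplified_model()
  a <- simulate(m, nsim = 40, seed = 115, M = 1e4, exact_threshold = 500)
  b <- simulate(m, nsim = 40, seed = 115, M = 1e4, exact_threshold = 500)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "state_at_detection"),
                   attr(b, "state_at_detection"))
  d <- simulate(m, nsim = 40, seed = 116, M = 1e4, exact_threshold = 500)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("exact-mode counts are integers and trajectories are recorded", {
  m <- amplified_model()
  st <- grow_to_detection(m, M = 5000, nsim = 10, seed = 117,
                          exact_threshold = 1e18)
  expect_true(all(st$counts == floor(st$counts)))
  cs <- simulate(m, nsim = 2, seed = 118, M = 1e4, exact_threshold = 500,
                 record_trajectory = TRUE)
  tr <- attr(cs, "trajectories")[[1]]
  expect_true(ncol(tr) == 10 && nrow(tr) > 1)
  expect_true(all(diff(tr[, "time"]) > 0))
  expect_true(all(tr[, -1] >= 0))
})

test_that("deterministic compartments follow the closed-form exponential when u = 0", {
  m0 <- update(default_model(), u = 0)
  st <- grow_to_detection(m0, M = 1e6, nsim = 1, seed = 119,
                          exact_threshold = 100)
  out <- run_treatment(st, exact_threshold = 100, record_trajectory = TRUE,
                       trajectory_dt = 5)
  tr <- out$trajectory
  n0 <- tr[, "00"]
  keep <- which(n0 > 200)  # deterministic regime only
  rate <- m0$b_treat - m0$d_treat
  pred <- n0[keep[1]] * exp(rate * (tr[keep, "time"] - tr[keep[1], "time"]))
  expect_equal(n0[keep], pred, tolerance = 1e-6)
})

test_that("growth to detection reports a timeout when M is unreachable in time", {
  m0 <- update(default_model(), u = 0)
  expect_error(grow_to_detection(m0, M = 1e9, nsim = 1, seed = 120,
                                 exact_threshold = 500, max_time = 10),
               "timeout")
})

test_that("ineffective treatment warns and leaves courses undecided", {
  m <- resistance_model(d_treat = 0.12)
  expect_warning(cs <- simulate(m, nsim = 2, seed = 121, M = 1e3,
                                exact_threshold = 100, max_time = 200),
                 "ineffective")
  expect_true(all(cs$timed_out))
})
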