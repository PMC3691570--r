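test_that("parameter validation rejects degenerate or subcritical inputs", {
  expect_error(resistance_model(b = 0), "positive")
  expect_error(resistance_model(d = 0.14), "subcritical")
  expect_error(resistance_model(d = 0.2), "subcritical")
  expect_error(resistance_model(u = 2), "u must lie")
  expect_error(resistance_model(c = 1), "cost")
  expect_error(resistance_model(n1 = -1), "nonnegative integer")
  expect_error(resistance_model(n1 = 2.5), "nonnegative integer")
  expect_error(resistance_model(b_treat = 0), "b_treat")
  expect_error(survival_probability(0, 0.1), "positive")
  expect_error(survival_probability(0.1, 0.2), "subcritical")
})

test_that("survival probabilities are exact", {
  expect_identical(survival_probability(0.14, 0), 1)
  expect_identical(survival_probability(0.14, 0.14), 0)
  expect_equal(survival_probability(0.14, 0.13), 1 / 14)
  expect_equal(survival_probability(default_model()), 1 / 14)
  expect_equal(treated_survival(default_model()), 1 - 0.17 / 0.14)
  expect_equal(treated_survival(0.14, 0.14), 0)
  expect_equal(treated_survival(0.10, 0.13), -0.3)
  expect_lt(treated_survival(default_model()), 0)
})

test_that("closed-form survival matches Monte-Carlo extinction frequency", {
  ext <- single_type_extinct(0.14, 0.13, reps = 1e5, seed = 401)
  p <- mean(ext)
  expect_within_3se(1 - p, 1 / 14, length(ext))
})

test_that("mutation channels follow the one-division transition rules", {
  m <- resistance_model(n1 = 50, n2 = 50, n12 = 1, u = 1e-9)
  ch <- mutation_channels("00", m)
  expect_equal(ch[["10"]], 5e-8)
  expect_equal(ch[["01"]], 5e-8)
  expect_equal(ch[["11"]], 1e-9)
  ch10 <- mutation_channels("10", m)
  expect_equal(ch10, c(`11` = 5.1e-8))
  expect_length(mutation_channels("11", m), 0)
  mono <- resistance_model(n1 = 50, n2 = NULL, n12 = NULL)
  expect_equal(mutation_channels("0", mono), c(`1` = 5e-8))
  expect_length(mutation_channels("1", mono), 0)
  expect_error(mutation_channels("2", m), "invalid genotype")
  expect_error(mutation_channels("0", m), "invalid genotype")
})

test_that("channel probabilities are nonnegative and bounded by u times total counts", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(0:60, 3, replace = TRUE)
    m <- resistance_model(n1 = n[1], n2 = n[2], n12 = n[3], u = 10^-runif(1, 4, 9))
    for (g in c("00", "10", "01", "11")) {
      ch <- mutation_channels(g, m)
      expect_true(all(ch >= 0))
      expect_lte(sum(ch), m$u * sum(n) + 1e-15)
    }
  }
  # oversized mutation load is rejected
  expect_error(resistance_model(u = 0.01, n1 = 60, n2 = 60, n12 = 0),
               "exceeds 1")
})

test_that("costly resistance reduces division rate but never below death rate", {
  m <- resistance_model(c = 0.1)
  expect_equal(division_rate_with_cost(m, 2), 0.01 * 0.81 + 0.13)
  expect_equal(division_rate_with_cost(m, 0), m$b)
  m0 <- resistance_model(c = 0)
  expect_equal(division_rate_with_cost(m0, 5), m0$b)
  rates <- division_rate_with_cost(m, 0:10)
  expect_true(all(diff(rates) <= 0))
  expect_true(all(rates >= m$d))
  mc <- resistance_model(c = 1 - 1e-12)
  expect_equal(division_rate_with_cost(mc, 1), mc$d, tolerance = 1e-9)
  expect_error(division_rate_with_cost(m, -1), "nonnegative")
})

test_that("lesion, patient and regimen constructors enforce their invariants", {
  expect_error(lesion(0), ">= 1")
  expect_error(patient("P", numeric(0)), ">= 1 lesion")
  pt <- patient("N22", 8.5e8)
  expect_equal(sum(pt$lesions), 8.5e8)
  expect_error(regimen(mode = "sequential", drugs = 1), "two drugs")
  rg <- regimen("sequential", 1e9, 1e9)
  expect_equal(rg$relapse_size_N, 1e9)
  expect_error(regimen(start_size_M = 0), ">= 1")
})

test_that("model object methods round-trip parameters", {
  m <- default_model()
  cf <- coef(m)
  expect_equal(unname(cf[c("b", "d_treat", "n12")]), c(0.14, 0.17, 1))
  m2 <- update(m, n12 = 0, c = 0.05)
  expect_equal(m2$counts$n12, 0)
  expect_equal(m2$c, 0.05)
  expect_equal(m2$b, m$b)
  expect_output(print(m), "resistance")
  mono <- resistance_model(n1 = 25, n2 = NULL, n12 = NULL)
  expect_equal(update(mono, n = 30)$counts$n, 30)
})
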