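test_that("mu intensity matches its closed form and is linear in u", {
  m <- default_model()
  s <- survival_probability(m)
  expect_equal(mu_intensity(m, 1 / s), 0)
  expect_equal(mu_intensity(m, 1e9), 2.531789e-7, tolerance = 1e-6)
  m2 <- update(m, u = 2e-9)
  expect_equal(mu_intensity(m2, 1e9), 2 * mu_intensity(m, 1e9))
  expect_error(mu_intensity(m, 0.5), ">= 1")
  # increasing in M
  Ms <- 10^seq(6, 12, by = 1)
  expect_true(all(diff(mu_intensity(m, Ms)) > 0))
})

test_that("expected dual-resistant count has the stated limiting forms", {
  M <- 1e9
  m0 <- resistance_model(n12 = 0)
  mu <- mu_intensity(m0, M)
  expect_equal(expected_dual_resistant(m0, M), M * 50 * 50 * mu^2)
  # pure cross-resistance degenerate bracket
  mx <- resistance_model(n1 = 0, n2 = 0, n12 = 1)
  expect_equal(expected_dual_resistant(mx, M), M * mu - (M / 2) * mu^2)
  # one-step dominance at default u: within 1% of M*n12*mu
  m1 <- default_model()
  X <- expected_dual_resistant(m1, M)
  expect_lt(abs(X - M * 1 * mu) / X, 0.01)
  expect_equal(M * mu, 253.1789, tolerance = 1e-6)
})

test_that("k-drug expected resistant count reduces consistently", {
  m <- default_model()
  M <- 1e9
  mu <- mu_intensity(m, M)
  expect_equal(expected_kdrug_resistant(m, M, 50), M * 50 * mu)
  expect_equal(expected_kdrug_resistant(m, M, c(50, 0, 10)), 0)
  m0 <- resistance_model(n12 = 0)
  expect_equal(expected_kdrug_resistant(m0, M, c(50, 50)),
               expected_dual_resistant(m0, M))
  expect_equal(expected_kdrug_resistant(m, M, c(20, 30, 40)),
               M * 20 * 30 * 40 * mu^3)
  expect_error(expected_kdrug_resistant(m, M, numeric(0)), "empty")
})

test_that("resistance at detection behaves across cross-resistance settings", {
  M <- 1e9
  none <- resistance_model(n1 = 0, n2 = 0, n12 = 0)
  expect_equal(resistance_at_detection(none, M)$pres, 0)
  m0 <- resistance_model(n12 = 0)
  r0 <- resistance_at_detection(m0, M)
  expect_identical(r0$p1, 1)   # no one-step path without cross resistance
  expect_lt(r0$p2, 1)
  m1 <- default_model()
  r1 <- resistance_at_detection(m1, M)
  expect_true(r1$p1 > 0 && r1$p1 < 1)
  expect_equal(r1$pres, 1 - r1$p1 * r1$p2)
  expect_true(r1$pres >= 0 && r1$pres <= 1)
})

test_that("eradication breakdown multiplies to perad with factors in (0, 1]", {
  m <- default_model()
  br <- eradication_probability(m, 1e9)
  fac <- c(br$p1_up, br$p1_down, br$p2_up, br$p2_down)
  expect_true(all(fac > 0 & fac <= 1))
  expect_equal(br$perad, prod(fac))
  expect_equal(br$failure + br$perad, 1)
  none <- resistance_model(n1 = 0, n2 = 0, n12 = 0)
  expect_equal(eradication_probability(none, 1e9)$perad, 1)
})

test_that("eradication probability decreases in M, u and n12", {
  for (M in c(1e7, 1e9)) {
    p <- sapply(c(1, 2, 5, 10), function(n12)
      eradication_probability(resistance_model(n12 = n12), M)$perad)
    expect_true(all(diff(p) < 0))
  }
  p_M <- sapply(10^seq(6, 11), function(M)
    eradication_probability(default_model(), M)$perad)
  expect_true(all(diff(p_M) < 0))
  p_u <- sapply(c(1e-10, 1e-9, 1e-8, 1e-7), function(u)
    eradication_probability(resistance_model(u = u), 1e9)$perad)
  expect_true(all(diff(p_u) < 0))
})

test_that("ineffective therapy yields zero eradication with a warning", {
  m <- resistance_model(d_treat = 0.12)  # s' > 0
  expect_warning(br <- eradication_probability(m, 1e9), "ineffective")
  expect_equal(br$perad, 0)
})

test_that("monotherapy reduction matches its two-factor closed form", {
  m <- default_model()
  M <- 8.5e8; n <- 50
  s <- survival_probability(m); sp <- treated_survival(m)
  br <- monotherapy_eradication(m, M, n = n)
  expect_equal(br$perad, exp(-M * 1e-9 * n) * exp(M * 1e-9 * n * s / sp))
  expect_equal(br$p2_up, 1)
  expect_equal(br$p2_down, 1)
  expect_equal(monotherapy_eradication(m, M, n = 0)$perad, 1)
  # equivalent dual parameterization with only a cross-resistance class
  dual <- resistance_model(n1 = 0, n2 = 0, n12 = n)
  expect_equal(eradication_probability(dual, M)$perad, br$perad)
})

test_that("patient-level cure is the product over independent lesions", {
  m <- default_model()
  single <- patient_eradication(m, patient("A", 1e9))
  expect_equal(single$perad, eradication_probability(m, 1e9)$perad)
  multi <- patient_eradication(m, patient("B", c(1e9, 5e8, 2e8)))
  expect_equal(multi$perad, prod(multi$per_lesion))
  expect_equal(multi$per_lesion,
               sapply(c(1e9, 5e8, 2e8), function(M)
                 eradication_probability(m, M)$perad))
  expect_equal(multi$failure + multi$perad, 1)
  expect_error(patient_eradication(m, list(id = "x")), "patient")
})

test_that("stem-cell effective parameters rescale the population", {
  m <- default_model()
  idm <- stem_cell_effective_params(m, 1e9, 1, symmetric_renewal_rate = m$b)
  expect_equal(idm$M_eff, 1e9)
  expect_equal(coef(idm$model), coef(m))
  sc <- stem_cell_effective_params(m, 1e9, 0.05)
  expect_equal(sc$M_eff, 5e7)
  # one-step failure exponent scales with the stem fraction
  f_full <- -log(monotherapy_eradication(m, 1e9, 50)$p1_up)
  f_stem <- -log(monotherapy_eradication(sc$model, sc$M_eff, 50)$p1_up)
  expect_equal(f_stem / f_full, 0.05)
  expect_error(stem_cell_effective_params(m, 1e9, 0), "stem_fraction")
  expect_error(stem_cell_effective_params(m, 1e9, 1.5), "stem_fraction")
})

test_that("predict dispatches the requested quantity over lesion sizes", {
  m <- default_model()
  Ms <- c(1e8, 1e9)
  expect_equal(predict(m, Ms, type = "eradication"),
               sapply(Ms, function(M) eradication_probability(m, M)$perad))
  expect_equal(predict(m, Ms, type = "failure"),
               1 - predict(m, Ms, type = "eradication"))
  expect_equal(predict(m, 1e9, type = "resistance"),
               resistance_at_detection(m, 1e9)$pres)
  expect_equal(predict(m, 1e9, type = "expected_resistant"),
               expected_dual_resistant(m, 1e9))
})
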