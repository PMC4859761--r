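test_that("link functions evaluate and invert correctly", {
  expect_equal(link_eval("logistic", 0), 0.5)
  expect_equal(link_eval("logistic", qlogis(0.33)), 0.33, tolerance = 1e-12)
  expect_equal(link_eval("normal_scaled", 0, sigma = 2), 0.5)
  for (w in c(-2, -0.3, 0, 1.7)) {
    expect_equal(link_inverse("logistic", link_eval("logistic", w)), w,
                 tolerance = 1e-10)
    expect_equal(
      link_inverse("normal_scaled", link_eval("normal_scaled", w, 0.5), 0.5),
      w, tolerance = 1e-10)
  }
  expect_error(link_eval("cauchy", 0), "unknown link_id")
  expect_error(link_eval("normal_scaled", 0, sigma = -1), "sigma")
})

test_that("scenario validation enforces the parameter constraints", {
  expect_error(scenario_spec("A", gamma = 0, rho1 = 0.5), "gamma")
  expect_error(scenario_spec("A", gamma = 0.5, rho1 = 0.5, rho0 = 0.4),
               "rho0 < theta")
  expect_error(scenario_spec("A", gamma = 0.5, rho1 = 0.01, rho0 = 0.05),
               "rho0 <= rho1")
})

test_that("model A reparameterization matches direct arithmetic", {
  sc <- scenario_spec("A", gamma = 0.5, rho1 = 0.5, rho0 = 0.05,
                      theta = 0.33)
  p <- model_params(sc)
  expect_equal(p$beta2, (qlogis(0.33) - qlogis(0.05)) / 0.5,
               tolerance = 1e-12)
  expect_equal(p$beta2, 4.4725, tolerance = 1e-4)
  expect_equal(p$alpha1, qlogis(0.5))
  expect_equal(p$alpha2, qlogis(0.05))
  expect_equal(prob_dlt(p, 0), 0.05, tolerance = 1e-12)
  expect_equal(prob_grade2plus(p, 0), 0.5, tolerance = 1e-12)
})

test_that("every model passes through the MTD anchor P(DLT | gamma) = theta", {
  for (m in c("A", "B", "C", "D", "E")) {
    for (sc in scenario_grid(m)) {
      p <- model_params(sc)
      expect_equal(prob_dlt(p, sc$gamma_true), sc$theta, tolerance = 1e-10,
                   label = sprintf("model %s, %s", m, scenario_id(sc)))
    }
  }
})

test_that("non-PO models keep model A's grade>=1 curve and stated intercepts", {
  scD <- scenario_spec("D", gamma = 0.5, rho1 = 0.5)
  scE <- scenario_spec("E", gamma = 0.5, rho1 = 0.5)
  scA <- scenario_spec("A", gamma = 0.5, rho1 = 0.5)
  pD <- model_params(scD); pE <- model_params(scE); pA <- model_params(scA)
  expect_equal(prob_dlt(pD, 0), 0.02, tolerance = 1e-12)
  expect_equal(prob_dlt(pE, 0), 0.126, tolerance = 1e-12)
  x <- seq(0, 1, length.out = 11)
  expect_equal(prob_grade2plus(pD, x), prob_grade2plus(pA, x))
  expect_equal(prob_grade2plus(pE, x), prob_grade2plus(pA, x))
})

test_that("toxicity curves are ordered and monotone over the dose grid", {
  x <- seq(0, 1, length.out = 1001)
  grids <- c(lapply(c("A", "B", "C", "E"), scenario_grid),
             list(scenario_grid("D", gammas = c(0.5, 0.7))))
  for (grid in grids) {
    for (sc in grid) {
      p <- model_params(sc)
      p1 <- prob_grade2plus(p, x)
      p2 <- prob_dlt(p, x)
      expect_true(all(p2 <= p1 + 1e-12), label = scenario_id(sc))
      expect_true(all(diff(p1) >= -1e-12) && all(diff(p2) >= -1e-12),
                  label = scenario_id(sc))
    }
  }
})

test_that("steepness over the dose grid is ordered C > A > B at gamma = 0.5", {
  x <- seq(0, 1, length.out = 1001)
  max_slope <- function(sc) {
    p2 <- prob_dlt(model_params(sc), x)
    max(diff(p2)) / (x[2] - x[1])
  }
  for (r1 in c(0.2, 0.5, 0.8)) {
    sA <- max_slope(scenario_spec("A", 0.5, r1))
    sB <- max_slope(scenario_spec("B", 0.5, r1))
    sC <- max_slope(scenario_spec("C", 0.5, r1))
    expect_gt(sC, sA)
    expect_gt(sA, sB)
  }
})

test_that("sampled outcome frequencies match the cell probabilities", {
  sc <- scenario_spec("A", gamma = 0.5, rho1 = 0.5)
  p <- model_params(sc)
  x <- 0.5
  probs <- c(p0 = 1 - prob_grade2plus(p, x),
             p1 = prob_grade2plus(p, x) - prob_dlt(p, x),
             p2 = prob_dlt(p, x))
  n <- 10000L
  set.seed(101)
  y <- sample_outcome(p, rep(x, n))
  freq <- tabulate(y + 1L, 3L) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) < 3 * se))
  expect_equal(prob_dlt(p, x), 0.33, tolerance = 1e-12)
})

test_that("degenerate tail probabilities give deterministic outcomes", {
  base <- model_params(scenario_spec("A", 0.5, 0.5))
  never <- base; never$alpha1 <- -60; never$alpha2 <- -70
  always <- base; always$alpha1 <- 70; always$alpha2 <- 60
  set.seed(7)
  expect_true(all(sample_outcome(never, rep(0, 200)) == 0L))
  expect_true(all(sample_outcome(always, rep(0, 200)) == 2L))
})

test_that("model D crossing at a low true MTD raises a model inconsistency", {
  sc <- scenario_spec("D", gamma = 0.1, rho1 = 0.2)
  p <- model_params(sc)
  # curves cross near x = 2.64 * gamma; beyond it the trinary model is invalid
  expect_lt(prob_grade2plus(p, 0.9), prob_dlt(p, 0.9))
  set.seed(8)
  expect_error(sample_outcome(p, 0.9), "model inconsistency")
  expect_silent(invisible(sample_outcome(p, 0.1)))
})

test_that("doses outside [0, 1] are rejected", {
  p <- model_params(scenario_spec("A", 0.5, 0.5))
  expect_error(prob_dlt(p, -0.1), "\\[0, 1\\]")
  expect_error(prob_grade2plus(p, 1.2), "\\[0, 1\\]")
})
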