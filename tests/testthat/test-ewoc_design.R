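test_that("log-likelihood matches closed-form single-record values", {
  expect_equal(ewoc_log_likelihood("binary", 0.05, gamma = 0.5,
                                   doses = numeric(0), y = integer(0)), 0)
  # one DLT at x = gamma: the reparameterization makes p(gamma) = theta
  for (g in c(0.2, 0.5, 0.9)) {
    expect_equal(
      ewoc_log_likelihood("binary", rho0 = 0.1, gamma = g,
                          doses = g, y = 2L, theta = 0.33),
      log(0.33), tolerance = 1e-12)
  }
  # one safe outcome at x = 0: p(0) = rho0
  expect_equal(
    ewoc_log_likelihood("binary", rho0 = 0.07, gamma = 0.4,
                        doses = 0, y = 0L),
    log(1 - 0.07), tolerance = 1e-12)
  # po trinomial cells at x = 0 are (1 - rho1, rho1 - rho0, rho0)
  expect_equal(
    ewoc_log_likelihood("po", rho0 = 0.05, rho1 = 0.3, gamma = 0.5,
                        doses = c(0, 0, 0), y = c(0L, 1L, 2L)),
    log(0.7) + log(0.25) + log(0.05), tolerance = 1e-12)
  # degenerate cell probability -> -Inf, not an exception
  expect_identical(
    ewoc_log_likelihood("po", rho0 = 0.1, rho1 = 0.1, gamma = 0.5,
                        doses = 0.2, y = 1L),
    -Inf)
})

test_that("draws stay in the prior support and the prior is reproduced", {
  ec <- ewoc_config("po", n_burnin = 2000, n_keep = 4000)
  set.seed(31)
  f <- mh_sample(ec, doses = 0, y = 0L, diagnostics = FALSE)
  d <- f$draws
  expect_true(all(d[, "rho0"] >= 0 & d[, "rho0"] <= 0.33))
  expect_true(all(d[, "gamma"] >= 0 & d[, "gamma"] <= 1))
  expect_true(all(d[, "rho1"] >= d[, "rho0"] & d[, "rho1"] <= 1))
  expect_gt(f$acceptance_rate, 0.2)
  expect_lt(f$acceptance_rate, 0.6)

  # with only the forced first patient at x = 0 the likelihood involves rho0
  # alone, so the gamma marginal equals its Unif[0,1] prior; thin the chain
  # before the iid-based KS test
  ecb <- ewoc_config("binary", n_burnin = 2000, n_keep = 4000)
  set.seed(32)
  fb <- mh_sample(ecb, doses = 0, y = 0L, diagnostics = FALSE)
  g <- fb$draws[, "gamma"]
  g_thin <- g[seq(1, length(g), by = 20)]
  expect_gt(ks.test(g_thin, "punif")$p.value, 0.01)
  expect_lt(abs(next_dose(fb, 0.25) - 0.25), 0.03)
})

test_that("MH posterior agrees with deterministic grid quadrature", {
  doses <- c(0, 0.25, 0.4, 0.3)
  y <- c(0L, 0L, 2L, 0L)
  q <- quad_binary_posterior(doses, y)
  set.seed(11)
  f <- mh_sample(ewoc_config("binary"), doses, y, diagnostics = FALSE)
  expect_lt(abs(next_dose(f, 0.25) - q$quantile(0.25)), 0.02)
  expect_lt(abs(mean(f$draws[, "gamma"]) - q$mean), 0.02)

  d2 <- c(0, 0.25, 0.4, 0.3, 0.35)
  y2 <- c(0L, 1L, 2L, 0L, 1L)
  qp <- quad_po_posterior(d2, y2)
  set.seed(12)
  fp <- mh_sample(ewoc_config("po"), d2, y2, diagnostics = FALSE)
  expect_lt(abs(next_dose(fp, 0.25) - qp$quantile(0.25)), 0.02)
  expect_lt(abs(mean(fp$draws[, "gamma"]) - qp$mean), 0.02)
})

test_that("next_dose uses the right-continuous inverse-ecdf convention", {
  fake <- list(draws = cbind(gamma = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(next_dose(fake, 0.25), 0.1)   # ceiling(0.25 * 4) = 1st
  expect_equal(next_dose(fake, 0.26), 0.2)
  degenerate <- list(draws = cbind(gamma = rep(0.37, 50)))
  expect_equal(next_dose(degenerate, 0.25), 0.37)
  expect_error(next_dose(list(draws = cbind(gamma = numeric(0)))), "empty")
})

test_that("recommendations are coherent under one extra observation", {
  base_d <- c(0, 0.25, 0.3, 0.35, 0.3)
  base_y <- c(0L, 0L, 0L, 2L, 0L)
  ec <- ewoc_config("binary")
  set.seed(21)
  rec0 <- next_dose(mh_sample(ec, base_d, base_y, diagnostics = FALSE))
  set.seed(21)
  rec_dlt <- next_dose(mh_sample(ec, c(base_d, rec0), c(base_y, 2L),
                                 diagnostics = FALSE))
  set.seed(21)
  rec_safe <- next_dose(mh_sample(ec, c(base_d, rec0), c(base_y, 0L),
                                  diagnostics = FALSE))
  mc_tol <- 0.02
  expect_lte(rec_dlt, rec0 + mc_tol)
  expect_gte(rec_safe, rec0 - mc_tol)
})

test_that("po and binary recommendations are close when no grade 2 was seen", {
  # the PO likelihood reads Y=0 through the grade>=1 curve, so with no
  # grade-2 events its posterior sits slightly HIGHER than the binary one;
  # exact quadrature puts the structural gap at 0.03-0.04 on histories of
  # this length, so assert the sign and a 0.05 bound
  # computed exactly by quadrature so the check is free of sampler noise
  d <- c(0, 0.25, 0.35, 0.3, 0.4)
  y <- c(0L, 0L, 2L, 0L, 0L)
  rec_b <- quad_binary_posterior(d, y)$quantile(0.25)
  rec_p <- quad_po_posterior(d, y)$quantile(0.25)
  expect_gte(rec_p, rec_b)
  expect_lt(abs(rec_p - rec_b), 0.05)
})

test_that("a full EWOC trial enrolls 30, starts at 0, then doses near 0.25", {
  sc <- scenario_spec("A", gamma = 0.5, rho1 = 0.5)
  ec <- ewoc_config("binary", n_burnin = 2000, n_keep = 2000)
  set.seed(51)
  tr <- run_ewoc_trial(ec, outcome_sampler(sc))
  expect_equal(tr$n_enrolled, 30L)
  expect_equal(nrow(tr$history), 30L)
  expect_equal(tr$history$dose[1], 0)
  expect_equal(tr$history$y[1], 0L)
  expect_lt(abs(tr$history$dose[2] - 0.25), 0.03)
  expect_true(all(tr$history$dose >= 0 & tr$history$dose <= 1))
  set.seed(51)
  tr2 <- run_ewoc_trial(ec, outcome_sampler(sc))
  expect_identical(tr$history, tr2$history)
})

test_that("the end-of-trial estimate recovers the MTD at gamma = 0.5", {
  sc <- scenario_spec("A", gamma = 0.5, rho1 = 0.5)
  ec <- ewoc_config("binary", n_burnin = 1000, n_keep = 1000)
  est <- numeric(100)
  for (i in seq_along(est)) {
    set.seed(replicate_seed(7, "EWOC", scenario_id(sc), i))
    est[i] <- run_ewoc_trial(ec, outcome_sampler(sc))$estimate
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
})
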