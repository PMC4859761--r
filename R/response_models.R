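#' Specify a true dose-toxicity scenario
#'
#' A scenario fixes the generating truth for one simulation cell: the
#' response model (one of five curves A-E), the target DLT probability
#' theta, the true MTD gamma on the standardized dose scale \[0, 1\], and
#' the baseline toxicity probabilities rho1 = P(Y >= 1 | x = 0) and
#' rho0 = P(Y = 2 | x = 0).
#'
#' Patient outcomes are trinary: Y = 0 for worst grade 0-1, Y = 1 for
#' grade 2, and Y = 2 for grade 3-4, i.e. a dose-limiting toxicity (DLT).
#' The MTD gamma is the dose at which P(Y = 2 | x) equals theta.
#'
#' The five models are: (A) proportional-odds logistic; (B) scaled-normal
#' link with sigma = 0.5 ("flat"); (C) scaled-normal link with sigma = 2
#' ("steep"); (D) non-proportional-odds logistic with DLT-curve intercept
#' rho0 = 0.02; (E) non-proportional-odds logistic with rho0 = 0.126.
#' For D and E the grade >= 1 curve is that of model A under the same
#' scenario; only the DLT curve is perturbed.
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param gamma true MTD, in (0, 1].
#' @param rho1 true P(Y >= 1 | x = 0), in (0, 1).
#' @param rho0 true P(Y = 2 | x = 0), in (0, theta) and <= rho1.  The
#'   scenario grid of the simulation study fixes (gamma, rho1) only; 0.05 is
#'   the package's documented default for the proportional-odds models.
#' @param theta target DLT probability at the MTD (default 0.33).
#' @return an object of class `"scenario_spec"`.
#' @seealso [model_params()], [scenario_grid()]
#' @export
scenario_spec <- function(model_id, gamma, rho1, rho0 = 0.05, theta = 0.33) {
  model_id <- match.arg(model_id, c("A", "B", "C", "D", "E"))
  stopifnot(is.numeric(gamma), length(gamma) == 1L,
            is.numeric(rho1), length(rho1) == 1L,
            is.numeric(rho0), length(rho0) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (!(gamma > 0 && gamma <= 1)) {
    stop("invalid scenario: `gamma` must be in (0, 1]", call. = FALSE)
  }
  if (!(rho0 > 0 && rho0 < theta)) {
    stop("invalid scenario: need 0 < rho0 < theta", call. = FALSE)
  }
  if (!(rho1 >= rho0 && rho1 < 1)) {
    stop("invalid scenario: need rho0 <= rho1 < 1", call. = FALSE)
  }
  if (!(theta > 0 && theta < 1)) {
    stop("invalid scenario: `theta` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(model_id = model_id, theta = theta, gamma_true = gamma,
         rho1_true = rho1, rho0_true = rho0),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> model %s: theta=%.3g, gamma=%.3g, rho1=%.3g, rho0=%.3g\n",
    x$model_id, x$theta, x$gamma_true, x$rho1_true, x$rho0_true))
  invisible(x)
}

#' Build the standard 3 x 3 scenario grid
#'
#' Crosses the true MTD values with the true rho1 values for one response
#' model, yielding the nine simulation scenarios of the study.
#'
#' @param model_id response model, see [scenario_spec()].
#' @param gammas true MTD values (default `c(0.1, 0.5, 0.7)`).
#' @param rho1s true rho1 values (default `c(0.2, 0.5, 0.8)`).
#' @inheritParams scenario_spec
#' @return a named list of `scenario_spec` objects.
#' @export
scenario_grid <- function(model_id = "A", gammas = c(0.1, 0.5, 0.7),
                          rho1s = c(0.2, 0.5, 0.8),
                          rho0 = 0.05, theta = 0.33) {
  out <- list()
  for (g in gammas) {
    for (r1 in rho1s) {
      sc <- scenario_spec(model_id, gamma = g, rho1 = r1,
                          rho0 = rho0, theta = theta)
      out[[scenario_id(sc)]] <- sc
    }
  }
  out
}

#' Scenario identifier string
#' @param scenario a `scenario_spec`.
#' @return a character scalar such as `"A_g0.5_r0.2"`.
#' @export
scenario_id <- function(scenario) {
  sprintf("%s_g%g_r%g", scenario$model_id,
          scenario$gamma_true, scenario$rho1_true)
}

# non-PO DLT-curve intercepts for models D and E
.rho0_override <- c(D = 0.02, E = 0.126)

#' Derive generating-curve parameters from a scenario
#'
#' Converts the clinician-facing parameterization (rho0, rho1, gamma, theta)
#' into the intercepts and slopes of the two toxicity curves
#' P(Y >= j | x) = F(alpha_j + beta_j x), j = 1 (grade >= 1) and j = 2 (DLT).
#'
#' For the proportional-odds models the inversion is
#' alpha1 = F^-1(rho1), alpha2 = F^-1(rho0),
#' beta = (F^-1(theta) - F^-1(rho0)) / gamma, so that the DLT curve passes
#' through (0, rho0) and (gamma, theta) exactly.
#'
#' For models B and C the probit-anchored curves are additionally scaled by
#' sigma about the point where each curve crosses theta: the linear
#' predictor becomes `qnorm(theta) + sigma * (a_j + b x - qnorm(theta))`.
#' This preserves P(Y = 2 | gamma) = theta exactly while sigma > 1 steepens
#' and sigma < 1 flattens both curves (the anchored probit family is
#' otherwise invariant to a scale parameter in the link).  The resulting
#' curves are plain probit curves with rescaled coefficients.
#'
#' Models D and E keep model A's grade >= 1 curve and replace the DLT curve
#' by a logistic curve through (0, rho0_override) and (gamma, theta), with
#' rho0_override = 0.02 (D) or 0.126 (E).
#'
#' @param scenario a [scenario_spec()].
#' @return an object of class `"model_params"` with fields `alpha1`,
#'   `alpha2`, `beta1`, `beta2`, `link_id` (`"logistic"` or `"probit"`) and
#'   `sigma`.
#' @export
model_params <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  th <- scenario$theta
  g  <- scenario$gamma_true
  r0 <- scenario$rho0_true
  r1 <- scenario$rho1_true
  if (g <= 0) stop("degenerate scenario: gamma must be > 0", call. = FALSE)
  if (r0 >= th) stop("invalid scenario: rho0 >= theta", call. = FALSE)

  id <- scenario$model_id
  if (id %in% c("A", "D", "E")) {
    # model A's proportional-odds logistic curves
    a1 <- stats::qlogis(r1)
    a2 <- stats::qlogis(r0)
    b  <- (stats::qlogis(th) - stats::qlogis(r0)) / g
    if (id == "A") {
      prm <- list(alpha1 = a1, alpha2 = a2, beta1 = b, beta2 = b,
                  link_id = "logistic", sigma = NA_real_)
    } else {
      r0o <- .rho0_override[[id]]
      a2o <- stats::qlogis(r0o)
      b2o <- (stats::qlogis(th) - stats::qlogis(r0o)) / g
      prm <- list(alpha1 = a1, alpha2 = a2o, beta1 = b, beta2 = b2o,
                  link_id = "logistic", sigma = NA_real_)
    }
  } else {
    sigma <- if (id == "B") 0.5 else 2
    qt <- stats::qnorm(th)
    a1 <- stats::qnorm(r1)
    a2 <- stats::qnorm(r0)
    b  <- (qt - stats::qnorm(r0)) / g
    # scale the linear predictor by sigma about the theta crossing
    prm <- list(alpha1 = qt * (1 - sigma) + sigma * a1,
                alpha2 = qt * (1 - sigma) + sigma * a2,
                beta1  = sigma * b, beta2 = sigma * b,
                link_id = "probit", sigma = sigma)
  }
  structure(c(prm, list(model_id = id, theta = th,
                        gamma_true = g, rho0_true = r0, rho1_true = r1)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> model %s (%s link): alpha1=%.4g beta1=%.4g | alpha2=%.4g beta2=%.4g\n",
    x$model_id, x$link_id, x$alpha1, x$beta1, x$alpha2, x$beta2))
  invisible(x)
}

.curve_eval <- function(link_id, w) {
  switch(link_id,
    logistic = stats::plogis(w),
    probit   = stats::pnorm(w),
    stop("unknown link_id: ", link_id, call. = FALSE))
}

.check_dose <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("dose `x` must lie in [0, 1]", call. = FALSE)
  }
}

#' True toxicity probabilities of a generating model
#'
#' `prob_dlt()` returns P(Y = 2 | x) and `prob_grade2plus()` returns
#' P(Y >= 1 | x), i.e. the probability of a grade 2 or worse toxicity, for
#' doses on the standardized scale.
#'
#' @param params a [model_params()] object.
#' @param x numeric vector of doses in \[0, 1\].
#' @return vector of probabilities.
#' @export
prob_dlt <- function(params, x) {
  stopifnot(inherits(params, "model_params"))
  .check_dose(x)
  .curve_eval(params$link_id, params$alpha2 + params$beta2 * x)
}

#' @rdname prob_dlt
#' @export
prob_grade2plus <- function(params, x) {
  stopifnot(inherits(params, "model_params"))
  .check_dose(x)
  .curve_eval(params$link_id, params$alpha1 + params$beta1 * x)
}

#' Sample trinary toxicity outcomes
#'
#' Draws Y in \{0, 1, 2\} with P(Y = 2) = `prob_dlt(params, x)` and
#' P(Y >= 1) = `prob_grade2plus(params, x)`, using R's RNG stream.
#'
#' Non-proportional-odds models can place the DLT curve above the
#' grade >= 1 curve at high doses (model D with a low true MTD); sampling
#' there is a model inconsistency and raises an error rather than silently
#' clamping the grade 2 cell probability.
#'
#' @inheritParams prob_dlt
#' @param n number of independent outcomes to draw per call (doses recycle).
#' @return integer vector of outcomes in \{0, 1, 2\}.
#' @export
sample_outcome <- function(params, x, n = length(x)) {
  stopifnot(inherits(params, "model_params"))
  .check_dose(x)
  p2 <- prob_dlt(params, x)
  p1 <- prob_grade2plus(params, x)
  if (any(p1 < p2 - 1e-12)) {
    stop(sprintf(
      "model inconsistency: P(Y>=1|x) < P(Y=2|x) for model %s at dose %.4g",
      params$model_id, x[which(p1 < p2 - 1e-12)[1L]]), call. = FALSE)
  }
  u <- stats::runif(n)
  as.integer(ifelse(u < p2, 2L, ifelse(u < p1, 1L, 0L)))
}

#' Outcome sampler bound to one generating model
#'
#' Convenience constructor used by the trial engine: returns a function of
#' a single dose that draws one trinary outcome from the scenario's truth.
#'
#' @param scenario a [scenario_spec()] or [model_params()] object.
#' @return a function `function(dose) -> integer in {0, 1, 2}`.
#' @export
outcome_sampler <- function(scenario) {
  params <- if (inherits(scenario, "model_params")) scenario
            else model_params(scenario)
  function(dose) sample_outcome(params, dose, n = 1L)
}
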