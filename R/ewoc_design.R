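#' EWOC design configuration
#'
#' Escalation with overdose control doses each incoming patient at the
#' alpha-quantile of the current marginal posterior of the MTD, so that the
#' posterior probability of exceeding the MTD equals the feasibility bound
#' alpha.  The `"binary"` variant models DLT / no-DLT responses; the
#' `"po"` variant (EWOC-PO) uses the proportional-odds trinary likelihood
#' and also learns from grade 2 toxicities.
#'
#' @param variant `"binary"` or `"po"`.
#' @param theta target DLT probability (default 0.33).
#' @param alpha_feas feasibility bound (default 0.25).
#' @param n_patients fixed trial size (default 30).
#' @param n_burnin,n_keep Metropolis-Hastings burn-in and retained
#'   iterations (default 4000 each; desk-scale runs use 2000).
#' @param proposal_scales random-walk step sizes on the transformed
#'   (rho0\[, rho1\], gamma) coordinates; the defaults were tuned once on
#'   pilot histories to 20-50 percent acceptance.
#' @return an object of class `"ewoc_config"`.
#' @export
ewoc_config <- function(variant = c("binary", "po"), theta = 0.33,
                        alpha_feas = 0.25, n_patients = 30L,
                        n_burnin = 4000L, n_keep = 4000L,
                        proposal_scales = NULL) {
  variant <- match.arg(variant)
  stopifnot(theta > 0, theta < 1, n_patients >= 2,
            n_burnin >= 0, n_keep >= 1)
  if (!(alpha_feas > 0 && alpha_feas < 0.5)) {
    stop("need 0 < alpha_feas < 0.5", call. = FALSE)
  }
  npar <- if (variant == "po") 3L else 2L
  if (is.null(proposal_scales)) {
    proposal_scales <- if (variant == "po") c(3.0, 3.0, 3.0) else c(3.0, 3.0)
  }
  if (length(proposal_scales) != npar || any(proposal_scales <= 0)) {
    stop("`proposal_scales` must be ", npar, " positive values",
         call. = FALSE)
  }
  structure(
    list(variant = variant, theta = theta, alpha_feas = alpha_feas,
         n_patients = as.integer(n_patients),
         n_burnin = as.integer(n_burnin), n_keep = as.integer(n_keep),
         proposal_scales = proposal_scales),
    class = "ewoc_config"
  )
}

#' @export
print.ewoc_config <- function(x, ...) {
  cat(sprintf(
    "<ewoc_config> %s: theta=%g alpha=%g n=%d, MH %d+%d\n",
    ewoc_label(x), x$theta, x$alpha_feas, x$n_patients,
    x$n_burnin, x$n_keep))
  invisible(x)
}

#' Design label ("EWOC" or "EWOC-PO")
#' @param config an [ewoc_config()].
#' @return character scalar.
#' @export
ewoc_label <- function(config) {
  if (config$variant == "po") "EWOC-PO" else "EWOC"
}

#' EWOC working-model log-likelihood
#'
#' Log-likelihood of a trial history under the logistic working model in
#' the (rho0, rho1, gamma) parameterization.  The binary variant collapses
#' grade 2 outcomes to the safe class and uses the DLT indicator with
#' p(x) = plogis(logit(rho0) + x (logit(theta) - logit(rho0)) / gamma);
#' the proportional-odds variant uses the trinomial cell probabilities
#' from both curves with shared slope.
#'
#' Parameter values that give a cell probability of zero for an observed
#' outcome return `-Inf` (so an MH sampler simply rejects them).
#'
#' @param variant `"binary"` or `"po"`.
#' @param rho0,rho1,gamma parameter values (vectors recycle together);
#'   `rho1` is ignored for the binary variant.
#' @param doses,y trial history: doses in \[0, 1\] and trinary outcomes.
#' @param theta target DLT probability.
#' @return numeric vector of log-likelihood values.
#' @export
ewoc_log_likelihood <- function(variant, rho0, rho1 = NULL, gamma,
                                doses, y, theta = 0.33) {
  variant <- match.arg(variant, c("binary", "po"))
  stopifnot(length(doses) == length(y))
  if (length(doses) == 0L) {
    return(rep(0, max(length(rho0), length(gamma))))
  }
  k <- max(length(rho0), length(gamma),
           if (variant == "po") length(rho1) else 0L)
  rho0 <- rep_len(rho0, k)
  gamma <- rep_len(gamma, k)
  b <- (stats::qlogis(theta) - stats::qlogis(rho0)) / gamma
  ll <- numeric(k)
  if (variant == "binary") {
    d <- as.integer(y == 2L)
    for (i in seq_along(doses)) {
      p <- stats::plogis(stats::qlogis(rho0) + b * doses[i])
      ll <- ll + ifelse(d[i] == 1L, log(p), log1p(-p))
    }
  } else {
    if (is.null(rho1)) stop("`rho1` required for the po variant", call. = FALSE)
    rho1 <- rep_len(rho1, k)
    a1 <- stats::qlogis(rho1)
    for (i in seq_along(doses)) {
      F2 <- stats::plogis(stats::qlogis(rho0) + b * doses[i])
      F1 <- stats::plogis(a1 + b * doses[i])
      p <- switch(as.character(y[i]),
                  "2" = F2, "1" = F1 - F2, "0" = 1 - F1,
                  stop("outcomes must be 0, 1 or 2", call. = FALSE))
      ll <- ll + ifelse(p > 0, log(p), -Inf)
    }
  }
  ll[!is.finite(ll)] <- -Inf
  ll
}

#' Sample the EWOC posterior by Metropolis-Hastings
#'
#' One-chain componentwise Gaussian random walk on logit-transformed
#' parameters mapped to the prior supports (gamma ~ U\[0,1\],
#' rho0 ~ U\[0,theta\], rho1 | rho0 ~ U\[rho0,1\]), targeting
#' prior x likelihood.  Draws use R's RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' A crude Geweke-style diagnostic (split-chain mean comparison on gamma)
#' and the acceptance rate are recorded; values outside the 20-50 percent
#' acceptance band or |z| > 4 yield a warning only.
#'
#' @param config an [ewoc_config()].
#' @param doses,y trial history (trinary outcomes; the binary variant
#'   collapses grade 2 internally).
#' @param diagnostics warn on tuning/convergence diagnostics (default TRUE).
#' @return an object of class `"posterior_draws"`: list with `draws`
#'   (matrix with columns `rho0`\[, `rho1`\], `gamma`), `acceptance_rate`,
#'   `geweke_z`, `variant`.
#' @export
mh_sample <- function(config, doses, y, diagnostics = TRUE) {
  stopifnot(inherits(config, "ewoc_config"), length(doses) == length(y))
  .check_dose(doses)
  po <- config$variant == "po"
  y <- as.integer(y)
  if (!po) y <- ifelse(y == 2L, 2L, 0L)
  fit <- .ewoc_mh_cpp(as.numeric(doses), y, po, config$theta,
                      config$n_burnin, config$n_keep,
                      as.numeric(config$proposal_scales))
  draws <- fit$draws
  colnames(draws) <- if (po) c("rho0", "rho1", "gamma") else c("rho0", "gamma")
  g <- draws[, "gamma"]
  n <- length(g)
  i1 <- seq_len(max(1L, floor(0.1 * n)))
  i2 <- seq.int(floor(0.5 * n) + 1L, n)
  z <- (mean(g[i1]) - mean(g[i2])) /
    sqrt(stats::var(g[i1]) / length(i1) + stats::var(g[i2]) / length(i2) + 1e-12)
  if (isTRUE(diagnostics)) {
    if (fit$acceptance_rate < 0.05 || fit$acceptance_rate > 0.95) {
      warning(sprintf("MH acceptance rate %.2f outside [0.05, 0.95]",
                      fit$acceptance_rate), call. = FALSE)
    }
    if (is.finite(z) && abs(z) > 4) {
      warning(sprintf("Geweke-style split-chain z = %.2f on gamma", z),
              call. = FALSE)
    }
  }
  structure(
    list(draws = draws, acceptance_rate = fit$acceptance_rate,
         geweke_z = z, variant = config$variant),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s, %d draws, acceptance %.2f\n",
              x$variant, nrow(x$draws), x$acceptance_rate))
  invisible(x)
}

#' Overdose-controlled dose selection
#'
#' Returns the empirical `alpha_feas`-quantile of the posterior draws of
#' the MTD, using the inverse of the right-continuous empirical c.d.f.
#' (the lowest draw q with Fhat(q) >= alpha; quantile type 1).  By
#' construction the posterior mass above the selected dose is about
#' 1 - alpha.
#'
#' @param draws a [mh_sample()] result (or any list with a `draws` matrix
#'   containing a `gamma` column).
#' @param alpha_feas feasibility bound.
#' @return a dose in \[0, 1\].
#' @export
next_dose <- function(draws, alpha_feas = 0.25) {
  g <- draws$draws[, "gamma"]
  if (length(g) == 0L) stop("empty posterior draws", call. = FALSE)
  g <- sort(g)
  q <- g[max(1L, ceiling(alpha_feas * length(g)))]
  min(max(q, 0), 1)
}

#' Run one EWOC trial
#'
#' The first patient receives dose 0 with a forced safe response (Y = 0,
#' included in the likelihood).  Each subsequent patient is dosed at the
#' feasibility-bound quantile of the refitted posterior; after the fixed
#' number of patients the MTD estimate is the same quantile of the
#' end-of-trial posterior.
#'
#' @param config an [ewoc_config()].
#' @param sampler outcome sampler `function(dose) -> {0,1,2}`, e.g. from
#'   [outcome_sampler()].  Responses are generated trinary regardless of
#'   variant; the binary variant collapses grade 2 in its likelihood only.
#' @param diagnostics passed to [mh_sample()].
#' @return an object of class `"ewoc_result"`: list with `estimate`
#'   (end-of-trial MTD estimate), `history` (data.frame `patient`, `dose`,
#'   `y`), `n_enrolled`, `n_dlt`, `acceptance_rates`, `config`.
#' @export
run_ewoc_trial <- function(config, sampler, diagnostics = FALSE) {
  stopifnot(inherits(config, "ewoc_config"), is.function(sampler))
  n <- config$n_patients
  doses <- numeric(n)
  ys <- integer(n)
  acc <- numeric(n)
  doses[1L] <- 0
  ys[1L] <- 0L                                   # forced safe response
  for (k in 2:n) {
    fit <- mh_sample(config, doses[seq_len(k - 1L)], ys[seq_len(k - 1L)],
                     diagnostics = diagnostics)
    acc[k - 1L] <- fit$acceptance_rate
    x <- next_dose(fit, config$alpha_feas)
    yk <- tryCatch(sampler(x), error = function(e) {
      stop(sprintf("outcome sampler failed for patient %d at dose %.6g: %s",
                   k, x, conditionMessage(e)), call. = FALSE)
    })
    doses[k] <- x
    ys[k] <- as.integer(yk)
  }
  fit <- mh_sample(config, doses, ys, diagnostics = diagnostics)
  acc[n] <- fit$acceptance_rate
  structure(
    list(estimate = next_dose(fit, config$alpha_feas),
         history = data.frame(patient = seq_len(n), dose = doses, y = ys),
         n_enrolled = n, n_dlt = sum(ys == 2L),
         acceptance_rates = acc, config = config),
    class = "ewoc_result"
  )
}
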