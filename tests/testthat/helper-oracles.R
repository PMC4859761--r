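# Independent oracles used across the test files.

# --- deterministic grid quadrature for the EWOC posterior -------------------
# The likelihood is written out here from first principles (logistic working
# model in the (rho0[, rho1], gamma) parameterization) and must stay
# independent of dosefindsim::ewoc_log_likelihood / the C++ sampler.

quad_binary_posterior <- function(doses, y, theta = 0.33,
                                  n_r0 = 400L, n_g = 400L) {
  r0 <- (seq_len(n_r0) - 0.5) / n_r0 * theta   # midpoints of Unif[0, theta]
  g  <- (seq_len(n_g) - 0.5) / n_g             # midpoints of Unif[0, 1]
  d <- as.integer(y == 2L)
  loglik <- matrix(0, n_r0, n_g)
  l0 <- log(r0 / (1 - r0))
  lt <- log(theta / (1 - theta))
  for (i in seq_along(doses)) {
    # linear predictor: l0 + x * (lt - l0) / g, over the (r0, g) grid
    for (jg in seq_len(n_g)) {
      p <- 1 / (1 + exp(-(l0 + doses[i] * (lt - l0) / g[jg])))
      loglik[, jg] <- loglik[, jg] +
        if (d[i] == 1L) log(p) else log1p(-p)
    }
  }
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  gamma_marg <- colSums(post)
  list(gamma = g, marg = gamma_marg,
       mean = sum(g * gamma_marg),
       quantile = function(a) g[which(cumsum(gamma_marg) >= a)[1L]])
}

quad_po_posterior <- function(doses, y, theta = 0.33,
                              n_r0 = 120L, n_r1 = 120L, n_g = 160L) {
  r0 <- (seq_len(n_r0) - 0.5) / n_r0 * theta
  g  <- (seq_len(n_g) - 0.5) / n_g
  l0 <- log(r0 / (1 - r0))
  lt <- log(theta / (1 - theta))
  gamma_marg <- numeric(n_g)
  for (jg in seq_len(n_g)) {
    b <- (lt - l0) / g[jg]                      # length n_r0
    acc <- matrix(0, n_r0, n_r1)                # log posterior over (r0, r1)
    # r1 | r0 ~ Unif[r0, 1]: midpoint grid on [r0, 1], density 1/(1 - r0);
    # the 1/(1-r0) prior factor cancels against the cell width (1-r0)/n_r1,
    # so equal weights per (r0, r1) node are exact for the mixture.
    u <- (seq_len(n_r1) - 0.5) / n_r1
    r1 <- outer(r0, u, function(a, s) a + (1 - a) * s)
    a1 <- log(r1 / (1 - r1))
    for (i in seq_along(doses)) {
      F2 <- 1 / (1 + exp(-(l0 + b * doses[i])))
      F1 <- 1 / (1 + exp(-(a1 + b * doses[i])))
      p <- switch(as.character(y[i]),
                  "2" = matrix(F2, n_r0, n_r1),
                  "1" = F1 - matrix(F2, n_r0, n_r1),
                  "0" = 1 - F1)
      p[p <= 0] <- NA_real_
      acc <- acc + log(p)
    }
    acc[is.na(acc)] <- -Inf
    gamma_marg[jg] <- sum(exp(acc - 0))         # unnormalized
  }
  gamma_marg <- gamma_marg / sum(gamma_marg)
  list(gamma = g, marg = gamma_marg,
       mean = sum(g * gamma_marg),
       quantile = function(a) g[which(cumsum(gamma_marg) >= a)[1L]])
}

# --- exact path enumeration of the AT state machine -------------------------
# Walks every reachable outcome sequence (outcomes restricted to {0, 2},
# i.e. Bernoulli DLTs) and accumulates exact terminal-status probabilities.

enumerate_at_paths <- function(config, p_dlt, max_depth = 40L) {
  status_prob <- c(mtd_declared = 0, mtd_above_range = 0,
                   mtd_below_range = 0, cap_reached = 0)
  max_dlt_among6 <- 0L
  n_paths <- 0L

  run_prefix <- function(prefix) {
    used <- 0L
    dose_seq <- numeric(length(prefix))
    sampler <- function(dose) {
      used <<- used + 1L
      if (used > length(prefix)) stop("NEED_MORE_OUTCOMES")
      dose_seq[used] <<- dose
      prefix[used]
    }
    res <- tryCatch(run_at_trial(config, sampler), error = function(e) {
      if (grepl("NEED_MORE_OUTCOMES", conditionMessage(e))) NULL else stop(e)
    })
    list(result = res, used = used, dose_seq = dose_seq)
  }

  recurse <- function(prefix) {
    if (length(prefix) > max_depth) {
      stop("enumeration deeper than max_depth; choose a smaller grid")
    }
    out <- run_prefix(prefix)
    if (is.null(out$result)) {
      recurse(c(prefix, 0L))
      recurse(c(prefix, 2L))
      return(invisible(NULL))
    }
    prob <- 1
    for (i in seq_len(out$used)) {
      pd <- p_dlt(out$dose_seq[i])
      prob <- prob * if (prefix[i] == 2L) pd else (1 - pd)
    }
    status_prob[[out$result$status]] <<-
      status_prob[[out$result$status]] + prob
    n_paths <<- n_paths + 1L
    # tally DLTs per level for the 5-or-6-of-6 impossibility check
    h <- out$result$history
    for (d in unique(h$dose)) {
      at <- abs(h$dose - d) <= 1e-9 * d
      if (sum(at) >= 6L) {
        max_dlt_among6 <<- max(max_dlt_among6, sum(h$y[at] == 2L))
      }
    }
    invisible(NULL)
  }

  recurse(integer(0))
  list(status_prob = status_prob, n_paths = n_paths,
       max_dlt_among6 = max_dlt_among6)
}

# scripted outcome sampler: pops outcomes from a vector, then returns `fill`
scripted_sampler <- function(outcomes, fill = 0L) {
  i <- 0L
  function(dose) {
    i <<- i + 1L
    if (i <= length(outcomes)) outcomes[i] else fill
  }
}

# the six AT versions of the study
at_study_designs <- function() {
  specs <- list(c(0.01, 2, 1.5), c(0.1, 2, 1.5), c(0.01, 1.69, 1.3),
                c(0.1, 1.69, 1.3), c(0.01, 1.96, 1.4), c(0.1, 1.96, 1.4))
  designs <- list()
  for (v in specs) {
    d <- at_config(v[1L], v[2L], v[3L])
    designs[[at_label(d)]] <- d
  }
  designs
}
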