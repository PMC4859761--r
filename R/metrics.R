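#' Bias and root mean square error of the MTD estimate
#'
#' `compute_bias()` is the mean of (estimate - gamma_true) over trials;
#' `compute_rmse()` is the square root of the mean squared error.
#'
#' @param estimates numeric vector of end-of-trial MTD estimates.
#' @param gamma_true true MTD.
#' @return numeric scalar (signed dose units for bias, dose units for rmse).
#' @export
compute_bias <- function(estimates, gamma_true) {
  if (length(estimates) == 0L) stop("empty estimate list", call. = FALSE)
  mean(estimates - gamma_true)
}

#' @rdname compute_bias
#' @export
compute_rmse <- function(estimates, gamma_true) {
  if (length(estimates) == 0L) stop("empty estimate list", call. = FALSE)
  sqrt(mean((estimates - gamma_true)^2))
}

#' Nearest-rank empirical quantile
#'
#' Quantile convention used for integer patient counts: the ceiling(p n)-th
#' order statistic (quantile type 1).
#'
#' @param x numeric vector.
#' @param p probabilities in (0, 1\].
#' @return numeric vector of quantiles.
#' @export
nearest_rank_quantile <- function(x, p) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  s <- sort(x)
  s[pmax(1L, ceiling(p * length(s)))]
}

#' Trial-size percentiles of a cell
#'
#' @param n_enrolled integer vector of per-trial enrollments.
#' @param probs percentiles (default 5th, 50th, 95th).
#' @return named numeric vector.
#' @export
size_percentiles <- function(n_enrolled, probs = c(0.05, 0.5, 0.95)) {
  q <- nearest_rank_quantile(n_enrolled, probs)
  names(q) <- sprintf("q%02d", round(100 * probs))
  q
}

#' Operating characteristics of one simulation cell
#'
#' Computes, over the trials of one (design, scenario) cell: bias and root
#' MSE of the MTD estimate; the average per-trial DLT proportion; the
#' proportion of trials whose DLT rate strictly exceeds theta + 0.05; the
#' proportion of trials with estimated MTD inside the optimal range
#' \[0.85 gamma, 1.15 gamma\] (endpoints inclusive); the proportion of
#' patients dosed inside that range, both trial-averaged (each trial
#' weighted equally) and patient-pooled; and the nearest-rank 5th/50th/95th
#' percentiles of enrollment.
#'
#' Failed or zero-patient trials are excluded with a warning.
#'
#' @param cell data.frame of trial rows from [run_study()] (a single cell).
#' @param gamma_true true MTD of the cell's scenario (defaults to the value
#'   recorded in the rows).
#' @param theta target DLT probability (defaults to the recorded value).
#' @return a one-row data.frame of class `"operating_characteristics"`.
#' @export
compute_safety_and_optimality <- function(cell,
                                          gamma_true = cell$gamma_true[1L],
                                          theta = cell$theta[1L]) {
  stopifnot(is.data.frame(cell), nrow(cell) >= 1L)
  bad <- is.na(cell$n_enrolled) | cell$n_enrolled == 0L
  if (any(bad)) {
    warning(sprintf("excluding %d failed/empty trial(s) from metrics",
                    sum(bad)), call. = FALSE)
    cell <- cell[!bad, , drop = FALSE]
  }
  if (nrow(cell) == 0L) stop("no usable trials in cell", call. = FALSE)
  dlt_rate <- cell$n_dlt / cell$n_enrolled
  lo <- 0.85 * gamma_true
  hi <- 1.15 * gamma_true
  q <- size_percentiles(cell$n_enrolled)
  out <- data.frame(
    n_trials = nrow(cell),
    bias = compute_bias(cell$estimate, gamma_true),
    rmse = compute_rmse(cell$estimate, gamma_true),
    avg_dlt_prop = mean(dlt_rate),
    prop_excess_dlt = mean(dlt_rate > theta + 0.05),
    prop_mtd_optimal = mean(cell$estimate >= lo & cell$estimate <= hi),
    prop_patients_optimal = mean(cell$n_opt_patients / cell$n_enrolled),
    prop_patients_optimal_pooled =
      sum(cell$n_opt_patients) / sum(cell$n_enrolled),
    size_q05 = q[["q05"]], size_q50 = q[["q50"]], size_q95 = q[["q95"]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("operating_characteristics", class(out))
  out
}

#' Per-cell operating characteristics of a whole study
#'
#' Splits the trial rows by (design, scenario) and applies
#' [compute_safety_and_optimality()] to each cell.
#'
#' @param rows data.frame from [run_study()] (or read back from its CSV).
#' @return a data.frame with one row per cell, carrying the cell
#'   identifiers and all operating characteristics.
#' @export
summarize_study <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  needed <- c("design", "scenario", "gamma_true", "theta", "estimate",
              "n_enrolled", "n_dlt", "n_opt_patients")
  missing <- setdiff(needed, names(rows))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(rows$design, rows$scenario, drop = TRUE)
  cells <- split(rows, key)
  out <- do.call(rbind, lapply(cells, function(cell) {
    oc <- compute_safety_and_optimality(cell)
    cbind(data.frame(design = cell$design[1L],
                     design_type = if ("design_type" %in% names(cell))
                       cell$design_type[1L] else NA_character_,
                     scenario = cell$scenario[1L],
                     model = if ("model" %in% names(cell))
                       cell$model[1L] else NA_character_,
                     gamma_true = cell$gamma_true[1L],
                     rho1_true = if ("rho1_true" %in% names(cell))
                       cell$rho1_true[1L] else NA_real_,
                     stringsAsFactors = FALSE),
          oc)
  }))
  rownames(out) <- NULL
  out
}
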