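#' Accelerated titration design configuration
#'
#' An AT design is identified by (starting dose, accelerated-phase increase
#' rate, MF-UD-phase increase rate) on the continuous standardized dose
#' scale.  Escalations multiply the current dose by the phase's rate;
#' MF-UD de-escalations divide by the MF-UD rate.
#'
#' @param start_dose first dose, in (0, max_dose].
#' @param acc_rate multiplicative increment in the accelerated phase (> mfud_rate).
#' @param mfud_rate multiplicative increment/decrement in the 3+3 (MF-UD)
#'   phase (> 1).
#' @param max_dose highest allowed dose (default 1, the top of the
#'   standardized scale).
#' @param max_patients enrollment cap (default 62).
#' @return an object of class `"at_config"`.
#' @export
at_config <- function(start_dose, acc_rate, mfud_rate,
                      max_dose = 1.0, max_patients = 62L) {
  stopifnot(is.numeric(start_dose), is.numeric(acc_rate),
            is.numeric(mfud_rate), is.numeric(max_dose))
  if (!(acc_rate > mfud_rate && mfud_rate > 1)) {
    stop("need acc_rate > mfud_rate > 1", call. = FALSE)
  }
  if (!(start_dose > 0 && start_dose <= max_dose)) {
    stop("need 0 < start_dose <= max_dose", call. = FALSE)
  }
  if (max_patients < 1) stop("max_patients must be >= 1", call. = FALSE)
  structure(
    list(start_dose = start_dose, acc_rate = acc_rate,
         mfud_rate = mfud_rate, max_dose = max_dose,
         max_patients = as.integer(max_patients)),
    class = "at_config"
  )
}

#' @export
print.at_config <- function(x, ...) {
  cat(sprintf("<at_config> (%g, %g, %g), max dose %g, cap %d patients\n",
              x$start_dose, x$acc_rate, x$mfud_rate, x$max_dose,
              x$max_patients))
  invisible(x)
}

#' Design label of the form "AT(start, acc, mfud)"
#' @param config an [at_config()].
#' @return character scalar.
#' @export
at_label <- function(config) {
  sprintf("AT(%g,%g,%g)", config$start_dose, config$acc_rate,
          config$mfud_rate)
}

# relative tolerance used to identify dose levels on the multiplicative grid
.level_tol <- 1e-9

.same_level <- function(a, b) {
  abs(a - b) <= .level_tol * pmax(abs(a), abs(b))
}

#' Run one accelerated titration trial
#'
#' Executes the two-phase algorithm.  Phase 1 (accelerated) treats one
#' patient per level, escalating by `acc_rate` after a safe outcome
#' (Y = 0); the first grade >= 2 toxicity (Y >= 1) ends the phase.  Phase 2
#' is the classical 3+3 MF-UD cohort design on the multiplicative grid with
#' rate `mfud_rate`; the accelerated-phase patient whose toxicity ended
#' phase 1 counts toward the first cohort at that level.  In the MF-UD
#' phase only DLTs (Y = 2) count as toxicities.
#'
#' The first patient is treated at the starting dose and is given a forced
#' safe response (Y = 0).  A proposed escalation above `max_dose` ends the
#' trial with the MTD declared above the dose range; a trial whose lowest
#' visited dose is declared exceeded ends with the MTD below the range.
#' Trials are capped at `max_patients` enrolled.
#'
#' @param config an [at_config()].
#' @param sampler a function `function(dose) -> integer in {0, 1, 2}`
#'   drawing one patient outcome, e.g. from [outcome_sampler()].
#' @return an object of class `"at_result"`: a list with `status` (one of
#'   `"mtd_declared"`, `"mtd_above_range"`, `"mtd_below_range"`,
#'   `"cap_reached"`), `declared_mtd` (dose, or `NA` unless declared),
#'   `last_dose` (current level at termination), `history` (data.frame with
#'   `patient`, `dose`, `y`, `phase`), `n_enrolled`, `n_dlt`.
#' @export
run_at_trial <- function(config, sampler) {
  stopifnot(inherits(config, "at_config"), is.function(sampler))
  doses  <- numeric(0)
  ys     <- integer(0)
  phases <- character(0)
  exceeded <- numeric(0)   # levels declared "MTD exceeded"

  enrol <- function(dose, phase, forced = FALSE) {
    if (!is.finite(dose) || dose <= 0) {
      stop("internal consistency: non-finite or non-positive dose",
           call. = FALSE)
    }
    y <- if (forced) 0L else {
      yy <- tryCatch(sampler(dose), error = function(e) {
        stop(sprintf("outcome sampler failed for patient %d at dose %.6g: %s",
                     length(doses) + 1L, dose, conditionMessage(e)),
             call. = FALSE)
      })
      as.integer(yy)
    }
    doses  <<- c(doses, dose)
    ys     <<- c(ys, y)
    phases <<- c(phases, phase)
    y
  }
  n_at <- function(level) sum(.same_level(doses, level))
  dlt_at <- function(level) sum(ys == 2L & .same_level(doses, level))
  finish <- function(status, declared = NA_real_, last = NA_real_) {
    structure(
      list(status = status, declared_mtd = declared, last_dose = last,
           history = data.frame(patient = seq_along(doses), dose = doses,
                                y = ys, phase = phases,
                                stringsAsFactors = FALSE),
           n_enrolled = length(doses), n_dlt = sum(ys == 2L)),
      class = "at_result")
  }

  cur <- config$start_dose

  ## accelerated phase: patient 1 forced safe, then one patient per level
  y <- enrol(cur, "accelerated", forced = TRUE)
  repeat {
    if (y >= 1L) break                                     # step 3a -> MF-UD
    nxt <- cur * config$acc_rate                           # step 4
    if (nxt > config$max_dose * (1 + .level_tol)) {
      return(finish("mtd_above_range", last = cur))        # step 4a
    }
    cur <- nxt
    if (length(doses) >= config$max_patients) {
      return(finish("cap_reached", last = cur))
    }
    y <- enrol(cur, "accelerated")                         # steps 2-3
  }

  ## MF-UD phase, steps 5-10
  step <- 5L
  repeat {
    if (step == 5L) {
      cnt <- n_at(cur)
      # first visit fills the cohort to 3 (counting any accelerated-phase
      # patient at this level); a revisit accrues a fresh cohort of 3
      target <- if (cnt < 3L) 3L else cnt + 3L
      while (n_at(cur) < target) {
        if (length(doses) >= config$max_patients) {
          return(finish("cap_reached", last = cur))        # step 5a
        }
        enrol(cur, "mfud")
      }
      step <- 6L
    } else if (step == 6L) {
      step <- if (n_at(cur) == 3L) 7L else 8L
    } else if (step == 7L) {
      d <- dlt_at(cur)
      if (d == 0L) {
        step <- 10L                                        # 7a
      } else if (d == 1L) {
        step <- 5L                                         # 7b: stay, +3
      } else {
        exceeded <- c(exceeded, cur)                       # 7c
        step <- 9L
      }
    } else if (step == 8L) {
      d <- dlt_at(cur)
      if (d == 0L) {
        return(finish("mtd_declared", declared = cur, last = cur))   # 8a
      } else if (d == 1L) {
        nxt <- cur * config$mfud_rate
        if (any(.same_level(exceeded, nxt))) {
          # 8b: the MTD has been exceeded above -> current dose is the MTD
          return(finish("mtd_declared", declared = cur, last = cur))
        }
        step <- 10L                                        # 8b: escalate
      } else if (d == 2L) {
        return(finish("mtd_declared", declared = cur, last = cur))   # 8c
      } else {
        exceeded <- c(exceeded, cur)                       # 8d
        step <- 9L
      }
    } else if (step == 9L) {
      lowest <- min(doses)
      if (.same_level(cur, lowest) || cur < lowest) {
        return(finish("mtd_below_range", last = cur))      # 9a
      }
      lower <- cur / config$mfud_rate
      if (n_at(lower) > 3L) {
        return(finish("mtd_declared", declared = lower, last = lower))  # 9b
      }
      cur <- lower
      step <- 5L
    } else { # step == 10L
      nxt <- cur * config$mfud_rate
      if (nxt > config$max_dose * (1 + .level_tol)) {
        return(finish("mtd_above_range", last = cur))      # 10a
      }
      if (any(.same_level(exceeded, nxt))) {
        # escalation into a level already declared exceeded: the current
        # dose is the best supported MTD (same resolution as step 8b)
        return(finish("mtd_declared", declared = cur, last = cur))
      }
      cur <- nxt
      step <- 5L
    }
  }
}

#' Numeric MTD estimate from an AT trial
#'
#' Bias and MSE summaries average the end-of-trial estimate over all
#' trials, so boundary declarations are imputed to a number: the declared
#' MTD when one exists; `max_dose` when the MTD was declared above the
#' range; the lowest visited dose divided by `mfud_rate` (floored at 0)
#' when declared below the range; and the current dose level when the
#' enrollment cap stopped the trial.
#'
#' @param result an [run_at_trial()] result.
#' @param config the [at_config()] used.
#' @return a dose (numeric scalar).
#' @export
at_declared_estimate <- function(result, config) {
  stopifnot(inherits(result, "at_result"), inherits(config, "at_config"))
  switch(result$status,
    mtd_declared    = result$declared_mtd,
    mtd_above_range = config$max_dose,
    mtd_below_range = max(0, min(result$history$dose) / config$mfud_rate),
    cap_reached     = result$last_dose,
    stop("unknown AT status: ", result$status, call. = FALSE))
}
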