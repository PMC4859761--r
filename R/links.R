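#' Link functions for dose-toxicity curves
#'
#' `link_eval()` evaluates a cumulative link function F(w) and
#' `link_inverse()` its inverse.  Two links are supported: the standard
#' logistic, F(w) = 1 / (1 + exp(-w)), and a scaled-normal link with shape
#' parameter `sigma`, F(w) = pnorm(w / sigma).
#'
#' @param link_id one of `"logistic"` or `"normal_scaled"`.
#' @param w numeric vector of link-scale values.
#' @param p numeric vector of probabilities in (0, 1).
#' @param sigma shape parameter of the scaled-normal link (> 0); ignored for
#'   the logistic link.
#' @return `link_eval()` returns probabilities in (0, 1); `link_inverse()`
#'   returns link-scale values.
#' @examples
#' link_eval("logistic", 0)            # 0.5
#' link_eval("normal_scaled", 0, 2)    # 0.5
#' link_inverse("logistic", 0.33)
#' @export
link_eval <- function(link_id, w, sigma = 1) {
  switch(link_id,
    logistic = stats::plogis(w),
    normal_scaled = {
      if (!is.numeric(sigma) || sigma <= 0) {
        stop("`sigma` must be > 0 for the normal_scaled link", call. = FALSE)
      }
      stats::pnorm(w / sigma)
    },
    stop("unknown link_id: ", link_id, call. = FALSE)
  )
}

#' @rdname link_eval
#' @export
link_inverse <- function(link_id, p, sigma = 1) {
  switch(link_id,
    logistic = stats::qlogis(p),
    normal_scaled = {
      if (!is.numeric(sigma) || sigma <= 0) {
        stop("`sigma` must be > 0 for the normal_scaled link", call. = FALSE)
      }
      sigma * stats::qnorm(p)
    },
    stop("unknown link_id: ", link_id, call. = FALSE)
  )
}
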