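#' Regression slope between stimuli and reproductions
#'
#' Ordinary least squares of single-trial reproductions on stimuli. A slope of
#' 1 means veridical reproduction; slopes below 1 quantify the regression
#' effect (central tendency).
#'
#' @param trials Trial table with columns `stimulus` and `reproduction`.
#' @return List with `slope` and `intercept` (seconds).
#' @export
regression_slope <- function(trials) {
  check_trials(trials)
  if (length(unique(trials$stimulus)) < 2L) {
    stop("at least two distinct stimulus values are required")
  }
  fit <- stats::lm(reproduction ~ stimulus, data = trials)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Coefficient of variation of reproductions
#'
#' Per-stimulus SD of the reproductions divided by the per-stimulus mean,
#' averaged over stimuli with equal weight:
#' \deqn{CV(r) = E_s[ STD_s(r) / E_r[r|s] ]}
#' The SD uses the population convention (denominator n), matching the
#' expectation-operator definition. Stimuli with fewer than two trials are
#' excluded with a warning.
#'
#' @param trials Trial table with columns `stimulus` and `reproduction`.
#' @return CV (dimensionless, >= 0).
#' @export
coefficient_of_variation <- function(trials) {
  check_trials(trials)
  sp <- split(trials$reproduction, trials$stimulus)
  few <- vapply(sp, length, 1L) < 2L
  if (all(few)) stop("no stimulus has at least two trials")
  if (any(few)) {
    warning(sprintf("%d stimulus value(s) with fewer than 2 trials excluded",
                    sum(few)))
    sp <- sp[!few]
  }
  cvs <- vapply(sp, function(r) {
    m <- mean(r)
    if (m == 0) stop("a stimulus has mean reproduction 0; CV undefined")
    sqrt(mean((r - m)^2)) / m
  }, 1.0)
  mean(cvs)
}

#' Reproduction bias
#'
#' Mean over stimuli of (mean reproduction - stimulus):
#' \deqn{BIAS(r) = E_s[ E_r[r|s] - s ]}
#'
#' @param trials Trial table with columns `stimulus` and `reproduction`.
#' @return Bias in seconds (positive = overestimation).
#' @export
bias <- function(trials) {
  check_trials(trials)
  sp <- split(trials$reproduction, trials$stimulus)
  s_vals <- as.numeric(names(sp))
  mean(vapply(sp, mean, 1.0) - s_vals)
}

#' Per-session behavioral summary
#'
#' @param trials Trial table; columns `stimulus`, `reproduction`, and
#'   optionally `k` and `reward`.
#' @return One-row data.frame with slope, intercept, cv, bias, mean tolerance
#'   and reward rate (the latter two NA when absent).
#' @export
behavior_summary <- function(trials) {
  sl <- regression_slope(trials)
  data.frame(
    slope = sl$slope,
    intercept = sl$intercept,
    cv = coefficient_of_variation(trials),
    bias = bias(trials),
    mean_k = if ("k" %in% names(trials)) mean(trials$k) else NA_real_,
    reward_rate = if ("reward" %in% names(trials)) mean(trials$reward) else NA_real_
  )
}

check_trials <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("stimulus", "reproduction") %in% names(trials))) {
    stop("trials must be a data.frame with columns stimulus and reproduction")
  }
  invisible(trials)
}

#' Read / write trial tables
#'
#' Plain-CSV interchange for behavioral trials (columns trial, stimulus_s,
#' reproduction_s, k, reward, gain).
#'
#' @param trials Trial table.
#' @param path CSV path.
#' @return `read_trials_csv` returns the trial table with canonical column
#'   names.
#' @export
write_trials_csv <- function(trials, path) {
  out <- data.frame(trial = trials$trial %||% seq_len(nrow(trials)),
                    stimulus_s = trials$stimulus,
                    reproduction_s = trials$reproduction,
                    k = trials$k %||% NA,
                    reward = trials$reward %||% NA,
                    gain = trials$gain %||% NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  x <- utils::read.csv(path)
  data.frame(trial = x$trial, stimulus = x$stimulus_s,
             reproduction = x$reproduction_s, k = x$k,
             reward = as.logical(x$reward), gain = x$gain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
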