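# Stagewise circuit representation accuracy: percent variance accounted
# for (R^2) of a univariate linear mapping between consecutive circuit
# signals, with a bounded best-lag search so conduction/integration delays
# are reported separately rather than conflated with attenuation.
# Independent stages compound multiplicatively.

#' Percent variance accounted for between two signals
#'
#' Regresses `reference` on `signal` (free gain and offset) at each
#' candidate lag in `[0, max_lag]` (signal delayed relative to reference)
#' and keeps the lag maximizing R^2. `r2_percent = 100 (1 - SS_res/SS_tot)`,
#' which for univariate regression equals 100 r^2; it is invariant to
#' affine transforms of either series.
#'
#' @param signal,reference Equal-length numeric series on a shared uniform
#'   clock.
#' @param max_lag Maximum lag searched (s); 0 disables the search.
#' @param sample_rate Samples per second (needed when `max_lag > 0`).
#' @param epoch Optional `c(start, end)` (s) restricting the comparison;
#'   requires `time`.
#' @param time Optional time vector for `epoch`.
#' @param stage_name Label stored in the result.
#' @return List of class `accuracy_result`: `stage_name`, `r2_percent`,
#'   `lag_used` (s), `gain`, `offset`, `n_samples`.
#' @export
vaf <- function(signal, reference, max_lag = 0, sample_rate = NULL,
                epoch = NULL, time = NULL, stage_name = "stage") {
  if (length(signal) != length(reference))
    stop("signal and reference must share a clock (equal length)",
         call. = FALSE)
  if (!is.null(epoch)) {
    stopifnot(!is.null(time))
    keep <- time >= epoch[1] & time <= epoch[2]
    signal <- signal[keep]; reference <- reference[keep]
  }
  if (stats::sd(reference) == 0)
    stop("constant reference: R^2 undefined", call. = FALSE)
  lags <- 0L
  if (max_lag > 0) {
    if (is.null(sample_rate))
      stop("`sample_rate` needed for a lag search", call. = FALSE)
    lags <- 0:round(max_lag * sample_rate)
  }
  best <- list(r2 = -Inf)
  n_all <- length(signal)
  for (L in lags) {
    # positive lag: signal delayed by L relative to the reference
    s <- signal[(1 + L):n_all]
    r <- reference[seq_len(n_all - L)]
    if (stats::sd(s) == 0) { r2 <- 0; b <- 0 } else {
      b <- stats::cov(s, r) / stats::var(s)
      r2 <- stats::cor(s, r)^2
    }
    if (r2 > best$r2)
      best <- list(r2 = r2, lag = L, gain = b,
                   offset = mean(r) - b * mean(s), n = length(s))
  }
  structure(list(stage_name = stage_name,
                 r2_percent = 100 * best$r2,
                 lag_used = best$lag / (if (max_lag > 0) sample_rate else 1),
                 gain = best$gain, offset = best$offset,
                 n_samples = best$n),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<%s: R^2 = %.1f%% (lag %.3f s, n = %d)>\n",
              x$stage_name, x$r2_percent, x$lag_used, x$n_samples))
  invisible(x)
}

#' Compound independent stage accuracies
#'
#' Overall circuit accuracy is the product of the stage fractions:
#' `100 * prod(stages / 100)`. Reported as an integer percent (rounded),
#' with the raw product kept alongside. Commutative and monotone in every
#' stage; never exceeds the weakest stage.
#'
#' @param stages Numeric vector of stage accuracies in percent, each in
#'   [0, 100]. `accuracy_result` objects are also accepted.
#' @return List of class `compound_accuracy`: `stage_accuracies`,
#'   `overall_percent` (raw), `overall_percent_int` (integer report).
#' @export
compound <- function(stages) {
  if (is.list(stages) && !is.null(stages[[1]]$r2_percent))
    stages <- vapply(stages, `[[`, numeric(1), "r2_percent")
  stages <- as.numeric(stages)
  if (!length(stages)) stop("no stages to compound", call. = FALSE)
  if (any(stages < 0 | stages > 100))
    stop("stage accuracies must be percentages in [0, 100]", call. = FALSE)
  raw <- 100 * prod(stages / 100)
  structure(list(stage_accuracies = stages, overall_percent = raw,
                 overall_percent_int = as.integer(round(raw))),
            class = "compound_accuracy")
}

#' @export
print.compound_accuracy <- function(x, ...) {
  cat(sprintf("<compound accuracy: [%s]%% -> %d%%>\n",
              paste(round(x$stage_accuracies, 1), collapse = ", "),
              x$overall_percent_int))
  invisible(x)
}
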