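`%||%` <- function(x, y) if (is.null(x)) y else x

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Duration intervals for a carried-forward clinical finding
#'
#' A charted value is taken to hold from the time it is recorded until the
#' next time the same item is recorded; the final recording contributes no
#' further duration (the chart is silent after it). Given the recording
#' times and an abnormality indicator at each recording, returns the
#' non-overlapping intervals during which the item was abnormal.
#'
#' @param ages numeric, strictly increasing recording times (hours).
#' @param abnormal logical, same length; `NA` counts as not abnormal.
#' @return two-column matrix of interval starts and ends (possibly 0 rows).
#' @keywords internal
#' @noRd
held_abnormal_intervals <- function(ages, abnormal) {
  k <- length(ages)
  if (k < 2L) return(matrix(numeric(0), ncol = 2L))
  abnormal[is.na(abnormal)] <- FALSE
  keep <- abnormal[-k]
  cbind(ages[-k][keep], ages[-1L][keep])
}

# Total abnormal duration over intervals whose start falls at or before
# `window_end`; intervals are allowed to extend beyond the window (a finding
# that begins inside the assessment window and persists past it still
# accrues its full duration).
held_abnormal_duration <- function(ages, abnormal, window_end = Inf) {
  iv <- held_abnormal_intervals(ages, abnormal)
  if (nrow(iv) == 0L) return(0)
  iv <- iv[iv[, 1L] <= window_end, , drop = FALSE]
  sum(iv[, 2L] - iv[, 1L])
}

# First time at which the cumulative duration over sorted, non-overlapping
# intervals reaches `threshold` hours; NA if it never does.
time_cumulative_reaches <- function(intervals, threshold) {
  if (threshold <= 0) {
    return(if (nrow(intervals)) intervals[1L, 1L] else NA_real_)
  }
  cum <- 0
  for (i in seq_len(nrow(intervals))) {
    len <- intervals[i, 2L] - intervals[i, 1L]
    if (cum + len >= threshold) return(intervals[i, 1L] + (threshold - cum))
    cum <- cum + len
  }
  NA_real_
}

# Truncated-normal draw via inverse CDF; used for gestational-age sampling.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n,
                    stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}
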