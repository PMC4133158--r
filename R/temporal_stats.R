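#' Inter-choice intervals of an event log
#'
#' The inter-choice interval (ICI) is the time between two consecutive
#' choices. Each interval carries the light/dark label of its *starting*
#' event, so per-cycle interval distributions can be formed.
#'
#' @param log An [event_log()] with at least 2 events.
#' @return An object of class `ici_series`: a data frame with columns
#'   `tau` (seconds), `cycle` (light/dark of the starting event) and
#'   `start_index` (index of the starting event in the log).
#' @export
interchoice_intervals <- function(log) {
  stopifnot(inherits(log, "event_log"))
  n <- length(log$time)
  if (n < 2L) stop("need at least 2 events to form intervals")
  tau <- diff(log$time)
  cyc <- assign_cycle_labels(log)[-n]
  out <- data.frame(tau = tau, cycle = cyc, start_index = seq_len(n - 1L))
  class(out) <- c("ici_series", "data.frame")
  attr(out, "session_start") <- log$session_start
  out
}

ici_values <- function(x) {
  if (inherits(x, "ici_series")) x$tau else as.numeric(x)
}

#' Burstiness index of an interval series
#'
#' `B = (sigma - m) / (sigma + m)` where `m` and `sigma` are the mean and
#' population standard deviation of the intervals. `B = 1` is maximally
#' bursty, `B = 0` neutral (Poisson-like), `B = -1` perfectly periodic.
#'
#' @param x An `ici_series` or a numeric vector of positive intervals.
#' @return The burstiness index, a number in `[-1, 1]`.
#' @export
#' @examples
#' burstiness(rep(5, 100))             # -1: periodic
#' burstiness(rexp(1e4))               # ~0: Poisson
burstiness <- function(x) {
  tau <- ici_values(x)
  if (length(tau) < 2L) stop("need at least 2 intervals")
  if (any(tau <= 0)) stop("intervals must be positive")
  m <- mean(tau)
  s <- sqrt(mean((tau - m)^2))  # population SD
  (s - m) / (s + m)
}

#' Memory coefficient of an interval series
#'
#' Lag-1 correlation between consecutive intervals:
#' `M = (1/(n-1)) * sum_i (tau_i - m1)(tau_{i+1} - m2) / (s1 * s2)`,
#' where `m1`/`s1` are the mean and population SD over the first `n-1`
#' intervals and `m2`/`s2` over the last `n-1`. `M > 0` means long
#' intervals tend to follow long ones; `M = -1` is perfectly alternating.
#'
#' @param x An `ici_series` or numeric vector of intervals (n >= 3).
#' @return The memory coefficient, a number in `[-1, 1]`.
#' @export
memory_coefficient <- function(x) {
  tau <- ici_values(x)
  n <- length(tau)
  if (n < 3L) stop("need at least 3 intervals")
  a <- tau[-n]
  b <- tau[-1L]
  s1 <- sqrt(mean((a - mean(a))^2))
  s2 <- sqrt(mean((b - mean(b))^2))
  if (s1 == 0 || s2 == 0)
    stop("memory coefficient undefined: zero variance in consecutive pairs")
  mean((a - mean(a)) * (b - mean(b))) / (s1 * s2)
}

shannon_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Choice entropy over successive trial windows
#'
#' Shannon entropy (bits) of the option frequencies inside consecutive
#' non-overlapping windows of trials. Zero bits marks a deterministic
#' (purely exploitative) window; `log2(n_options)` marks uniform
#' exploration. Only complete windows are scored.
#'
#' @param options Choice sequence (character/factor vector), or an
#'   [event_log()].
#' @param window Window width in trials (default 100).
#' @param option_set Option levels to tabulate over; defaults to the
#'   distinct observed values (or the log's declared set).
#' @return An object of class `entropy_trace`: data frame with columns
#'   `window`, `start`, `end`, `entropy`.
#' @export
choice_entropy_trace <- function(options, window = 100, option_set = NULL) {
  if (inherits(options, "event_log")) {
    if (is.null(option_set)) option_set <- options$options
    options <- options$option
  }
  stopifnot(window >= 1)
  options <- as.character(options)
  if (is.null(option_set)) option_set <- unique(options)
  n_win <- length(options) %/% window
  if (n_win == 0L) stop("sequence shorter than one window")
  ent <- numeric(n_win)
  starts <- (seq_len(n_win) - 1L) * window + 1L
  for (w in seq_len(n_win)) {
    seg <- options[starts[w]:(starts[w] + window - 1L)]
    ent[w] <- shannon_entropy(table(factor(seg, levels = option_set)))
  }
  out <- data.frame(window = seq_len(n_win), start = starts,
                    end = starts + window - 1L, entropy = ent)
  class(out) <- c("entropy_trace", "data.frame")
  out
}

#' Compare choice entropy with frequency-preserving shuffles
#'
#' Shuffling the full choice sequence removes all dependence on choice
#' history while preserving option frequencies. Persistent (run-heavy)
#' sequences concentrate options within windows, so their empirical
#' window entropies fall below the shuffled mean.
#'
#' @inheritParams choice_entropy_trace
#' @param n_shuffles Number of uniform permutations (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `empirical` (entropy per window), `shuffled_mean`
#'   (mean shuffled entropy per window), `difference`
#'   (empirical - shuffled per window) and `mean_difference`.
#' @export
entropy_shuffle_comparison <- function(options, window = 100,
                                       n_shuffles = 100, seed = NULL,
                                       option_set = NULL) {
  if (inherits(options, "event_log")) {
    if (is.null(option_set)) option_set <- options$options
    options <- options$option
  }
  stopifnot(n_shuffles >= 100)
  if (!is.null(seed)) set.seed(seed)
  emp <- choice_entropy_trace(options, window, option_set)$entropy
  acc <- numeric(length(emp))
  for (s in seq_len(n_shuffles)) {
    shuf <- sample(options)
    acc <- acc + choice_entropy_trace(shuf, window, option_set)$entropy
  }
  shuffled_mean <- acc / n_shuffles
  list(empirical = emp, shuffled_mean = shuffled_mean,
       difference = emp - shuffled_mean,
       mean_difference = mean(emp - shuffled_mean))
}

#' Autocorrelogram and periodicity of event counts
#'
#' Events are binned into counts per `bin_hours`; the autocorrelation of
#' the mean-subtracted counts (normalized to 1 at lag 0) is scanned for
#' peaks: local maxima with positive autocorrelation separated by at
#' least `min_separation` hours. The period estimate is the mean spacing
#' between successive peaks — for circadian activity, 24 hours.
#'
#' @param log An [event_log()].
#' @param bin_hours Bin width in hours (default 1).
#' @param max_lag_hours Largest lag scanned; defaults to half the record,
#'   capped at 3 days.
#' @param min_separation Minimum spacing between accepted peaks, hours.
#' @param threshold Peak eligibility threshold on the autocorrelation;
#'   defaults to the white-noise 95% band `qnorm(0.975)/sqrt(n_bins)`,
#'   so a homogeneous Poisson record yields no qualifying peaks.
#' @return An object of class `autocorrelogram`: list with `lag_hours`,
#'   `acf`, `peak_lags`, `period_hours` (NA if fewer than 2 peaks, with
#'   `period_defined = FALSE` and a warning), `bin_hours`.
#' @export
autocorrelogram_period <- function(log, bin_hours = 1,
                                   max_lag_hours = NULL,
                                   min_separation = 12,
                                   threshold = NULL) {
  stopifnot(inherits(log, "event_log"))
  dur_h <- log$duration / 3600
  if (is.null(max_lag_hours)) max_lag_hours <- min(78, dur_h / 2)
  if (dur_h < 3 * 24)
    warning("record shorter than 3 periods; period estimate unreliable")
  breaks <- seq(0, ceiling(dur_h / bin_hours) * bin_hours, by = bin_hours)
  counts <- tabulate(findInterval(log$time / 3600, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  lag_max <- floor(max_lag_hours / bin_hours)
  ac <- as.numeric(stats::acf(counts, lag.max = lag_max,
                              plot = FALSE, demean = TRUE)$acf)
  lags <- (0:lag_max) * bin_hours
  if (is.null(threshold))
    threshold <- stats::qnorm(0.975) / sqrt(length(counts))
  # candidate peaks: local maxima above the eligibility threshold,
  # excluding lag 0
  is_peak <- rep(FALSE, length(ac))
  for (i in 2:(length(ac) - 1L)) {
    if (ac[i] > threshold && ac[i] >= ac[i - 1L] && ac[i] >= ac[i + 1L])
      is_peak[i] <- TRUE
  }
  # greedy selection by height under the separation constraint, so the
  # dominant peaks suppress their noise neighbours; lag 0 (trivially the
  # global maximum) takes part in the constraint, which excludes the
  # short-lag correlation shoulder produced by bursts
  cand <- which(is_peak)[order(ac[is_peak], decreasing = TRUE)]
  kept_lags <- 0
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(lags[i] - kept_lags) >= min_separation)) {
      keep <- c(keep, i)
      kept_lags <- c(kept_lags, lags[i])
    }
  }
  peaks <- sort(lags[keep])
  if (length(peaks) >= 2) {
    period <- mean(diff(peaks))
    defined <- TRUE
  } else {
    period <- NA_real_
    defined <- FALSE
    warning("fewer than 2 qualifying autocorrelogram peaks; ",
            "period undefined")
  }
  structure(list(lag_hours = lags, acf = ac, peak_lags = peaks,
                 period_hours = period, period_defined = defined,
                 bin_hours = bin_hours),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat("<autocorrelogram> bin ", x$bin_hours, " h, ",
      length(x$peak_lags), " peaks", sep = "")
  if (x$period_defined)
    cat(", period ", sprintf("%.2f", x$period_hours), " h", sep = "")
  cat("\n")
  invisible(x)
}
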