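#' Extract runs of consecutive identical choices
#'
#' A run is a maximal block of consecutive identical choices. Adjacent
#' runs always differ in option and run lengths sum to the number of
#' trials.
#'
#' @param options Choice sequence (character/factor vector), or an
#'   [event_log()].
#' @return Object of class `run_sequence`: data frame with columns
#'   `option` and `length`, in sequence order.
#' @export
#' @examples
#' extract_runs(c("A", "A", "B", "C", "C", "C"))
extract_runs <- function(options) {
  if (inherits(options, "event_log")) options <- options$option
  options <- as.character(options)
  if (length(options) == 0L) stop("empty choice sequence")
  r <- rle(options)
  out <- data.frame(option = r$values, length = r$lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("run_sequence", "data.frame")
  attr(out, "n_trials") <- length(options)
  out
}

run_lengths_survival <- function(lengths, lmax = max(lengths)) {
  counts <- tabulate(lengths, nbins = lmax)
  rev(cumsum(rev(counts))) / length(lengths)
}

#' Survival and hazard of run lengths
#'
#' The run-length survival function `S(l) = P(L >= l)` and the hazard of
#' ending a run, `h(l) = [S(l) - S(l+1)] / S(l)`: the probability a run
#' stops at length `l` given it reached `l`. For i.i.d. choices the
#' hazard is flat; persistent (preferential-attachment) choice makes it
#' decrease with run length.
#'
#' @param runs A [extract_runs()] result (or vector of run lengths).
#' @param scope `"overall"`, or a rank number to restrict to runs of the
#'   option holding that rank.
#' @param ranks A [assign_ranks()] result; required when `scope` is a
#'   rank.
#' @return Object of class `run_distribution`: data frame with columns
#'   `length`, `survival`, `hazard` (hazard only where survival > 0).
#' @export
#' @examples
#' run_distribution(extract_runs(c("A", "B", "B", "C", "C", "C", "C")))
run_distribution <- function(runs, scope = "overall", ranks = NULL) {
  lengths <- if (inherits(runs, "run_sequence")) runs$length
             else as.numeric(runs)
  if (!identical(scope, "overall")) {
    stopifnot(inherits(runs, "run_sequence"),
              inherits(ranks, "rank_assignment"))
    opt <- ranks$option[ranks$rank == scope]
    lengths <- runs$length[runs$option == opt]
  }
  if (length(lengths) == 0L) stop("no runs in scope")
  lmax <- max(lengths)
  S <- run_lengths_survival(lengths, lmax)
  S_next <- c(S[-1L], 0)
  hazard <- ifelse(S > 0, (S - S_next) / S, NA_real_)
  out <- data.frame(length = seq_len(lmax), survival = S, hazard = hazard)
  class(out) <- c("run_distribution", "data.frame")
  attr(out, "scope") <- scope
  out
}

#' Monte-Carlo shuffle test for run-length persistence
#'
#' Compares the empirical run-length survival with that of uniformly
#' shuffled sequences of the same data (frequency-preserving, history-
#' destroying). The statistic is the largest absolute difference between
#' the empirical survival and the shuffled-ensemble mean survival; each
#' shuffle's statistic against the mean of the remaining ensemble forms
#' the null. The p-value uses the +1 correction, so `p >= 1/(n+1)`.
#'
#' @param options Choice sequence, or an [event_log()].
#' @param n_shuffles Number of shuffles (>= 999; use >= 1999 to resolve
#'   p < 0.001).
#' @param seed Optional integer seed.
#' @param scope `"overall"` or a rank number (see [run_distribution()]).
#' @param statistic `"sup"` (default) for the sup-difference of survival
#'   curves, or `"area"` for the log-log area statistic of
#'   [loglog_area()].
#' @return Object of class `shuffle_test`: list with `observed`, `null`
#'   (length `n_shuffles`), `p_value`, `n_shuffles`, `seed`, `scope`.
#' @export
shuffle_run_test <- function(options, n_shuffles = 999, seed = NULL,
                             scope = "overall",
                             statistic = c("sup", "area")) {
  if (inherits(options, "event_log")) options <- options$option
  statistic <- match.arg(statistic)
  stopifnot(n_shuffles >= 999)
  if (!is.null(seed)) set.seed(seed)
  options <- as.character(options)
  ranks <- assign_ranks(options)

  scoped_lengths <- function(seq) {
    r <- rle(seq)
    if (identical(scope, "overall")) return(r$lengths)
    opt <- ranks$option[ranks$rank == scope]
    r$lengths[r$values == opt]
  }

  emp_len <- scoped_lengths(options)
  if (length(emp_len) == 0L) stop("no runs in scope")
  shuf_len <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shuf_len[[s]] <- scoped_lengths(sample(options))
  }
  lmax <- max(emp_len, vapply(shuf_len, max, numeric(1)))
  S_emp <- run_lengths_survival(emp_len, lmax)
  S_shuf <- vapply(shuf_len, run_lengths_survival, numeric(lmax),
                   lmax = lmax)                       # lmax x n matrix
  S_mean <- rowMeans(S_shuf)

  if (statistic == "sup") {
    stat_fun <- function(S, Sref) max(abs(S - Sref))
  } else {
    lx <- log10(seq_len(lmax))
    stat_fun <- function(S, Sref) {
      keep <- S > 0 & Sref > 0
      if (sum(keep) < 2L) return(0)
      dy <- abs(log10(S[keep]) - log10(Sref[keep]))
      sum(diff(lx[keep]) * (dy[-1L] + dy[-length(dy)]) / 2)
    }
  }
  observed <- stat_fun(S_emp, S_mean)
  null <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    # leave-one-out ensemble mean
    Sref <- (S_mean * n_shuffles - S_shuf[, s]) / (n_shuffles - 1)
    null[s] <- stat_fun(S_shuf[, s], Sref)
  }
  p <- (1 + sum(null >= observed)) / (n_shuffles + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_shuffles = n_shuffles, seed = seed, scope = scope,
                 statistic = statistic),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(
    "<shuffle_test> scope %s: observed %s-statistic = %.4f, p = %.4g (%d shuffles)\n",
    as.character(x$scope), x$statistic, x$observed, x$p_value,
    x$n_shuffles))
  invisible(x)
}

#' Rank options by total consumption
#'
#' Rank 1 is the most-chosen option — the behavioral proxy for the
#' animal's subjective value ordering. Ties are broken by order of first
#' appearance in the sequence.
#'
#' @param options Choice sequence, or an [event_log()].
#' @return Object of class `rank_assignment`: data frame with columns
#'   `option`, `count`, `percent`, `rank`.
#' @export
assign_ranks <- function(options) {
  if (inherits(options, "event_log")) options <- options$option
  options <- as.character(options)
  if (length(options) == 0L) stop("empty choice sequence")
  opts <- unique(options)  # first-appearance order, for tie-breaking
  counts <- vapply(opts, function(o) sum(options == o), numeric(1))
  ord <- order(-counts)    # stable: ties keep first-appearance order
  out <- data.frame(option = opts[ord], count = counts[ord],
                    percent = 100 * counts[ord] / length(options),
                    rank = seq_along(opts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rank_assignment", "data.frame")
  out
}

#' Log-linear fit of choice percentage against rank
#'
#' Ordinary least squares of choice percentage on `log10(rank)`. A steep
#' negative slope quantifies how sharply preference is skewed toward the
#' top-ranked option.
#'
#' @param ranks A [assign_ranks()] result, or a numeric vector of
#'   percentages ordered by rank (rank 1 first).
#' @return List with `slope` (percent per decade of rank), `intercept`,
#'   `adj_r_squared` and the underlying `lm` fit.
#' @export
fit_rank_loglinear <- function(ranks) {
  percent <- if (inherits(ranks, "rank_assignment")) ranks$percent
             else as.numeric(ranks)
  if (length(percent) < 3L) stop("need at least 3 ranks")
  if (any(percent <= 0)) stop("percentages must be positive")
  df <- data.frame(percent = percent, lr = log10(seq_along(percent)))
  fit <- stats::lm(percent ~ lr, data = df)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adj_r_squared = summary(fit)$adj.r.squared,
       fit = fit)
}
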