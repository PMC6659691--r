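#' Classify a percent change into a trend label
#'
#' `up` when the change exceeds the dead-band `theta`, `down` when it falls
#' below `-theta`, otherwise `no_change`; the boundary `|delta| == theta`
#' is `no_change`. The dead-band absorbs assay-level jitter around zero and
#' is surfaced in every report.
#'
#' @param delta_percent Numeric vector of percent changes.
#' @param theta Dead-band in percent (default 5).
#' @return Character vector in `{"up", "down", "no_change"}`.
#' @export
classify_trend <- function(delta_percent, theta = 5) {
  if (any(is.na(delta_percent)))
    mcs_error("percent change must be finite", "mcs_input_error")
  ifelse(delta_percent > theta, "up",
         ifelse(delta_percent < -theta, "down", "no_change"))
}

#' Exact binomial tail probability
#'
#' One-sided: `P(X >= k) = sum_{j=k}^{n} C(n,j) p0^j (1-p0)^(n-j)` with the
#' binomial coefficients summed explicitly as exact integers. Two-sided:
#' `2 * min(P(X >= k), P(X <= k))` capped at 1 — the doubling convention,
#' which reproduces the two-sided value printed for 9 matches out of 10
#' (`2 * 11/1024 = 0.02148`). Under the fair-coin null `p0 = 1/2` the exact
#' rational form (integer numerator over `2^n`) is returned alongside.
#'
#' @param k Number of successes (matches), `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @param p0 Null success probability in (0, 1); default 0.5 (complete
#'   randomness of trend matching).
#' @param sided `"one"` or `"two"`.
#' @return A list of class `"binom_exact"`: `p`, `k`, `n`, `p0`, `sided`,
#'   and for `p0 = 1/2` the exact `numerator` and `denominator`.
#' @export
binomial_exact <- function(k, n, p0 = 0.5, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    mcs_error("need integers 0 <= k <= n, n >= 1", "mcs_input_error")
  if (p0 <= 0 || p0 >= 1)
    mcs_error("p0 must lie in (0, 1)", "mcs_input_error")
  upper_coefs <- choose(n, k:n)          # exact integers for n <= ~50
  lower_coefs <- choose(n, 0:k)
  p_ge <- sum(upper_coefs * p0^(k:n) * (1 - p0)^(n - (k:n)))
  p_le <- sum(lower_coefs * p0^(0:k) * (1 - p0)^(n - (0:k)))
  p <- if (sided == "one") p_ge else min(1, 2 * min(p_ge, p_le))
  out <- list(p = min(p, 1), k = k, n = n, p0 = p0, sided = sided)
  if (p0 == 0.5) {
    num <- if (sided == "one") sum(upper_coefs) else
      min(2^n, 2 * min(sum(upper_coefs), sum(lower_coefs)))
    out$numerator <- num
    out$denominator <- 2^n
  }
  structure(out, class = "binom_exact")
}

#' @export
print.binom_exact <- function(x, ...) {
  rat <- if (!is.null(x$numerator))
    sprintf(" = %.0f/%.0f", x$numerator, x$denominator) else ""
  cat(sprintf("exact binomial (%s-sided): k = %d, n = %d, p0 = %g, p = %.4g%s\n",
              x$sided, x$k, x$n, x$p0, x$p, rat))
  invisible(x)
}

#' Tabulate predicted-versus-observed trend matches
#'
#' Each marker's predicted and observed trends (labels, or percent changes
#' classified through [classify_trend()]) are compared as binary
#' match/mismatch outcomes under strict label equality (`no_change` matches
#' only `no_change`); the match count is scored with the exact binomial test
#' under a null matching probability of 0.5.
#'
#' @param predicted,observed Character trend labels, or numeric percent
#'   changes.
#' @param markers Optional marker names; when both inputs are named the
#'   names must agree (alignment is checked).
#' @param theta Dead-band for classifying numeric input.
#' @param p0 Null matching probability.
#' @return A list of class `"trend_table"`: `table` (marker, predicted,
#'   observed, match), `k`, `n`, `match_percent`, `p_one_sided`,
#'   `p_two_sided`, `theta`, `p0`.
#' @export
tabulate_matches <- function(predicted, observed, markers = NULL,
                             theta = 5, p0 = 0.5) {
  if (is.null(markers)) {
    markers <- names(predicted) %||% names(observed) %||%
      paste0("marker_", seq_along(predicted))
  }
  if (length(predicted) != length(observed))
    mcs_error("predicted and observed differ in length", "mcs_alignment_error")
  if (!is.null(names(predicted)) && !is.null(names(observed)) &&
      !identical(names(predicted), names(observed))) {
    diff <- c(setdiff(names(predicted), names(observed)),
              setdiff(names(observed), names(predicted)))
    mcs_error(paste("marker sets differ:", paste(unique(diff), collapse = ", ")),
              "mcs_alignment_error")
  }
  if (!length(predicted)) mcs_error("no rows to tabulate", "mcs_input_error")
  to_label <- function(x) if (is.numeric(x)) classify_trend(x, theta) else {
    bad <- setdiff(x, c("up", "down", "no_change"))
    if (length(bad)) mcs_error(sprintf("unknown trend label '%s'", bad[1]),
                               "mcs_input_error")
    as.character(x)
  }
  pl <- to_label(predicted); ol <- to_label(observed)
  match <- pl == ol
  k <- sum(match); n <- length(match)
  structure(list(
    table = data.frame(marker = markers, predicted = pl, observed = ol,
                       match = match, stringsAsFactors = FALSE),
    k = k, n = n, match_percent = 100 * k / n,
    p_one_sided = binomial_exact(k, n, p0, "one")$p,
    p_two_sided = binomial_exact(k, n, p0, "two")$p,
    theta = theta, p0 = p0), class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(trend_summary_line(x), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

trend_summary_line <- function(x) {
  rat <- if (x$p0 == 0.5) {
    one <- binomial_exact(x$k, x$n, 0.5, "one")
    sprintf(" (= %.0f/%.0f)", one$numerator, one$denominator)
  } else ""
  sprintf("%d/%d, %.4g%%, p_one = %.4g%s, p_two = %.4g",
          x$k, x$n, x$match_percent, x$p_one_sided, rat, x$p_two_sided)
}

#' Expected multi-cell trend from single-cell magnitudes
#'
#' The naive multi-cell expectation: the per-cell single-culture percent
#' changes are summed exactly and the sum classified into a trend.
#'
#' @param magnitudes Numeric vector of per-cell percent changes (>= 1).
#' @param theta Dead-band in percent.
#' @return A list of class `"expected_trend"`: `magnitudes`,
#'   `expected_magnitude`, `trend`, `theta`.
#' @export
expected_trend_sum <- function(magnitudes, theta = 5) {
  if (!length(magnitudes) || any(is.na(magnitudes)))
    mcs_error("need at least one finite magnitude", "mcs_input_error")
  s <- sum(magnitudes)
  structure(list(magnitudes = magnitudes, expected_magnitude = s,
                 trend = classify_trend(s, theta), theta = theta),
            class = "expected_trend")
}
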