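lag_matrix <- function(v, lag, n) {
  # columns v_{t-1} .. v_{t-lag}, rows t = lag+1 .. n
  sapply(seq_len(lag), function(j) v[(lag + 1 - j):(n - j)])
}

#' Granger-causality F-test
#'
#' Tests whether lagged values of `x` improve the prediction of `y`
#' beyond `y`'s own lags. Fits by OLS the restricted autoregression
#' y_t ~ y_{t-1..t-lag} and the unrestricted model adding
#' x_{t-1..t-lag}, both with intercept, on the n_eff = n - lag usable
#' observations, and forms
#' F = ((RSS_r - RSS_u)/lag) / (RSS_u/(n_eff - 2*lag - 1)),
#' referred to the F(lag, n_eff - 2*lag - 1) distribution.
#'
#' @param x Predictor series (numeric).
#' @param y Response series, same length, non-constant.
#' @param lag Positive integer lag order (default 1).
#' @param term Optional label carried into the result.
#' @return A `granger_result`: term, direction, lag, F, p_value,
#'   n_effective, df.
#' @export
granger_test <- function(x, y, lag = 1, term = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (lag < 1 || lag != round(lag)) stop("lag must be a positive integer")
  n <- length(y)
  if (n <= 10 * lag) stop("series too short: need length > 10 * lag")
  if (stats::var(y) == 0) stop("degenerate input: y is constant")
  yt <- y[(lag + 1):n]
  Yl <- lag_matrix(y, lag, n)
  Xl <- lag_matrix(x, lag, n)
  fit_r <- stats::lm.fit(cbind(1, Yl), yt)
  fit_u <- stats::lm.fit(cbind(1, Yl, Xl), yt)
  rss_r <- sum(fit_r$residuals^2)
  rss_u <- sum(fit_u$residuals^2)
  n_eff <- n - lag
  df2 <- n_eff - 2 * lag - 1
  if (df2 < 1) stop("series too short for this lag order")
  f_stat <- max(0, ((rss_r - rss_u) / lag) / (rss_u / df2))
  p <- stats::pf(f_stat, lag, df2, lower.tail = FALSE)
  structure(list(term = term, direction = "mentions->sentiment",
                 lag = as.integer(lag), F = f_stat, p_value = p,
                 n_effective = n_eff, df = c(lag, df2)),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger test (%s), lag %d: F(%d, %d) = %.4g, p = %.4g\n",
              ifelse(is.na(x$term), x$direction, x$term), x$lag,
              x$df[1], x$df[2], x$F, x$p_value))
  invisible(x)
}

#' Multi-lag Granger scan with Bonferroni correction
#'
#' Runs [granger_test()] at each lag in `lags` and reports the smallest
#' Bonferroni-adjusted p-value together with the lag attaining it.
#'
#' @inheritParams granger_test
#' @param lags Vector of positive integer lags to scan.
#' @return A `granger_result` for the best lag, with the adjusted p-value
#'   and a `scanned_lags` field.
#' @export
granger_scan <- function(x, y, lags = 1:3, term = NA_character_) {
  res <- lapply(lags, function(l) granger_test(x, y, lag = l, term = term))
  p_adj <- pmin(1, vapply(res, `[[`, 0, "p_value") * length(lags))
  best <- which.min(p_adj)
  out <- res[[best]]
  out$p_value <- p_adj[best]
  out$scanned_lags <- lags
  out
}

#' Rank candidate terms by term-mention / sentiment association
#'
#' For each candidate term, builds its daily mention series and the daily
#' positive-share and negative-share series of the posts mentioning it,
#' and Granger-tests mentions against each polarity share separately
#' (positive and negative attitudes are reported as distinct
#' associations). Terms are ranked by the minimum of the two p-values;
#' terms whose minimum p is below `alpha` are flagged significant.
#' P-values are reported raw by default; set `adjust = "BH"` for a
#' Benjamini-Hochberg correction across terms.
#'
#' @param corpus A [corpus()].
#' @param scores Output of [classify_corpus()].
#' @param terms Character vector of candidate terms (>= 1).
#' @param lag Lag order in days (default 1).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` across terms.
#' @return Tibble ranked by min p: term, p_positive, p_negative, p_min,
#'   F_positive, F_negative, mentions, significant, degenerate.
#' @export
rank_terms <- function(corpus, scores, terms, lag = 1, alpha = 0.05,
                       adjust = c("none", "BH")) {
  stopifnot(inherits(corpus, "corpus"))
  adjust <- match.arg(adjust)
  if (length(terms) < 1) stop("need at least one candidate term")
  rows <- lapply(terms, function(tm) {
    ds <- daily_series(corpus, scores, tm)
    total <- sum(ds$mentions)
    one <- function(share) {
      tryCatch({
        g <- granger_test(ds$mentions, share, lag = lag, term = tm)
        c(g$p_value, g$F)
      }, error = function(e) c(NA_real_, NA_real_))
    }
    pos <- one(ds$pos_share)
    neg <- one(ds$neg_share)
    tibble::tibble(term = tm, p_positive = pos[1], p_negative = neg[1],
                   F_positive = pos[2], F_negative = neg[2],
                   mentions = total,
                   degenerate = total == 0 || (is.na(pos[1]) && is.na(neg[1])))
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") {
    out$p_positive <- stats::p.adjust(out$p_positive, method = "BH")
    out$p_negative <- stats::p.adjust(out$p_negative, method = "BH")
  }
  both_na <- is.na(out$p_positive) & is.na(out$p_negative)
  out$p_min <- ifelse(both_na, NA_real_,
                      pmin(out$p_positive, out$p_negative, na.rm = TRUE))
  out$significant <- !is.na(out$p_min) & out$p_min < alpha
  out[order(out$p_min, na.last = TRUE), , drop = FALSE]
}
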