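#' Score one post's sentiment against a lexicon
#'
#' Counts token hits in the positive and negative word lists and labels the
#' post by the sign of the difference: +1 when positive hits exceed
#' negative, -1 for the converse, 0 for a tie or no hits. Negation
#' ("not better") is deliberately not handled; the scorer is a transparent
#' word-count polarity classifier.
#'
#' @param text Post text.
#' @param lexicon A [sentiment_lexicon()].
#' @return List: n_positive_hits, n_negative_hits, label (-1/0/1).
#' @export
score_post <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  toks <- tokenize(text)
  npos <- sum(toks %in% lexicon$positive)
  nneg <- sum(toks %in% lexicon$negative)
  list(n_positive_hits = npos, n_negative_hits = nneg,
       label = as.integer(sign(npos - nneg)))
}

#' Classify every post in a corpus
#'
#' Applies [score_post()] per post and logs the resulting
#' positive/neutral/negative proportions.
#'
#' @param corpus A [corpus()].
#' @param lexicon A [sentiment_lexicon()].
#' @return Tibble: post_id, n_positive_hits, n_negative_hits, label.
#' @export
classify_corpus <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "corpus"))
  scores <- lapply(corpus$posts$text, score_post, lexicon = lexicon)
  out <- tibble::tibble(
    post_id = corpus$posts$post_id,
    n_positive_hits = vapply(scores, `[[`, 0L, "n_positive_hits"),
    n_negative_hits = vapply(scores, `[[`, 0L, "n_negative_hits"),
    label = vapply(scores, `[[`, 0L, "label")
  )
  if (nrow(out) > 0) {
    prop <- table(factor(out$label, levels = c(1, 0, -1))) / nrow(out)
    message(sprintf(
      "classify_corpus: %d posts; %.1f%% positive, %.1f%% neutral, %.1f%% negative",
      nrow(out), 100 * prop[["1"]], 100 * prop[["0"]], 100 * prop[["-1"]]))
  }
  out
}

post_contains_term <- function(text, term) {
  toks <- tokenize(text)
  term %in% c(toks, token_bigrams(toks))
}

#' Daily mention and sentiment series for a term
#'
#' Aggregates a classified corpus to one row per calendar day across the
#' full corpus date range (days without posts appear as zero-mention
#' days). For each day: `mentions` is the number of posts containing the
#' term, `sentiment` the mean label of those posts (0 when none),
#' `pos_share`/`neg_share` the fractions of those posts labeled +1/-1.
#'
#' @param corpus A [corpus()].
#' @param scores Output of [classify_corpus()] aligned to the corpus, or
#'   any tibble with post_id and label columns covering every post.
#' @param term Target term (lowercase word or two-word phrase).
#' @return Tibble: date, mentions, sentiment, pos_share, neg_share.
#' @export
daily_series <- function(corpus, scores, term) {
  stopifnot(inherits(corpus, "corpus"))
  if (!nzchar(trimws(term))) stop("term must be nonempty")
  term <- tolower(trimws(term))
  if (!all(corpus$posts$post_id %in% scores$post_id)) {
    stop("scores do not cover every post in the corpus")
  }
  days <- seq(corpus$date_range[1], corpus$date_range[2], by = "day")
  out <- tibble::tibble(date = days, mentions = 0L, sentiment = 0,
                        pos_share = 0, neg_share = 0)
  if (nrow(corpus$posts) == 0) return(out)
  lab <- scores$label[match(corpus$posts$post_id, scores$post_id)]
  has <- vapply(corpus$posts$text, post_contains_term, logical(1),
                term = term, USE.NAMES = FALSE)
  if (!any(has)) return(out)
  d <- as.Date(corpus$posts$timestamp[has], tz = "UTC")
  l <- lab[has]
  agg <- tibble::tibble(date = d, label = l) |>
    dplyr::group_by(date) |>
    dplyr::summarise(mentions = dplyr::n(), sentiment = mean(label),
                     pos_share = mean(label == 1),
                     neg_share = mean(label == -1), .groups = "drop")
  idx <- match(agg$date, out$date)
  out$mentions[idx] <- as.integer(agg$mentions)
  out$sentiment[idx] <- agg$sentiment
  out$pos_share[idx] <- agg$pos_share
  out$neg_share[idx] <- agg$neg_share
  out
}
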