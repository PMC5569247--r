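FILLER_WORDS <- c(
  "today", "week", "month", "morning", "evening", "again", "later",
  "update", "share", "story", "question", "anyone", "else", "time",
  "year", "people", "group", "page", "reading", "writing", "journey",
  "thoughts", "everyone", "little", "really", "about", "along", "still",
  "maybe", "soon"
)

#' Configuration for the synthetic-corpus generator
#'
#' The generator emulates the statistical structure of a scraped
#' social-media patient corpus: many accounts with heterogeneous
#' (Poisson) posting rates, a spam subpopulation that reposts identical
#' messages, posts seeded with subtopic-dictionary terms, post-level
#' sentiment polarity encoded with lexicon words, and (optionally) a
#' lagged coupling in which a drug term's daily mention count shifts the
#' mean sentiment of that term's posts some days later, so that Granger
#' structure is recoverable. Defaults reflect the study setting: the
#' October 2011 - August 2015 window and a sentiment mix near the
#' published expert proportions.
#'
#' @param n_accounts Number of author accounts.
#' @param spam_fraction Proportion of accounts that are spam (< 1).
#' @param posts_per_account_mean Mean of the per-account Poisson post
#'   count (spam accounts post at least 2).
#' @param date_range Length-2 Date vector.
#' @param subtopic_term_rate Probability a post is seeded with a term from
#'   each subtopic dictionary (independently per dictionary).
#' @param sentiment_mix Probabilities (pos, neu, neg) summing to 1.
#' @param coupled_term Term whose mentions drive later sentiment; `NULL`
#'   disables coupling posts.
#' @param coupling_beta Strength of the lagged mention-to-sentiment
#'   dependence (0 = independent).
#' @param coupling_lag Lag in days.
#' @param coupled_daily_rate Poisson mean of coupled-term posts per day.
#' @param seed Integer RNG seed; identical seeds give identical corpora.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_accounts = 100,
                             spam_fraction = 0.1,
                             posts_per_account_mean = 8,
                             date_range = as.Date(c("2011-10-01",
                                                    "2015-08-31")),
                             subtopic_term_rate = 0.3,
                             sentiment_mix = c(pos = 0.37, neu = 0.27,
                                               neg = 0.36),
                             coupled_term = NULL,
                             coupling_beta = 0,
                             coupling_lag = 1,
                             coupled_daily_rate = 2,
                             seed = 1) {
  stopifnot(n_accounts >= 1, posts_per_account_mean > 0)
  if (spam_fraction < 0 || spam_fraction >= 1) {
    stop("spam_fraction must lie in [0, 1)")
  }
  if (subtopic_term_rate < 0 || subtopic_term_rate > 1) {
    stop("subtopic_term_rate must lie in [0, 1]")
  }
  if (length(sentiment_mix) != 3 || any(sentiment_mix < 0) ||
      abs(sum(sentiment_mix) - 1) > 1e-9) {
    stop("sentiment_mix must be 3 probabilities summing to 1")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range) ||
      date_range[2] < date_range[1]) {
    stop("date_range must be a valid [start, end] pair")
  }
  if (!is.finite(coupling_beta)) stop("coupling_beta must be finite")
  if (coupling_lag < 1) stop("coupling_lag must be a positive integer")
  structure(list(
    n_accounts = as.integer(n_accounts), spam_fraction = spam_fraction,
    posts_per_account_mean = posts_per_account_mean,
    date_range = date_range, subtopic_term_rate = subtopic_term_rate,
    sentiment_mix = unname(sentiment_mix), coupled_term = coupled_term,
    coupling_beta = coupling_beta, coupling_lag = as.integer(coupling_lag),
    coupled_daily_rate = coupled_daily_rate, seed = as.integer(seed)
  ), class = "generator_config")
}

sample_label <- function(n, mix) {
  sample(c(1L, 0L, -1L), n, replace = TRUE, prob = mix)
}

# Build one post text from shuffled closed-vocabulary units. Units are
# whole dictionary terms (possibly bigrams), polarity words and filler;
# the closed vocabulary guarantees downstream counts match ground truth.
build_text <- function(dict_terms, label, lexicon) {
  units <- dict_terms
  if (label == 1L) {
    units <- c(units, sample(lexicon$positive, sample(1:3, 1)))
  } else if (label == -1L) {
    units <- c(units, sample(lexicon$negative, sample(1:3, 1)))
  }
  units <- c(units, sample(FILLER_WORDS, sample(3:6, 1)))
  paste(sample(units), collapse = " ")
}

#' Generate a synthetic corpus with known ground truth
#'
#' See [generator_config()] for the emulated structure. Guarantees by
#' construction: spam accounts emit at least one exact-duplicate pair;
#' non-spam posts are globally distinct; a post labeled positive
#' (negative) contains strictly more positive (negative) lexicon words
#' than the opposite polarity and a neutral post contains none; every
#' subtopic-tagged post contains at least one term of that dictionary;
#' identical seeds yield identical output.
#'
#' @param config A [generator_config()].
#' @param dictionaries Subtopic dictionaries (default the packaged four).
#' @param lexicon Sentiment lexicon (default the packaged stand-in).
#' @return List with elements `corpus` (a [corpus()]) and `truth`, the
#'   ground truth: `spam_accounts`, `post_sentiment` (named vector by
#'   post_id), `post_subtopics` (named list), `term_counts` (tibble of
#'   injected occurrence counts), `daily_coupled_mentions` (tibble, when
#'   coupling posts are generated).
#' @export
generate_corpus <- function(config,
                            dictionaries = packaged_dictionaries(),
                            lexicon = packaged_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  days <- seq(config$date_range[1], config$date_range[2], by = "day")

  accounts <- sprintf("acct%04d", seq_len(config$n_accounts))
  n_spam <- round(config$n_accounts * config$spam_fraction)
  spam_accounts <- if (n_spam > 0) sort(sample(accounts, n_spam)) else character()
  is_spam <- accounts %in% spam_accounts

  dict_names <- vapply(dictionaries, `[[`, "", "name")
  # the coupled term is reserved for coupling posts so its mention series
  # carries only the injected lag structure
  pools <- lapply(dictionaries, function(d) {
    setdiff(d$entries, config$coupled_term)
  })

  post_rows <- list()
  truth_sent <- integer()
  truth_sub <- list()
  inject_terms <- list()
  seen_norm <- new.env(hash = TRUE, parent = emptyenv())
  pid <- 0L

  new_id <- function() {
    pid <<- pid + 1L
    sprintf("p%06d", pid)
  }

  draw_subtopics <- function() {
    hit <- runif(length(dictionaries)) < config$subtopic_term_rate
    terms <- character()
    for (j in which(hit)) {
      if (length(pools[[j]]) > 0) terms <- c(terms, sample(pools[[j]], 1))
    }
    list(subtopics = dict_names[hit & lengths(pools) > 0], terms = terms)
  }

  make_post <- function(author, day, label, extra_term = NULL) {
    sub <- draw_subtopics()
    terms <- c(extra_term, sub$terms)
    subtopics <- sub$subtopics
    if (!is.null(extra_term)) {
      owner <- dict_names[vapply(dictionaries, function(d)
        extra_term %in% d$entries, logical(1))]
      subtopics <- union(subtopics, owner)
    }
    repeat {
      text <- build_text(terms, label, lexicon)
      norm <- normalize_text(text)
      if (!exists(norm, envir = seen_norm, inherits = FALSE)) break
    }
    assign(norm, TRUE, envir = seen_norm)
    id <- new_id()
    ts <- as.POSIXct(day, tz = "UTC") + sample(0:86399, 1)
    platform <- sample(c("facebook", "twitter"), 1, prob = c(0.7, 0.3))
    truth_sent[[id]] <<- label
    truth_sub[[id]] <<- subtopics
    inject_terms[[id]] <<- terms
    tibble::tibble(post_id = id, author_id = author, platform = platform,
                   timestamp = ts, text = text)
  }

  for (a in seq_along(accounts)) {
    n_i <- rpois(1, config$posts_per_account_mean)
    if (is_spam[a]) n_i <- max(n_i, 3L)
    if (n_i == 0) next
    labels <- sample_label(n_i, config$sentiment_mix)
    post_days <- sample(days, n_i, replace = TRUE)
    if (is_spam[a]) {
      # bulk-posting accounts repeat one message: at most a third of their
      # posts are distinct, so every spam account carries >= 2 duplicates
      # of its lead text (and >= 1 exact-duplicate pair)
      n_base <- max(1L, floor(n_i / 3))
      rows <- lapply(seq_len(n_base), function(j) {
        make_post(accounts[a], post_days[j], labels[j])
      })
      base <- rows[[1]]
      for (j in (n_base + 1):n_i) {
        id <- new_id()
        ts <- as.POSIXct(post_days[j], tz = "UTC") + sample(0:86399, 1)
        truth_sent[[id]] <- truth_sent[[base$post_id]]
        truth_sub[[id]] <- truth_sub[[base$post_id]]
        inject_terms[[id]] <- inject_terms[[base$post_id]]
        rows <- c(rows, list(tibble::tibble(
          post_id = id, author_id = accounts[a], platform = base$platform,
          timestamp = ts, text = base$text)))
      }
      post_rows <- c(post_rows, rows)
    } else {
      post_rows <- c(post_rows, lapply(seq_len(n_i), function(j) {
        make_post(accounts[a], post_days[j], labels[j])
      }))
    }
  }

  daily_mentions <- NULL
  if (!is.null(config$coupled_term)) {
    lam <- config$coupled_daily_rate
    m <- rpois(length(days), lam)
    z <- (m - lam) / sqrt(lam)
    lag <- config$coupling_lag
    nonspam <- accounts[!is_spam]
    rows <- list()
    for (d in seq_along(days)) {
      if (m[d] == 0) next
      drive <- if (d > lag) tanh(config$coupling_beta * z[d - lag]) else 0
      p_pos <- (1 + drive) / 2
      for (j in seq_len(m[d])) {
        lab <- if (runif(1) < p_pos) 1L else -1L
        rows <- c(rows, list(make_post(sample(nonspam, 1), days[d], lab,
                                       extra_term = config$coupled_term)))
      }
    }
    post_rows <- c(post_rows, rows)
    daily_mentions <- tibble::tibble(date = days, mentions = as.integer(m))
  }

  posts <- dplyr::bind_rows(post_rows)
  posts <- posts[order(posts$timestamp, posts$post_id), , drop = FALSE]
  cp <- corpus(posts, date_range = config$date_range)

  counts <- table(unlist(inject_terms[posts$post_id], use.names = FALSE))
  term_counts <- tibble::tibble(term = names(counts),
                                count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(count), term)

  truth <- list(spam_accounts = spam_accounts,
                post_sentiment = unlist(truth_sent),
                post_subtopics = truth_sub,
                term_counts = term_counts,
                daily_coupled_mentions = daily_mentions)
  list(corpus = cp, truth = truth)
}

#' Generate a pair of series with known lagged dependence
#'
#' x is standard-normal white noise; y_t = beta * x_{t-lag} + eps_t with
#' eps ~ Normal(0, noise_sd^2) (pure noise for t <= lag). With beta = 0
#' the series are independent; otherwise x Granger-causes y at the given
#' lag. Used as a calibration testbed for [granger_test()].
#'
#' @param n Series length (> 10 * lag).
#' @param beta Coupling coefficient (finite).
#' @param lag Positive integer lag.
#' @param noise_sd Positive noise standard deviation.
#' @param seed Integer RNG seed.
#' @return List with numeric vectors `x` and `y` of length n.
#' @export
generate_coupled_series <- function(n, beta, lag = 1, noise_sd = 1,
                                    seed = 1) {
  if (!is.finite(beta) || !is.finite(noise_sd)) {
    stop("beta and noise_sd must be finite")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (lag < 1) stop("lag must be a positive integer")
  if (n <= 10 * lag) stop("series too short: need n > 10 * lag")
  set.seed(seed)
  x <- rnorm(n)
  eps <- rnorm(n, sd = noise_sd)
  y <- eps
  idx <- (lag + 1):n
  y[idx] <- beta * x[idx - lag] + eps[idx]
  list(x = x, y = y)
}

#' Generate rating pairs realizing a given contingency table
#'
#' Expands a k x k cell-count matrix into the corresponding list of
#' (rater_a, rater_b) score pairs and shuffles their order under the
#' seed. [build_confusion_matrix()] on the output recovers the input
#' matrix exactly.
#'
#' @param cell_counts k x k nonnegative integer matrix (rows = rater A).
#' @param scores Ordered score levels, default c(-1, 0, 1).
#' @param seed Integer RNG seed for the shuffle.
#' @return Tibble with sum(cell_counts) rows: rater_a, rater_b.
#' @export
generate_rating_pairs <- function(cell_counts, scores = c(-1, 0, 1),
                                  seed = 1) {
  cell_counts <- as.matrix(cell_counts)
  if (any(cell_counts < 0) || any(cell_counts != round(cell_counts))) {
    stop("cell_counts must be nonnegative integers")
  }
  if (nrow(cell_counts) != length(scores) ||
      ncol(cell_counts) != length(scores)) {
    stop("cell_counts must be ", length(scores), " x ", length(scores))
  }
  idx <- which(cell_counts > 0, arr.ind = TRUE)
  a <- rep(scores[idx[, 1]], cell_counts[idx])
  b <- rep(scores[idx[, 2]], cell_counts[idx])
  out <- tibble::tibble(rater_a = a, rater_b = b)
  if (nrow(out) > 1) {
    set.seed(seed)
    out <- out[sample(nrow(out)), , drop = FALSE]
  }
  out
}

#' The published 3 x 3 expert contingency table
#'
#' The cross-tabulation of the senior gastroenterologist's (rows) and
#' computer-science expert's (columns) 3-point Likert ratings of the 261
#' Infliximab posts, used as the package's exact validation fixture for
#' the agreement module.
#'
#' @return A `confusion_matrix` with N = 261.
#' @export
expert_table <- function() {
  as_confusion_matrix(rbind(c(62, 17, 5),
                            c(22, 40, 16),
                            c(11, 13, 75)),
                      scores = c(-1, 0, 1))
}
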