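#' Configuration for a full pipeline run
#'
#' Bundles the inputs and tuning parameters of the end-to-end analysis:
#' spam filtering, subtopic tagging, frequent-term selection, sentiment
#' classification, and Granger ranking of candidate terms.
#'
#' @param corpus Either a [corpus()] or a path readable by [read_posts()].
#' @param dictionaries Named list of `subtopic_dictionary` (default the
#'   packaged four).
#' @param lexicon A [sentiment_lexicon()] (default the packaged stand-in).
#' @param spam_max_duplicates Duplicate tolerance for
#'   [flag_spam_accounts()] (default 1).
#' @param term_min_count Minimum occurrences for [select_terms()]
#'   (default 50).
#' @param candidate_terms Terms to Granger-rank; `NULL` uses the selected
#'   frequent terms (capped at `max_candidates` by count).
#' @param max_candidates Cap on auto-selected candidates (default 10).
#' @param granger_lag Lag order in days (default 1).
#' @param alpha Significance level for flagging (default 0.05).
#' @param kappa_scheme Weight scheme for any agreement stage.
#' @param output_dir Optional directory for the JSON report and CSV
#'   artifacts; `NULL` writes nothing.
#' @param seed Integer seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus,
                            dictionaries = packaged_dictionaries(),
                            lexicon = packaged_lexicon(),
                            spam_max_duplicates = 1,
                            term_min_count = 50,
                            candidate_terms = NULL,
                            max_candidates = 10,
                            granger_lag = 1,
                            alpha = 0.05,
                            kappa_scheme = "quadratic",
                            output_dir = NULL,
                            seed = 1) {
  if (is.character(corpus)) {
    if (!file.exists(corpus)) stop("corpus path does not exist: ", corpus)
  } else {
    stopifnot(inherits(corpus, "corpus"))
  }
  if (spam_max_duplicates < 0) stop("spam_max_duplicates must be >= 0")
  if (term_min_count < 0) stop("term_min_count must be >= 0")
  if (granger_lag < 1) stop("granger_lag must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(corpus = corpus, dictionaries = dictionaries,
                 lexicon = lexicon,
                 spam_max_duplicates = spam_max_duplicates,
                 term_min_count = term_min_count,
                 candidate_terms = candidate_terms,
                 max_candidates = max_candidates,
                 granger_lag = granger_lag, alpha = alpha,
                 kappa_scheme = kappa_scheme, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full patient-feedback analysis pipeline
#'
#' Executes, in order: corpus loading, duplicate-based spam-account
#' flagging and filtering, subtopic term counting, frequent-term
#' selection, lexicon sentiment classification, and Granger ranking of
#' candidate terms against daily polarity-share series. Logs each
#' filter's input/output counts; deterministic given the input and seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `counts` (funnel of post counts),
#'   `flagged_accounts`, `term_counts`, `selected_terms`,
#'   `sentiment_proportions`, `ranking`, `seed`. If `output_dir` is set,
#'   also writes report.json plus CSV tables there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cp <- stage("load", {
    if (is.character(config$corpus)) read_posts(config$corpus)
    else config$corpus
  })
  n_in <- n_posts(cp)
  message(sprintf("pipeline: %d posts in", n_in))

  rep_dup <- stage("spam_filter", duplicate_counts(cp))
  flagged <- stage("spam_filter",
                   flag_spam_accounts(rep_dup, config$spam_max_duplicates))
  cp_clean <- stage("spam_filter", filter_corpus(cp, flagged))

  tf <- stage("subtopics", term_frequencies(cp_clean, config$dictionaries))
  selected <- stage("subtopics", select_terms(tf, config$term_min_count))

  scores <- stage("sentiment", classify_corpus(cp_clean, config$lexicon))
  n_cl <- nrow(scores)
  props <- if (n_cl > 0) {
    tab <- table(factor(scores$label, levels = c(1, 0, -1)))
    c(positive = unname(tab[["1"]]) / n_cl,
      neutral = unname(tab[["0"]]) / n_cl,
      negative = unname(tab[["-1"]]) / n_cl)
  } else c(positive = NA_real_, neutral = NA_real_, negative = NA_real_)

  cands <- config$candidate_terms
  if (is.null(cands)) cands <- head(selected$term, config$max_candidates)
  ranking <- if (length(cands) > 0) {
    stage("granger", rank_terms(cp_clean, scores, cands,
                                lag = config$granger_lag,
                                alpha = config$alpha))
  } else {
    NULL
  }

  report <- structure(list(
    counts = c(posts_in = n_in, posts_after_spam_filter = n_posts(cp_clean),
               posts_removed = n_in - n_posts(cp_clean)),
    flagged_accounts = flagged,
    term_counts = tf$counts,
    selected_terms = selected,
    sentiment_proportions = props,
    ranking = ranking,
    seed = config$seed
  ), class = "pipeline_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      counts = as.list(report$counts),
      flagged_accounts = report$flagged_accounts,
      sentiment_proportions = as.list(props),
      selected_terms = selected,
      ranking = ranking,
      seed = config$seed
    ), file.path(config$output_dir, "report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
    write.csv(tf$counts, file.path(config$output_dir, "term_counts.csv"),
              row.names = FALSE)
    if (!is.null(ranking)) {
      write.csv(ranking, file.path(config$output_dir, "term_ranking.csv"),
                row.names = FALSE)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  posts: %d in -> %d after spam filter (%d removed, %d accounts flagged)\n",
              x$counts["posts_in"], x$counts["posts_after_spam_filter"],
              x$counts["posts_removed"], length(x$flagged_accounts)))
  cat(sprintf("  sentiment: %.1f%% positive / %.1f%% neutral / %.1f%% negative\n",
              100 * x$sentiment_proportions["positive"],
              100 * x$sentiment_proportions["neutral"],
              100 * x$sentiment_proportions["negative"]))
  cat(sprintf("  %d terms selected (min count rule)\n", nrow(x$selected_terms)))
  if (!is.null(x$ranking)) {
    top <- x$ranking[1, ]
    cat(sprintf("  top term: %s (min p = %.4g%s)\n", top$term, top$p_min,
                ifelse(isTRUE(top$significant), ", significant", "")))
  }
  invisible(x)
}
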