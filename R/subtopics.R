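#' Tokenize free text
#'
#' Lowercases, splits on whitespace, and strips leading/trailing
#' punctuation from each token. Internal hyphens and apostrophes are
#' preserved ("can't" stays one token); no stemming is applied, so
#' dictionary matching is token-exact ("bleeding" does not match "bleed").
#'
#' @param text A character scalar.
#' @return Character vector of tokens (empty for empty text).
#' @export
tokenize <- function(text) {
  if (length(text) != 1) stop("tokenize expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  toks <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  toks <- gsub("^[^a-z0-9]+|[^a-z0-9']+$", "", toks)
  toks <- sub("'+$", "", toks)
  toks[nzchar(toks)]
}

token_bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2) return(character())
  paste(tokens[-n], tokens[-1])
}

#' Count dictionary-term occurrences across a corpus
#'
#' Single-word dictionary entries are matched as exact lowercase tokens;
#' two-word entries as adjacent token bigrams. Every occurrence counts (a
#' term appearing twice in one post contributes 2). Dictionaries must be
#' disjoint: each term belongs to exactly one subtopic.
#'
#' @param corpus A [corpus()].
#' @param dictionaries List of `subtopic_dictionary` objects.
#' @return A `term_frequency_table`: list with `counts` (tibble: subtopic,
#'   term, count) and `post_hits` (tibble: post_id, subtopic, term, n).
#' @export
term_frequencies <- function(corpus, dictionaries) {
  stopifnot(inherits(corpus, "corpus"))
  if (inherits(dictionaries, "subtopic_dictionary")) {
    dictionaries <- list(dictionaries)
  }
  all_terms <- unlist(lapply(dictionaries, `[[`, "entries"), use.names = FALSE)
  dup <- all_terms[duplicated(all_terms)]
  if (length(dup) > 0) {
    stop("dictionaries overlap on term(s): ",
         paste(unique(dup), collapse = ", "))
  }
  term_topic <- rep(vapply(dictionaries, `[[`, "", "name"),
                    vapply(dictionaries, function(d) length(d$entries), 0L))
  names(term_topic) <- all_terms

  hits <- vector("list", nrow(corpus$posts))
  for (i in seq_len(nrow(corpus$posts))) {
    toks <- tokenize(corpus$posts$text[i])
    grams <- c(toks, token_bigrams(toks))
    found <- grams[grams %in% all_terms]
    if (length(found) > 0) {
      tab <- table(found)
      hits[[i]] <- tibble::tibble(
        post_id = corpus$posts$post_id[i],
        subtopic = unname(term_topic[names(tab)]),
        term = names(tab),
        n = as.integer(tab)
      )
    }
  }
  post_hits <- dplyr::bind_rows(hits)
  if (nrow(post_hits) == 0) {
    post_hits <- tibble::tibble(post_id = character(), subtopic = character(),
                                term = character(), n = integer())
  }
  counts <- post_hits |>
    dplyr::group_by(subtopic, term) |>
    dplyr::summarise(count = sum(n), .groups = "drop") |>
    dplyr::arrange(subtopic, dplyr::desc(count), term)
  structure(list(counts = counts, post_hits = post_hits),
            class = "term_frequency_table")
}

#' @export
print.term_frequency_table <- function(x, ...) {
  cat(sprintf("<term_frequency_table> %d distinct terms, %d total occurrences\n",
              nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

#' Select frequent terms
#'
#' Keeps terms whose corpus-wide occurrence count is at least `min_count`
#' (default 50, the conventional cut for retaining a term as an analysis
#' candidate), sorted by descending count with ties broken alphabetically.
#'
#' @param table A `term_frequency_table` from [term_frequencies()].
#' @param min_count Minimum occurrence count (inclusive).
#' @return Tibble with columns subtopic, term, count.
#' @export
select_terms <- function(table, min_count = 50) {
  stopifnot(inherits(table, "term_frequency_table"))
  if (min_count < 0) stop("min_count must be nonnegative")
  table$counts |>
    dplyr::filter(count >= min_count) |>
    dplyr::arrange(dplyr::desc(count), term)
}

#' Class-conditional probabilities of a term
#'
#' For a term w and posts labeled with one of k classes, p_i(w) is the
#' fraction of the posts containing w that belong to class i: the
#' conditional probability that a document is of class i given that it
#' contains w. The vector sums to 1 and feeds [gini_index()].
#'
#' @param corpus A [corpus()].
#' @param labels Character/factor vector of class labels, one per post,
#'   aligned with the corpus.
#' @param w Term (single word or two-word phrase, lowercase).
#' @param classes Optional class level ordering; defaults to sorted unique
#'   labels.
#' @return Named numeric probability vector over classes.
#' @export
class_conditional_probabilities <- function(corpus, labels, w,
                                            classes = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  if (length(labels) != nrow(corpus$posts)) {
    stop("labels must align with corpus posts")
  }
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (!all(labels %in% classes)) stop("labels outside declared classes")
  w <- tolower(trimws(w))
  contains <- vapply(corpus$posts$text, function(txt) {
    toks <- tokenize(txt)
    w %in% c(toks, token_bigrams(toks))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(contains)) {
    stop("term '", w, "' does not occur in the corpus; conditional ",
         "probabilities are undefined")
  }
  tab <- table(factor(labels[contains], levels = classes))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, classes)
}

#' Gini index of a class-probability vector
#'
#' G = sum of squared class-conditional probabilities p_i(w)^2. Measures a
#' term's discriminative power across k classes: 1/k for a term spread
#' uniformly over classes (uninformative) up to 1 for a term confined to a
#' single class. The attainable range is the closed interval [1/k, 1].
#'
#' @param p Probability vector (entries in [0,1], summing to 1).
#' @return The Gini index value.
#' @export
gini_index <- function(p) {
  p <- as.numeric(p)
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("probabilities must lie in [0,1]")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probability vector must sum to 1 (got ", format(sum(p)), ")")
  }
  sum(p^2)
}
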