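#' Normalize post text for duplicate detection
#'
#' Lowercases, strips punctuation, and collapses runs of whitespace, so
#' that trivial reformattings of the same message ("Buy now!" vs
#' "buy  now") compare equal. Duplicate detection is exact match on this
#' normalized form; no fuzzy/edit-distance matching is attempted, keeping
#' the filter auditable.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(text) {
  out <- tolower(text)
  out <- gsub("[[:punct:]]+", " ", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Per-author duplicate-post report
#'
#' Nonhuman accounts (news feeds, advertisers) tend to repost identical
#' messages; this report counts, for every author, how many of their posts
#' exactly duplicate (after [normalize_text()]) an earlier post of theirs,
#' and the size of their largest clone set.
#'
#' @param corpus A [corpus()].
#' @return A `duplicate_report` tibble: author_id, n_posts,
#'   n_duplicate_posts, max_clone_size; one row per author with >= 1 post.
#' @export
duplicate_counts <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  df <- corpus$posts
  if (nrow(df) == 0) {
    out <- tibble::tibble(author_id = character(), n_posts = integer(),
                          n_duplicate_posts = integer(),
                          max_clone_size = integer())
  } else {
    out <- tibble::tibble(author_id = df$author_id,
                          norm = normalize_text(df$text)) |>
      dplyr::group_by(author_id) |>
      dplyr::summarise(
        n_posts = dplyr::n(),
        n_duplicate_posts = sum(duplicated(norm)),
        max_clone_size = max(table(norm)),
        .groups = "drop"
      ) |>
      dplyr::arrange(author_id)
    out$n_duplicate_posts <- as.integer(out$n_duplicate_posts)
    out$max_clone_size <- as.integer(out$max_clone_size)
  }
  class(out) <- c("duplicate_report", class(out))
  out
}

#' Flag spam accounts by duplicate count
#'
#' Authors with strictly more than `max_duplicates` duplicate posts are
#' flagged. The default of 1 tolerates a single repost; accounts posting
#' three or more identical messages are flagged.
#'
#' @param report Output of [duplicate_counts()].
#' @param max_duplicates Nonnegative tolerance threshold.
#' @return Character vector of flagged author ids (sorted).
#' @export
flag_spam_accounts <- function(report, max_duplicates = 1) {
  stopifnot(inherits(report, "duplicate_report"))
  if (max_duplicates < 0) stop("max_duplicates must be nonnegative")
  sort(report$author_id[report$n_duplicate_posts > max_duplicates])
}

#' Most prolific authors
#'
#' Ranks authors by post count, descending, ties broken lexicographically
#' by author id. Intended for human review: highly prolific accounts merit
#' a manual check of whether they are patients or bulk posters.
#'
#' @param corpus A [corpus()].
#' @param k Number of authors to return.
#' @return Tibble author_id, n_posts with at most k rows.
#' @export
top_authors <- function(corpus, k) {
  stopifnot(inherits(corpus, "corpus"))
  if (k < 1) stop("k must be >= 1")
  corpus$posts |>
    dplyr::count(author_id, name = "n_posts") |>
    dplyr::arrange(dplyr::desc(n_posts), author_id) |>
    head(k)
}

#' Remove flagged authors' posts from a corpus
#'
#' Keeps exactly the posts of unflagged authors, preserving order, and
#' reports the number of removed posts as a message.
#'
#' @param corpus A [corpus()].
#' @param flagged Character vector of author ids to drop.
#' @return Filtered [corpus()] (same date_range).
#' @export
filter_corpus <- function(corpus, flagged) {
  stopifnot(inherits(corpus, "corpus"))
  keep <- !corpus$posts$author_id %in% flagged
  removed <- sum(!keep)
  message(sprintf("filter_corpus: removed %d of %d posts (%d flagged authors)",
                  removed, length(keep), length(unique(flagged))))
  corpus(corpus$posts[keep, , drop = FALSE], date_range = corpus$date_range)
}
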