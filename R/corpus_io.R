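#' @importFrom stats pf rbinom rnorm rpois runif setNames
#' @importFrom utils head read.csv write.csv
NULL

POST_FIELDS <- c("post_id", "author_id", "platform", "timestamp", "text")
PLATFORMS <- c("facebook", "twitter")
SUBTOPIC_NAMES <- c("lifestyle", "symptoms", "treatments", "side_effects")

#' Construct a corpus of social-media posts
#'
#' A corpus is the unit of analysis of the pipeline: an ordered collection of
#' posts (one row per message) together with the calendar date range they
#' span. Post ids must be unique and every timestamp must fall inside the
#' date range.
#'
#' @param posts A data frame with columns `post_id`, `author_id`, `platform`
#'   (`"facebook"` or `"twitter"`), `timestamp` (POSIXct, UTC) and `text`.
#' @param date_range Length-2 `Date` vector `[start, end]`; defaults to the
#'   range of the post timestamps.
#' @return An object of class `corpus`: a list with elements `posts`
#'   (a tibble) and `date_range`.
#' @export
corpus <- function(posts, date_range = NULL) {
  posts <- tibble::as_tibble(posts)
  missing <- setdiff(POST_FIELDS, names(posts))
  if (length(missing) > 0) {
    stop("corpus posts missing field(s): ", paste(missing, collapse = ", "))
  }
  posts$post_id <- as.character(posts$post_id)
  posts$author_id <- as.character(posts$author_id)
  posts$platform <- as.character(posts$platform)
  posts$text <- as.character(posts$text)
  if (anyDuplicated(posts$post_id)) {
    stop("duplicate post_id in corpus: ",
         posts$post_id[duplicated(posts$post_id)][1])
  }
  bad <- !posts$platform %in% PLATFORMS
  if (any(bad)) {
    stop("unknown platform in record ", which(bad)[1], ": ",
         posts$platform[which(bad)[1]])
  }
  if (!inherits(posts$timestamp, "POSIXct")) {
    stop("timestamp column must be POSIXct (UTC)")
  }
  attr(posts$timestamp, "tzone") <- "UTC"
  if (is.null(date_range)) {
    date_range <- if (nrow(posts) > 0) {
      range(as.Date(posts$timestamp, tz = "UTC"))
    } else {
      as.Date(c(NA, NA))
    }
  }
  date_range <- as.Date(date_range)
  if (nrow(posts) > 0) {
    d <- as.Date(posts$timestamp, tz = "UTC")
    if (any(d < date_range[1] | d > date_range[2])) {
      stop("post timestamps fall outside the corpus date_range")
    }
  }
  structure(list(posts = posts, date_range = date_range), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d posts, %d authors, %s to %s\n",
              nrow(x$posts), length(unique(x$posts$author_id)),
              format(x$date_range[1]), format(x$date_range[2])))
  invisible(x)
}

#' Number of posts in a corpus
#' @param x A `corpus`.
#' @return Integer post count.
#' @export
n_posts <- function(x) {
  stopifnot(inherits(x, "corpus"))
  nrow(x$posts)
}

parse_timestamp <- function(x) {
  # returns NA (rather than erroring) for unparseable entries so callers
  # can report the offending record number
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Read a corpus of posts from JSON Lines or CSV
#'
#' JSON Lines is the canonical on-disk format: one JSON object per line with
#' fields `post_id`, `author_id`, `platform`, `timestamp`, `text`. CSV is
#' supported with the same columns in that order. Timestamps are ISO-8601
#' and interpreted as UTC. Malformed records are an error naming the record
#' number, never silently dropped.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A [corpus()].
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("empty corpus file: ", path)
      return(empty_corpus())
    }
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("record ", i,
                                               ": invalid JSON (", conditionMessage(e), ")",
                                               call. = FALSE))
      miss <- setdiff(POST_FIELDS, names(rec))
      if (length(miss) > 0) {
        stop("record ", i, ": missing field(s) ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      rec[POST_FIELDS]
    })
    posts <- tibble::tibble(
      post_id = vapply(recs, function(r) as.character(r$post_id), ""),
      author_id = vapply(recs, function(r) as.character(r$author_id), ""),
      platform = vapply(recs, function(r) as.character(r$platform), ""),
      timestamp_raw = vapply(recs, function(r) as.character(r$timestamp), ""),
      text = vapply(recs, function(r) as.character(r$text), "")
    )
  } else {
    df <- read.csv(path, colClasses = "character")
    if (nrow(df) == 0) {
      warning("empty corpus file: ", path)
      return(empty_corpus())
    }
    miss <- setdiff(POST_FIELDS, names(df))
    if (length(miss) > 0) {
      stop("csv missing column(s): ", paste(miss, collapse = ", "))
    }
    posts <- tibble::tibble(
      post_id = df$post_id, author_id = df$author_id,
      platform = df$platform, timestamp_raw = df$timestamp, text = df$text
    )
  }
  ts <- parse_timestamp(posts$timestamp_raw)
  if (anyNA(ts)) {
    stop("record ", which(is.na(ts))[1], ": unparseable timestamp '",
         posts$timestamp_raw[which(is.na(ts))[1]], "'")
  }
  posts$timestamp <- ts
  posts$timestamp_raw <- NULL
  corpus(posts)
}

empty_corpus <- function() {
  corpus(tibble::tibble(
    post_id = character(), author_id = character(), platform = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"), text = character()
  ))
}

#' Write a corpus to JSON Lines or CSV
#'
#' Inverse of [read_posts()]: field values round-trip byte-stably
#' (timestamps serialized as ISO-8601 UTC).
#'
#' @param x A `corpus`.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(x, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format)
  df <- x$posts
  out <- data.frame(
    post_id = df$post_id, author_id = df$author_id, platform = df$platform,
    timestamp = format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    text = df$text, stringsAsFactors = FALSE
  )
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, "")
    writeLines(lines, path)
  } else {
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Load a subtopic dictionary from a plain-text word list
#'
#' One term per line, or comma-separated; case arbitrary on disk. Entries
#' are lowercased, trimmed, and deduplicated preserving first-occurrence
#' order. Multi-word entries (at most two words, e.g. "health care",
#' "reaction allergy") are matched downstream as adjacent token bigrams.
#'
#' @param path File path to the word list.
#' @param name Subtopic name; defaults to the file name without extension.
#' @return A `subtopic_dictionary`: list with `name` and `entries`.
#' @export
load_dictionary <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  entries <- unlist(strsplit(lines, ","), use.names = FALSE)
  entries <- trimws(tolower(entries))
  entries <- gsub("\\s+", " ", entries)
  entries <- entries[nzchar(entries)]
  entries <- entries[!duplicated(entries)]
  if (length(entries) == 0) stop("dictionary is empty: ", path)
  nwords <- lengths(strsplit(entries, " ", fixed = TRUE))
  if (any(nwords > 2)) {
    stop("dictionary entries must be 1-2 words; offending entry: '",
         entries[nwords > 2][1], "'")
  }
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  structure(list(name = name, entries = entries),
            class = "subtopic_dictionary")
}

#' @export
print.subtopic_dictionary <- function(x, ...) {
  cat(sprintf("<subtopic_dictionary> %s: %d entries (%s, ...)\n", x$name,
              length(x$entries), paste(head(x$entries, 4), collapse = ", ")))
  invisible(x)
}

#' Load the packaged subtopic dictionaries
#'
#' The four curated dictionaries (lifestyle, symptoms, treatments,
#' side_effects) shipped with the package, as used to tag posts about
#' Crohn's disease and its treatments.
#'
#' @param names Which dictionaries to load; default all four.
#' @return Named list of `subtopic_dictionary` objects.
#' @export
packaged_dictionaries <- function(names = SUBTOPIC_NAMES) {
  names <- match.arg(names, SUBTOPIC_NAMES, several.ok = TRUE)
  out <- lapply(names, function(nm) {
    load_dictionary(system.file("extdata", "dictionaries",
                                paste0(nm, ".txt"), package = "infodem"),
                    name = nm)
  })
  setNames(out, names)
}

#' Construct or load a sentiment lexicon
#'
#' A lexicon is two disjoint nonempty sets of lowercase polarity words.
#' `load_lexicon()` reads the two plain-text lists (newline- or
#' comma-separated); `packaged_lexicon()` returns the small generic
#' stand-in lexicon shipped with the package. Any external plain word list
#' (e.g. a subjectivity-clue lexicon) can be dropped in via
#' `load_lexicon()`.
#'
#' @param positive,negative Character vectors or file paths of polarity words.
#' @return A `sentiment_lexicon`: list with `positive` and `negative`.
#' @export
sentiment_lexicon <- function(positive, negative) {
  positive <- unique(tolower(trimws(positive)))
  negative <- unique(tolower(trimws(negative)))
  positive <- positive[nzchar(positive)]
  negative <- negative[nzchar(negative)]
  if (length(positive) == 0 || length(negative) == 0) {
    stop("lexicon polarity lists must be nonempty")
  }
  shared <- intersect(positive, negative)
  if (length(shared) > 0) {
    stop("lexicon lists overlap: ", paste(head(shared, 3), collapse = ", "))
  }
  structure(list(positive = positive, negative = negative),
            class = "sentiment_lexicon")
}

read_wordlist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  w <- unlist(strsplit(readLines(path, warn = FALSE), ","), use.names = FALSE)
  w <- trimws(w)
  w[nzchar(w)]
}

#' @rdname sentiment_lexicon
#' @param positive_path,negative_path Paths to plain-text word lists.
#' @export
load_lexicon <- function(positive_path, negative_path) {
  sentiment_lexicon(read_wordlist(positive_path), read_wordlist(negative_path))
}

#' @rdname sentiment_lexicon
#' @export
packaged_lexicon <- function() {
  load_lexicon(
    system.file("extdata", "lexicon", "positive_synthetic.txt",
                package = "infodem"),
    system.file("extdata", "lexicon", "negative_synthetic.txt",
                package = "infodem")
  )
}

#' Read a paired-ratings file
#'
#' A two-column CSV (`rater_a`, `rater_b`), one post per row, each value in
#' the Likert score set (default -1, 0, 1). Used for the rater-agreement
#' stage.
#'
#' @param path CSV path.
#' @return A tibble with integer columns `rater_a`, `rater_b`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (nrow(df) == 0) stop("ratings file is empty: ", path)
  if (!all(c("rater_a", "rater_b") %in% names(df))) {
    stop("ratings file must have columns rater_a, rater_b")
  }
  tibble::tibble(rater_a = as.integer(df$rater_a),
                 rater_b = as.integer(df$rater_b))
}
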