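# Small in-code fixtures shared across test files.

make_posts <- function(ids, authors, texts,
                       days = rep("2014-03-01", length(ids)),
                       platform = "facebook") {
  ts <- if (length(ids) == 0) {
    as.POSIXct(character(), tz = "UTC")
  } else {
    as.POSIXct(paste(days, "12:00:00"), tz = "UTC")
  }
  tibble::tibble(
    post_id = ids, author_id = authors, platform = platform,
    timestamp = ts, text = texts
  )
}

make_corpus <- function(ids, authors, texts, ...) {
  corpus(make_posts(ids, authors, texts, ...))
}

write_jsonl_fixture <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path)
  path
}

expert_cells <- rbind(c(62, 17, 5),
                      c(22, 40, 16),
                      c(11, 13, 75))

toy_lexicon <- function() {
  sentiment_lexicon(c("great", "better", "relief"),
                    c("awful", "worse", "bad"))
}
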