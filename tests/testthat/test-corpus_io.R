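jsonl_line <- function(id, author = "a1", platform = "facebook",
                       ts = "2014-03-01T10:00:00", text = "hello world") {
  jsonlite::toJSON(list(post_id = id, author_id = author, platform = platform,
                        timestamp = ts, text = text), auto_unbox = TRUE)
}

test_that("read_posts parses JSONL preserving ids and order", {
  path <- write_jsonl_fixture(c(jsonl_line("p1"), jsonl_line("p2"),
                                jsonl_line("p3", text = "second post")))
  cp <- read_posts(path)
  expect_s3_class(cp, "corpus")
  expect_equal(n_posts(cp), 3)
  expect_equal(cp$posts$post_id, c("p1", "p2", "p3"))
  expect_equal(cp$posts$text[3], "second post")
  expect_equal(attr(cp$posts$timestamp, "tzone"), "UTC")
})

test_that("write_posts / read_posts round-trips byte-stable field values", {
  cp <- make_corpus(c("x1", "x2"), c("a1", "a2"),
                    c("It's GREAT, really!", "plain text"),
                    days = c("2013-01-05", "2013-02-10"))
  for (fmt in c("jsonl", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_posts(cp, path, format = fmt)
    back <- read_posts(path, format = fmt)
    expect_identical(back$posts$post_id, cp$posts$post_id)
    expect_identical(back$posts$text, cp$posts$text)
    expect_identical(back$posts$author_id, cp$posts$author_id)
    expect_equal(back$posts$timestamp, cp$posts$timestamp)
  }
})

test_that("malformed records are rejected with the record number", {
  broken <- c(jsonl_line("p1"),
              jsonlite::toJSON(list(post_id = "p2", author_id = "a1",
                                    platform = "facebook",
                                    timestamp = "2014-03-01T10:00:00"),
                               auto_unbox = TRUE))
  expect_error(read_posts(write_jsonl_fixture(broken)), "record 2.*text")

  badts <- c(jsonl_line("p1"), jsonl_line("p2", ts = "not-a-date"))
  expect_error(read_posts(write_jsonl_fixture(badts)), "record 2.*timestamp")
})

test_that("empty corpus file yields an empty corpus with a warning", {
  path <- write_jsonl_fixture(character())
  expect_warning(cp <- read_posts(path), "empty")
  expect_equal(n_posts(cp), 0)
})

test_that("corpus invariants are enforced", {
  posts <- make_posts(c("p1", "p1"), c("a", "b"), c("x", "y"))
  expect_error(corpus(posts), "duplicate post_id")
  posts2 <- make_posts("p1", "a", "x", days = "2014-03-01")
  expect_error(corpus(posts2, date_range = as.Date(c("2015-01-01",
                                                     "2015-12-31"))),
               "outside")
  posts3 <- make_posts("p1", "a", "x")
  posts3$platform <- "myspace"
  expect_error(corpus(posts3), "platform")
})

test_that("load_dictionary lowercases, dedupes and keeps order", {
  path <- tempfile()
  writeLines(c("Smoke", "smoke"), path)
  d <- load_dictionary(path)
  expect_equal(d$entries, "smoke")

  writeLines(c("Coffee, WINE", "milk"), path)
  d2 <- load_dictionary(path, name = "lifestyle")
  expect_equal(d2$entries, c("coffee", "wine", "milk"))

  writeLines(character(), path)
  expect_error(load_dictionary(path), "empty")

  writeLines("one two three", path)
  expect_error(load_dictionary(path), "1-2 words")
})

test_that("packaged dictionaries match the curated subtopic word lists", {
  dicts <- packaged_dictionaries()
  expect_named(dicts, c("lifestyle", "symptoms", "treatments",
                        "side_effects"))
  expect_equal(dicts$side_effects$entries,
               c("complications", "effect", "lupus", "reaction allergy",
                 "skin"))
  expect_length(dicts$lifestyle$entries, 23)
  expect_length(dicts$symptoms$entries, 53)
  expect_length(dicts$treatments$entries, 69)
  expect_true(all(c("infliximab", "remicade", "rafton", "remedy",
                    "resection", "health care") %in%
                    dicts$treatments$entries))
  expect_true(all(c("tnf", "map", "cell") %in% dicts$lifestyle$entries))
  # all rows disjoint, lowercase, 1-2 words
  all_terms <- unlist(lapply(dicts, `[[`, "entries"))
  expect_equal(anyDuplicated(all_terms), 0)
  expect_identical(all_terms, tolower(all_terms))
})

test_that("sentiment lexicon rejects overlapping or empty lists", {
  expect_error(sentiment_lexicon(c("good", "odd"), c("bad", "odd")),
               "overlap")
  expect_error(sentiment_lexicon(character(), "bad"), "nonempty")
  lex <- packaged_lexicon()
  expect_gt(length(lex$positive), 0)
  expect_gt(length(lex$negative), 0)
  expect_length(intersect(lex$positive, lex$negative), 0)
  # lexicon stays disjoint from dictionary terms so generated ground truth
  # is exactly recoverable
  dict_terms <- unlist(lapply(packaged_dictionaries(), `[[`, "entries"))
  expect_length(intersect(c(lex$positive, lex$negative), dict_terms), 0)
})

test_that("read_ratings reads two-column Likert CSVs", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("rater_a,rater_b", "-1,0", "1,1"), path)
  r <- read_ratings(path)
  expect_equal(r$rater_a, c(-1L, 1L))
  expect_equal(r$rater_b, c(0L, 1L))
  writeLines("rater_a,rater_b", path)
  expect_error(read_ratings(path), "empty")
})

test_that("the packaged expert ratings fixture realizes the expert table", {
  path <- system.file("extdata", "ratings", "expert_ratings.csv",
                      package = "infodem")
  m <- build_confusion_matrix(read_ratings(path))
  expect_equal(unname(m$cells), unname(expert_table()$cells))
  expect_equal(m$N, 261)
})
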