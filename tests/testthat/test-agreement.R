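# Brute-force oracles: elementwise double loops over cells.
brute_weighted_po <- function(cells, w) {
  s <- 0
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    s <- s + w[i, j] * cells[i, j]
  }
  list(numerator = s, po = s / sum(cells))
}
brute_weighted_pe <- function(cells, w) {
  r <- rowSums(cells)
  cc <- colSums(cells)
  s <- 0
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    s <- s + w[i, j] * r[i] * cc[j]
  }
  unname(s / sum(cells)^2)
}

test_that("build_confusion_matrix cross-tabulates and validates pairs", {
  pairs <- generate_rating_pairs(expert_cells, seed = 2)
  expect_equal(nrow(pairs), 261)
  m <- build_confusion_matrix(pairs)
  expect_equal(unname(m$cells), expert_cells)
  expect_equal(m$N, 261)
  m1 <- build_confusion_matrix(data.frame(rater_a = 1, rater_b = 1))
  expect_equal(m1$cells["1", "1"], 1L)
  expect_equal(sum(m1$cells), 1L)
  expect_error(build_confusion_matrix(data.frame(rater_a = c(1, 2),
                                                 rater_b = c(0, 0))),
               "pair 2")
  expect_error(build_confusion_matrix(data.frame(rater_a = numeric(),
                                                 rater_b = numeric())),
               "no rating pairs")
})

test_that("cross-tabulation round-trips arbitrary matrices", {
  set.seed(7)
  for (i in 1:10) {
    cells <- matrix(rpois(9, 5), 3)
    if (sum(cells) == 0) cells[1, 1] <- 1
    pairs <- generate_rating_pairs(cells, seed = i)
    expect_equal(unname(build_confusion_matrix(pairs)$cells), cells)
  }
  expect_equal(nrow(generate_rating_pairs(matrix(0, 3, 3))), 0)
  conc <- generate_rating_pairs(diag(3))
  expect_equal(nrow(conc), 3)
  expect_true(all(conc$rater_a == conc$rater_b))
  expect_error(generate_rating_pairs(matrix(0.5, 3, 3)), "integer")
})

test_that("quadratic weights follow 1 - ((i-j)/(k-1))^2", {
  expect_equal(quadratic_weights(3),
               rbind(c(1, 0.75, 0), c(0.75, 1, 0.75), c(0, 0.75, 1)))
  expect_equal(quadratic_weights(2), diag(2))  # reduces to unweighted
  for (k in 2:6) {
    w <- quadratic_weights(k)
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(1, k))
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(quadratic_weights(1), ">= 2")
})

test_that("expert-table agreement reproduces the published statistics", {
  m <- expert_table()
  w <- quadratic_weights(3)
  oa <- weighted_agreement(m, w)
  # numerator decomposes as 177 exact + 0.75 * 68 one-step disagreements
  expect_equal(oa$numerator, 177 + 0.75 * 68)
  expect_equal(oa$numerator, 228)
  expect_equal(oa$P_o_w, 228 / 261)
  expect_equal(round(100 * oa$P_o_w, 2), 87.36)
  bf <- brute_weighted_po(m$cells, w)
  expect_equal(oa$numerator, bf$numerator)

  pe <- expected_weighted_agreement(m, w)
  expect_equal(pe, 43725 / 68121)          # = sum w_ij * r_i * c_j / N^2
  expect_equal(pe, brute_weighted_pe(m$cells, w))

  k <- weighted_kappa(m, "quadratic")
  expect_equal(k$kappa, 5261 / 8132)
  expect_equal(k$kappa_4dp, 0.6470)
  expect_equal(k$label, "substantial")

  # identity weights give raw percent agreement, a different (lower) figure
  raw <- weighted_agreement(m, identity_weights(3))
  expect_equal(raw$numerator, 177)
  expect_equal(raw$P_o_w, 177 / 261)
})

test_that("expected agreement degenerate and symmetric cases", {
  w <- quadratic_weights(3)
  uni <- as_confusion_matrix(matrix(29, 3, 3))
  expect_equal(expected_weighted_agreement(uni, w), 6 / 9)
  onecell <- as_confusion_matrix(rbind(c(0, 0, 7), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(expected_weighted_agreement(onecell, w), w[1, 3])
})

test_that("kappa limits: perfect concordance, uniform independence", {
  conc <- as_confusion_matrix(diag(c(5, 9, 3)))
  expect_equal(weighted_kappa(conc)$kappa, 1)
  expect_equal(weighted_agreement(conc, quadratic_weights(3))$P_o_w, 1)
  uni <- as_confusion_matrix(matrix(29, 3, 3))
  expect_equal(weighted_kappa(uni)$kappa, 0)
  # corners only: zero weighted agreement
  corners <- as_confusion_matrix(rbind(c(0, 0, 4), c(0, 0, 0), c(6, 0, 0)))
  expect_equal(weighted_agreement(corners, quadratic_weights(3))$P_o_w, 0)
})

test_that("kappa is 1 iff off-diagonal mass is zero", {
  set.seed(11)
  for (i in 1:20) {
    cells <- matrix(rpois(9, 4), 3)
    cells[1, 1] <- cells[1, 1] + 1
    k <- weighted_kappa(as_confusion_matrix(cells))$kappa
    if (sum(cells) == sum(diag(cells))) expect_equal(k, 1)
    else expect_lt(k, 1)
  }
})

test_that("kappa is 0 under statistical independence for any scheme", {
  r <- c(2, 3, 5)
  cc <- c(4, 1, 5)
  cells <- outer(r, cc)                    # cells proportional to r_i * c_j
  m <- as_confusion_matrix(cells)
  for (scheme in c("quadratic", "linear", "unweighted")) {
    expect_equal(weighted_kappa(m, scheme)$kappa, 0)
  }
})

test_that("two-level quadratic kappa equals unweighted Cohen's kappa", {
  set.seed(3)
  for (i in 1:10) {
    cells <- matrix(rpois(4, 6) + 1, 2)
    m <- as_confusion_matrix(cells, scores = c(0, 1))
    kq <- weighted_kappa(m, "quadratic")$kappa
    ku <- weighted_kappa(m, "unweighted")$kappa
    expect_equal(kq, ku)
  }
})

test_that("degenerate marginals make kappa undefined", {
  m <- as_confusion_matrix(rbind(c(9, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_error(weighted_kappa(m), "undefined|degenerate")
})

test_that("rating proportions match the published marginal percentages", {
  p <- rating_proportions(expert_table())
  # rows: senior gastroenterologist
  expect_equal(unname(p$rater_a), c(38, 30, 32))
  # columns: computer-science expert; neutral 27%
  expect_equal(unname(p$rater_b["neu"]), 27)
  uni <- as_confusion_matrix(matrix(29, 3, 3))
  expect_equal(unname(rating_proportions(uni)$rater_a), c(33, 33, 33))
})

test_that("interpretation bands follow the Landis-Koch convention", {
  expect_equal(interpret_kappa(0.6470), "substantial")
  expect_equal(interpret_kappa(1.0), "almost perfect")
  expect_equal(interpret_kappa(0.15), "slight")
  expect_equal(interpret_kappa(-0.2), "poor")
  expect_equal(interpret_kappa(0.205), "fair")
  expect_equal(interpret_kappa(0.45), "moderate")
  expect_error(interpret_kappa(1.2), "exceed")
})

test_that("confusion matrices round-trip through CSV", {
  m <- expert_table()
  path <- tempfile(fileext = ".csv")
  write_confusion_matrix(m, path)
  back <- read_confusion_matrix(path)
  expect_equal(back$cells, m$cells)
  expect_equal(back$scores, m$scores)
})
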