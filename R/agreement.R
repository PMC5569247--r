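#' Cross-tabulate two raters' Likert scores
#'
#' Builds the k x k contingency table of paired ratings: rows index the
#' first rater's score, columns the second rater's, over the ordered level
#' set `scores` (default the 3-point Likert scale -1, 0, 1).
#'
#' @param pairs Two-column data frame / tibble (rater_a, rater_b) or list
#'   of length-2 vectors.
#' @param scores Ordered score levels.
#' @return A `confusion_matrix`: list with `cells` (k x k integer matrix,
#'   dimnames = scores), `scores`, and `N`.
#' @export
build_confusion_matrix <- function(pairs, scores = c(-1, 0, 1)) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(rater_a = vapply(pairs, `[[`, 0, 1),
                        rater_b = vapply(pairs, `[[`, 0, 2))
  }
  if (nrow(pairs) == 0) stop("no rating pairs supplied")
  a <- pairs[[1]]
  b <- pairs[[2]]
  bad <- which(!(a %in% scores) | !(b %in% scores))
  if (length(bad) > 0) {
    stop("rating outside score set at pair ", bad[1], ": (",
         a[bad[1]], ", ", b[bad[1]], ")")
  }
  cells <- table(factor(a, levels = scores), factor(b, levels = scores))
  cells <- matrix(as.integer(cells), nrow = length(scores),
                  dimnames = list(as.character(scores), as.character(scores)))
  structure(list(cells = cells, scores = scores, N = nrow(pairs)),
            class = "confusion_matrix")
}

#' Wrap an existing k x k count matrix as a confusion matrix
#'
#' @param cells k x k nonnegative integer matrix (rows = rater A).
#' @param scores Ordered score levels, length k.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(cells, scores = c(-1, 0, 1)) {
  cells <- as.matrix(cells)
  if (nrow(cells) != length(scores) || ncol(cells) != length(scores)) {
    stop("cells must be ", length(scores), " x ", length(scores))
  }
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers")
  }
  cells <- matrix(as.integer(cells), nrow = length(scores),
                  dimnames = list(as.character(scores), as.character(scores)))
  structure(list(cells = cells, scores = scores, N = sum(cells)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d x %d, N = %d\n",
              nrow(x$cells), ncol(x$cells), x$N))
  print(x$cells)
  invisible(x)
}

#' Quadratic (squared-distance) agreement weights
#'
#' w_ij = 1 - ((i-j)/(k-1))^2 for ordinal categories i, j in 1..k: full
#' credit on the diagonal, partial credit decreasing with the squared
#' category distance. For k = 3 the matrix has diagonal 1, adjacent cells
#' 0.75 and the two extreme corners 0; for k = 2 it reduces to the
#' unweighted identity.
#'
#' @param k Number of ordered categories (>= 2).
#' @return k x k symmetric weight matrix with unit diagonal.
#' @export
quadratic_weights <- function(k) {
  if (k < 2) stop("k must be >= 2")
  i <- seq_len(k)
  outer(i, i, function(a, b) 1 - ((a - b) / (k - 1))^2)
}

#' Linear agreement weights
#'
#' w_ij = 1 - |i-j|/(k-1).
#'
#' @inheritParams quadratic_weights
#' @return k x k weight matrix.
#' @export
linear_weights <- function(k) {
  if (k < 2) stop("k must be >= 2")
  i <- seq_len(k)
  outer(i, i, function(a, b) 1 - abs(a - b) / (k - 1))
}

#' Identity (unweighted) agreement weights
#'
#' @inheritParams quadratic_weights
#' @return k x k identity matrix; weighted agreement under these weights is
#'   raw percent agreement.
#' @export
identity_weights <- function(k) {
  if (k < 2) stop("k must be >= 2")
  diag(k)
}

weight_matrix <- function(scheme, k) {
  switch(scheme,
         quadratic = quadratic_weights(k),
         linear = linear_weights(k),
         unweighted = identity_weights(k),
         stop("unknown weight scheme: ", scheme))
}

#' Weighted observed agreement
#'
#' The weighted agreement numerator is the sum over cells of w_ij * n_ij;
#' dividing by N gives the weighted observed agreement P_o(w). With
#' quadratic weights on a 3-level table, exact agreements count fully and
#' one-step disagreements count 0.75.
#'
#' @param m A `confusion_matrix`.
#' @param w Weight matrix matching m's dimensions.
#' @return List: `numerator` (sum of w_ij * n_ij) and `P_o_w` (in [0,1]).
#' @export
weighted_agreement <- function(m, w) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!all(dim(w) == dim(m$cells))) stop("weight matrix dimension mismatch")
  if (m$N == 0) stop("empty confusion matrix")
  num <- sum(w * m$cells)
  list(numerator = num, P_o_w = num / m$N)
}

#' Weighted expected (chance) agreement
#'
#' P_e(w) = sum over cells of w_ij * r_i * c_j / N^2, where r and c are the
#' row and column marginals: the weighted agreement two independent raters
#' with these marginal rating distributions would reach by chance.
#'
#' @inheritParams weighted_agreement
#' @return P_e_w in [0,1].
#' @export
expected_weighted_agreement <- function(m, w) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!all(dim(w) == dim(m$cells))) stop("weight matrix dimension mismatch")
  if (m$N == 0) stop("empty confusion matrix")
  r <- rowSums(m$cells)
  cc <- colSums(m$cells)
  sum(w * outer(r, cc)) / m$N^2
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement kappa = (P_o(w) - P_e(w)) / (1 - P_e(w))
#' under the chosen weight scheme. The default quadratic scheme discounts
#' disagreements by squared category distance (the "square weighted"
#' kappa, w2K). Computation is at full precision; `kappa_4dp` carries the
#' conventional 4-decimal display rounding.
#'
#' @param m A `confusion_matrix`.
#' @param scheme `"quadratic"` (default), `"linear"`, or `"unweighted"`.
#' @return A `kappa_result`: weight_scheme, weights, numerator, P_o_w,
#'   P_e_w, kappa, kappa_4dp, label (Landis-Koch band).
#' @export
weighted_kappa <- function(m, scheme = c("quadratic", "linear", "unweighted")) {
  stopifnot(inherits(m, "confusion_matrix"))
  scheme <- match.arg(scheme)
  w <- weight_matrix(scheme, nrow(m$cells))
  oa <- weighted_agreement(m, w)
  pe <- expected_weighted_agreement(m, w)
  if (1 - pe <= .Machine$double.eps) {
    stop("degenerate marginals: expected agreement is 1, kappa undefined")
  }
  kappa <- (oa$P_o_w - pe) / (1 - pe)
  structure(list(weight_scheme = scheme, weights = w,
                 numerator = oa$numerator, P_o_w = oa$P_o_w, P_e_w = pe,
                 kappa = kappa, kappa_4dp = round_half_up(kappa, 4),
                 label = interpret_kappa(kappa)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s weighted Cohen's kappa\n", x$weight_scheme))
  cat(sprintf("  weighted agreement: %.4g / N  (P_o_w = %.2f%%)\n",
              x$numerator, 100 * x$P_o_w))
  cat(sprintf("  expected agreement: P_e_w = %.4f\n", x$P_e_w))
  cat(sprintf("  kappa = %.4f  (%s)\n", x$kappa_4dp, x$label))
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Marginal rating proportions per rater
#'
#' Each rater's marginal counts divided by N, expressed as integer
#' percentages (half-up rounding), ordered positive/neutral/negative.
#'
#' @param m A `confusion_matrix` over scores -1, 0, 1 (or any ordered
#'   low-to-high levels; "positive" is the highest level).
#' @return List of two named vectors `rater_a`, `rater_b`, each with
#'   elements pos, neu, neg (integer percent).
#' @export
rating_proportions <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$N == 0) stop("empty confusion matrix")
  if (nrow(m$cells) != 3) stop("proportions defined for 3-level scales")
  pct <- function(counts) {
    p <- round_half_up(100 * counts / m$N)
    # levels are ordered low-to-high: (neg, neu, pos)
    c(pos = unname(p[3]), neu = unname(p[2]), neg = unname(p[1]))
  }
  list(rater_a = pct(rowSums(m$cells)), rater_b = pct(colSums(m$cells)))
}

#' Landis-Koch interpretation of a kappa value
#'
#' Conventional verbal bands: below 0 poor; 0-0.20 slight; 0.21-0.40 fair;
#' 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#'
#' @param kappa A kappa value (<= 1).
#' @return Interpretation label string.
#' @export
interpret_kappa <- function(kappa) {
  if (kappa > 1 + 1e-12) stop("kappa cannot exceed 1")
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Write / read a confusion matrix as CSV
#'
#' A k x k CSV with a header row of score labels and score labels in the
#' first column.
#'
#' @param m A `confusion_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (write) or a `confusion_matrix` (read).
#' @export
write_confusion_matrix <- function(m, path) {
  stopifnot(inherits(m, "confusion_matrix"))
  df <- data.frame(score = rownames(m$cells), m$cells, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_matrix
#' @export
read_confusion_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  scores <- as.numeric(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  as_confusion_matrix(cells, scores = scores)
}

#' Full rater-agreement report from a ratings file
#'
#' Convenience wrapper: reads a paired-ratings CSV, builds the confusion
#' matrix, and prints matrix, weighted observed agreement (plus raw percent
#' agreement, which differs from it), expected agreement, kappa, and its
#' interpretation.
#'
#' @param ratings_path CSV with columns rater_a, rater_b.
#' @param scheme Weight scheme, default quadratic.
#' @param scores Likert levels, default c(-1, 0, 1).
#' @return The `kappa_result`, invisibly; also prints the report.
#' @export
agreement_report <- function(ratings_path, scheme = "quadratic",
                             scores = c(-1, 0, 1)) {
  ratings <- read_ratings(ratings_path)
  m <- build_confusion_matrix(ratings, scores = scores)
  res <- weighted_kappa(m, scheme = scheme)
  raw <- weighted_agreement(m, identity_weights(nrow(m$cells)))
  print(m)
  cat(sprintf("raw percent agreement: %.2f%% (%d/%d)\n",
              100 * raw$P_o_w, as.integer(raw$numerator), m$N))
  print(res)
  props <- rating_proportions(m)
  cat(sprintf("rater A pos/neu/neg: %d%%/%d%%/%d%%; rater B: %d%%/%d%%/%d%%\n",
              props$rater_a["pos"], props$rater_a["neu"], props$rater_a["neg"],
              props$rater_b["pos"], props$rater_b["neu"], props$rater_b["neg"]))
  invisible(res)
}
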