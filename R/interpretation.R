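#' Influence of each first-stage filter by ablation
#'
#' Each filter's activation map is zeroed in turn (no retraining, no
#' renormalization) and the accuracy metric is recomputed on the same test
#' set; influence = baseline metric - ablated metric. Filters are ranked by
#' decreasing influence.
#'
#' @param model trained `str_cnn` with >= 2 filters.
#' @param X test design matrix (or `str_dataset`).
#' @param y test targets/labels on the model's training scale.
#' @return data frame: `filter`, `baseline`, `ablated`, `influence`,
#'   `rank`; also `log2_influence` with non-positive influences floored at
#'   `floor_eps` before the log.
#' @param floor_eps floor applied to non-positive influences before log2.
#' @export
filter_influence <- function(model, X, y, floor_eps = 1e-6) {
  if (inherits(X, "str_dataset")) { y <- X$y; X <- X$X }
  s <- model$spec
  if (s$n_filters < 2) stop("need at least 2 first-stage filters")
  metric <- function(pred) {
    if (s$task == "regression") eval_regression(pred, y)$value
    else eval_classification(pred, y)$value
  }
  baseline <- metric(predict(model, X, type = "raw"))
  abl <- vapply(seq_len(s$n_filters), function(f)
    metric(predict(model, X, type = "raw", ablate = f)), numeric(1))
  # a constant ablated predictor has no rank metric; score it 0
  abl[is.na(abl)] <- 0
  infl <- baseline - abl
  data.frame(filter = seq_len(s$n_filters), baseline = baseline,
             ablated = abl, influence = infl,
             log2_influence = log2(pmax(infl, floor_eps)),
             rank = rank(-infl, ties.method = "first"))
}

#' Chance-level influence threshold from repeated retraining
#'
#' Given the accuracies of independently retrained models, computes the
#' t-based 95% confidence interval of their mean and the threshold
#' tau = log2(CI length / 2): influences above tau exceed what mere
#' retraining variability produces.
#'
#' @param accuracies numeric vector (>= 2 values; the reference protocol
#'   uses 10 retrainings).
#' @param conf confidence level (default 0.95).
#' @return list of class `influence_threshold`: `accuracies`, `ci`
#'   (lower, upper), `ci_length`, `threshold` (`NA` with a reason when the
#'   accuracies have zero variance).
#' @export
influence_threshold <- function(accuracies, conf = 0.95) {
  n <- length(accuracies)
  if (n < 2) stop("need at least 2 accuracies")
  m <- mean(accuracies); s <- stats::sd(accuracies)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  len <- 2 * half
  structure(list(accuracies = accuracies, ci = c(m - half, m + half),
                 ci_length = len,
                 threshold = if (len > 0) log2(len / 2) else NA_real_,
                 note = if (len > 0) NA_character_ else
                   "zero variance: CI length 0, threshold undefined"),
            class = "influence_threshold")
}

#' @export
print.influence_threshold <- function(x, ...) {
  cat(sprintf("influence_threshold: CI [%.4g, %.4g], length %.4g, tau = %s\n",
              x$ci[1], x$ci[2], x$ci_length,
              ifelse(is.na(x$threshold), "undefined",
                     formatC(x$threshold, digits = 4))))
  invisible(x)
}

#' Build a position weight matrix from aligned sequences
#'
#' Column-wise base frequencies with a pseudocount, plus the log-odds form
#' against a uniform background.
#'
#' @param sequences equal-length character vector (>= 1) over ACGT.
#' @param pseudocount added to every base count (default 0.5).
#' @return list of class `pwm`: `prob` (4 x W, rows A/C/G/T, columns sum to
#'   1), `logodds` (log2 prob/0.25), `n`, `pseudocount`.
#' @export
build_pwm <- function(sequences, pseudocount = 0.5) {
  if (!length(sequences)) stop("need at least one sequence")
  W <- nchar(sequences[1])
  if (any(nchar(sequences) != W)) stop("ragged input: unequal lengths")
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  nrow = length(sequences), byrow = TRUE)
  counts <- vapply(seq_len(W), function(j)
    tabulate(match(chars[, j], c("A", "C", "G", "T")), 4L),
    numeric(4))
  counts <- counts + pseudocount
  prob <- sweep(counts, 2, colSums(counts), `/`)
  dimnames(prob) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(prob = prob, logodds = log2(prob / 0.25),
                 n = length(sequences), pseudocount = pseudocount),
            class = "pwm")
}

#' Maximal sliding-window score of a scorer over a sequence
#'
#' The scorer is either a `pwm` (its log-odds matrix is used) or a numeric
#' 4 x w matrix (e.g. a first-layer convolution filter); the score at an
#' offset is the sum of position-wise entries selected by the sequence, `N`
#' contributing 0 (the zero-column convention); the maximum over all offsets
#' is returned.
#'
#' @param sequence character scalar, length >= scorer width.
#' @param scorer a `pwm` or a 4 x w numeric matrix (rows A/C/G/T).
#' @return numeric scalar.
#' @export
max_score_scan <- function(sequence, scorer) {
  mat <- if (inherits(scorer, "pwm")) scorer$logodds else scorer
  w <- ncol(mat)
  L <- nchar(sequence)
  if (L < w) stop("sequence shorter than scorer width")
  oh <- one_hot(sequence)
  scores <- vapply(seq_len(L - w + 1), function(o)
    sum(oh[, o:(o + w - 1)] * mat), numeric(1))
  max(scores)
}

#' Convert a first-layer filter to a 4 x w scoring matrix
#' @param model a `str_cnn`.
#' @param filter filter index.
#' @return numeric 4 x kernel_width matrix (rows A/C/G/T).
#' @export
filter_matrix <- function(model, filter) {
  k <- model$spec$kernel_width
  m <- matrix(model$weights$Wc[, filter], nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Rank correlation between filter scores and PWM scores
#'
#' Restricted to sequences carrying a PWM hit (the supplied `hit` mask, or
#' all sequences when absent), with average ranks for ties.
#'
#' @param filter_scores,pwm_scores paired per-sequence maximal scores.
#' @param hit optional logical mask of sequences with a PWM hit.
#' @return list: `rho`, `n`.
#' @export
filter_pwm_correlation <- function(filter_scores, pwm_scores, hit = NULL) {
  if (length(filter_scores) != length(pwm_scores)) stop("length mismatch")
  if (!is.null(hit)) {
    filter_scores <- filter_scores[hit]; pwm_scores <- pwm_scores[hit]
  }
  if (length(filter_scores) < 3) stop("need at least 3 paired scores")
  if (stats::sd(filter_scores) == 0 || stats::sd(pwm_scores) == 0)
    stop("constant score vector")
  list(rho = stats::cor(filter_scores, pwm_scores, method = "spearman"),
       n = length(filter_scores))
}

#' Prediction difference between a reference and a mutated window
#'
#' Delta = predict(reference) - predict(mutated), on the model's natural
#' output scale.
#'
#' @param model trained `str_cnn`.
#' @param reference,mutated equal-width window sequences.
#' @return numeric scalar.
#' @export
prediction_delta <- function(model, reference, mutated) {
  if (nchar(reference) != nchar(mutated)) stop("window width mismatch")
  X <- encode_windows(c(reference, mutated), nchar(reference))
  p <- predict(model, X)
  p[1] - p[2]
}

#' Positional impact profile by random in-silico mutagenesis
#'
#' Mutation positions are drawn uniformly over the window; at a drawn
#' position the three alternative bases are equiprobable. Prediction deltas
#' (reference - mutated) are pooled by position relative to the 3'-end
#' column (the window center) and their variance per position is reported.
#'
#' @param model trained `str_cnn`.
#' @param windows character vector of window sequences (model input width).
#' @param mutations_per_window draws per window (default 5).
#' @param seed integer seed.
#' @return data frame of class `positional_impact`: `position` (relative to
#'   the 3'-end column, 0 = the 3'-end base), `variance`, `n`.
#' @export
mutagenesis_profile <- function(model, windows, mutations_per_window = 5L,
                                seed = 1L) {
  if (!length(windows)) stop("need at least one window")
  W <- model$spec$input_width
  if (any(nchar(windows) != W)) stop("window width mismatch")
  old <- .save_rng(); on.exit(.restore_rng(old))
  nmut <- length(windows) * mutations_per_window
  widx <- rep(seq_along(windows), each = mutations_per_window)
  bases <- c("A", "C", "G", "T")
  # draws are keyed to (seed, window content), so the pooled profile is
  # exactly invariant to the order of the input windows
  pos <- integer(nmut); alt <- character(nmut)
  poly_hash <- function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 1000000007
    h
  }
  for (i in seq_along(windows)) {
    h <- poly_hash(windows[i])
    set.seed((as.integer(seed) + h) %% .Machine$integer.max)
    k <- (i - 1) * mutations_per_window + seq_len(mutations_per_window)
    pos[k] <- sample.int(W, mutations_per_window, replace = TRUE)
    rb <- substring(windows[i], pos[k], pos[k])
    alt[k] <- vapply(rb, function(b) {
      cand <- setdiff(bases, b)
      cand[sample.int(length(cand), 1)]
    }, character(1), USE.NAMES = FALSE)
  }
  mutated <- windows[widx]
  substr(mutated, pos, pos) <- alt
  # one reference prediction per window, reused across its mutations
  pref <- predict(model, encode_windows(windows, W))
  pmut <- predict(model, encode_windows(mutated, W))
  delta <- pref[widx] - pmut
  center <- (W + 1) / 2
  rel <- pos - center
  agg <- tapply(delta, rel, function(d)
    c(var = if (length(d) > 1) stats::var(d) else 0, n = length(d)))
  rel_sorted <- sort(unique(rel))
  out <- data.frame(position = rel_sorted,
                    variance = vapply(as.character(rel_sorted), function(k)
                      agg[[k]]["var"], numeric(1)),
                    n = vapply(as.character(rel_sorted), function(k)
                      agg[[k]]["n"], numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("positional_impact", "data.frame")
  out
}

#' Histogram of event positions relative to an anchor
#'
#' @param events numeric vector of offsets (e.g. variant position minus
#'   3'-end position).
#' @param breaks passed to [graphics::hist()] semantics via `cut`; default
#'   unit bins spanning the data.
#' @return data frame `offset`, `count`.
#' @export
positional_distribution <- function(events, breaks = NULL) {
  if (!length(events)) stop("empty event set")
  tab <- table(events)
  data.frame(offset = as.numeric(names(tab)), count = as.integer(tab))
}

#' Two-sample Kolmogorov-Smirnov comparison of positional samples
#'
#' @param a,b raw offset samples (>= 1 event each).
#' @return list: `statistic` (max ECDF gap), `p_value`.
#' @export
compare_positional <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
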