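# Independent brute-force oracles used across the suite. They deliberately
# share no code with the package's implementations.

# all-pairs O(n*m) window overlap
brute_overlap <- function(a, b, w = 0, same_strand = FALSE) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    if (same_strand && a$strand[i] != b$strand[j]) next
    lo <- a$start[i] - w; hi <- a$end[i] + w
    if (max(lo, b$start[j]) < min(hi, b$end[j]))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(a_idx = out[, 1], b_idx = out[, 2])
}

# Spearman rho via the explicit rank formula (average ranks)
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# AUC by exhaustive pair counting with half-credit ties
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# two-sample KS statistic as the max ECDF gap over the pooled support
naive_ks <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(vapply(g, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# maximal sliding scorer by explicit double loop over offsets/columns
naive_scan <- function(seq, mat) {
  chars <- strsplit(seq, "")[[1]]
  w <- ncol(mat); best <- -Inf
  for (o in 0:(length(chars) - w)) {
    sc <- 0
    for (j in 1:w) {
      b <- chars[o + j]
      k <- match(b, c("A", "C", "G", "T"))
      if (!is.na(k)) sc <- sc + mat[k, j]
    }
    best <- max(best, sc)
  }
  best
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 500) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(20, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), s, s + len,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small shared synthetic world, built once per test run
.world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.world_cache$w)) {
    .world_cache$w <- generate_world(
      world_spec(n_str = 800, chrom_lengths = c(chr1 = 100000,
                                                chr2 = 100000)),
      seed = 42)
    .world_cache$cov <- generate_coverage(.world_cache$w, seed = 43)
  }
  list(world = .world_cache$w, cov = .world_cache$cov)
}
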