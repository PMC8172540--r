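#' Average several coverage tracks position-wise
#'
#' Absent positions count as zero; provenance accumulates the library counts.
#'
#' @param tracks non-empty list of `coverage_track` objects over the same
#'   genome.
#' @return a `coverage_track` holding the per-position arithmetic mean.
#' @export
mean_coverage <- function(tracks) {
  if (!length(tracks)) stop("mean_coverage needs at least one track")
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$values))))
  lens <- numeric(length(chroms)); names(lens) <- chroms
  for (ch in chroms)
    lens[ch] <- max(vapply(tracks, function(t)
      if (ch %in% names(t$values)) length(t$values[[ch]]) else 0, numeric(1)))
  out <- coverage_track(lens,
                        n_libraries = sum(vapply(tracks, function(t)
                          t$n_libraries, numeric(1))),
                        quality_filter = tracks[[1]]$quality_filter)
  for (ch in chroms) {
    acc <- numeric(lens[ch])
    for (t in tracks) {
      v <- t$values[[ch]]
      if (!is.null(v)) acc[seq_along(v)] <- acc[seq_along(v)] + v
    }
    out$values[[ch]] <- acc / length(tracks)
  }
  out
}

#' Initiation signal of one STR on one strand
#'
#' The statistic is the coverage summed over the STR extended by 5 bp on each
#' side, divided by the STR length plus 10 bp:
#' \deqn{S = \sum_{p \in [start-5,\ end+5)} cov[p] \; / \; (L + 10).}
#' The fixed denominator removes the dependence of the statistic on STR
#' length that low scattered counts along the repeat body would otherwise
#' create. The window is clipped at chromosome edges but the nominal
#' denominator is retained.
#'
#' @param str one-row STR record (0-based half-open interval columns).
#' @param cov `coverage_track` for the strand being scored.
#' @param flank window extension in bp (default 5, fixing the `L + 10`
#'   denominator).
#' @return non-negative numeric scalar.
#' @export
cage_signal <- function(str, cov, flank = 5L) {
  ch <- str$chrom[1]
  v <- cov$values[[ch]]
  if (is.null(v)) return(0)
  L <- str$end[1] - str$start[1]
  lo <- max(str$start[1] - flank, 0)
  hi <- min(str$end[1] + flank, length(v))
  s <- if (hi > lo) sum(v[(lo + 1):hi]) else 0
  s / (L + 2 * flank)
}

#' Signals for many STRs at once
#'
#' Vectorised convenience over [cage_signal()].
#'
#' @param strs STR catalog data frame.
#' @param cov `coverage_track`.
#' @param flank window extension in bp.
#' @return numeric vector, one signal per row of `strs`.
#' @export
cage_signal_many <- function(strs, cov, flank = 5L) {
  out <- numeric(nrow(strs))
  for (ch in unique(strs$chrom)) {
    v <- cov$values[[ch]]
    k <- which(strs$chrom == ch)
    if (is.null(v)) { out[k] <- 0; next }
    cs <- c(0, cumsum(v))
    lo <- pmax(strs$start[k] - flank, 0)
    hi <- pmin(strs$end[k] + flank, length(v))
    out[k] <- (cs[hi + 1] - cs[lo + 1]) /
      (strs$end[k] - strs$start[k] + 2 * flank)
  }
  out
}

#' Orient an STR on both strands and attach signals
#'
#' Catalog STRs are (+)-strand normalized; each is evaluated in both
#' orientations, nearly doubling the records per class. The (-) orientation's
#' effective motif (and class key) is the reverse complement of the catalog
#' motif; its 3' end is the first catalog base. 3'-end coordinates are
#' reported 1-based.
#'
#' @param strs STR catalog data frame.
#' @param cov_plus,cov_minus strand-specific `coverage_track`s.
#' @param flank signal window extension in bp.
#' @return data frame with one row per orientation (2 per input STR):
#'   catalog columns plus `strand`, `three_prime_end` (1-based),
#'   `effective_motif`, `class_key`, `signal`.
#' @export
orient_strs <- function(strs, cov_plus, cov_minus, flank = 5L) {
  if (!nrow(strs)) {
    out <- strs
    out$three_prime_end <- numeric(0); out$effective_motif <- character(0)
    out$class_key <- character(0); out$signal <- numeric(0)
    return(out)
  }
  s_plus <- cage_signal_many(strs, cov_plus, flank)
  s_minus <- cage_signal_many(strs, cov_minus, flank)
  rc <- revcomp(strs$motif)
  plus <- strs; plus$strand <- "+"
  plus$three_prime_end <- strs$end          # 1-based last base on (+)
  plus$effective_motif <- strs$motif
  plus$class_key <- strs$motif
  plus$signal <- s_plus
  minus <- strs; minus$strand <- "-"
  minus$three_prime_end <- strs$start + 1   # 1-based first catalog base
  minus$effective_motif <- rc
  minus$class_key <- rc
  minus$signal <- s_minus
  # interleave so the two orientations of each STR are adjacent
  idx <- as.vector(rbind(seq_len(nrow(strs)), nrow(strs) + seq_len(nrow(strs))))
  out <- rbind(plus, minus)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcriptional directionality score
#'
#' \eqn{D = (S^+ - S^-) / (S^+ + S^-)}. A score of 1 (resp. -1) means
#' transcription strictly on the (+) (resp. (-)) strand; 0 means balanced
#' bidirectional transcription. Undefined (NA) when both signals are zero.
#'
#' @param s_plus,s_minus non-negative signals; vectorised.
#' @return numeric vector in `[-1, 1]`, `NA` where both inputs are zero.
#' @export
directionality <- function(s_plus, s_minus) {
  if (any(s_plus < 0) || any(s_minus < 0))
    stop("directionality needs non-negative signals")
  tot <- s_plus + s_minus
  ifelse(tot == 0, NA_real_, (s_plus - s_minus) / tot)
}

#' Per-class fraction of STRs near an anchor set, with Wilson 95% CIs
#'
#' For every class key, the fraction of oriented STRs having at least one
#' anchor interval within `w` bp, with a Wilson score 95% confidence
#' interval. Empty classes are omitted with a warning.
#'
#' @param oriented oriented STR data frame (needs `class_key` and interval
#'   columns).
#' @param anchors anchor intervals (e.g. CAGE peaks), data frame.
#' @param w window extension in bp (default 5).
#' @return data frame: `class_key`, `n`, `n_overlap`, `fraction`, `ci_lo`,
#'   `ci_hi`.
#' @export
class_peak_fraction <- function(oriented, anchors, w = 5L) {
  if (!nrow(oriented)) {
    warning("no oriented STRs supplied")
    return(data.frame(class_key = character(0), n = integer(0),
                      n_overlap = integer(0), fraction = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  }
  hits <- window_overlap(oriented, anchors, w = w)
  has <- seq_len(nrow(oriented)) %in% hits$a_idx
  keys <- sort(unique(oriented$class_key))
  res <- lapply(keys, function(k) {
    sel <- oriented$class_key == k
    n <- sum(sel); x <- sum(has[sel])
    ci <- wilson_ci(x, n)
    data.frame(class_key = k, n = n, n_overlap = x, fraction = x / n,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector `(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Overlap fraction of randomly relocated intervals
#'
#' Shuffles the STR intervals (excluding the catalog's own footprint) and
#' reports the fraction of relocated intervals having an anchor within `w`
#' bp — the chance baseline for the observed STR/anchor overlap rate.
#'
#' @param strs STR catalog data frame.
#' @param anchors anchor intervals.
#' @param genome_sizes named chromosome lengths.
#' @param seed integer seed.
#' @param w window extension in bp (default 5).
#' @return list with `fraction`, `n`, and the shuffled `intervals`.
#' @export
random_overlap_baseline <- function(strs, anchors, genome_sizes, seed = 1L,
                                    w = 5L) {
  shuf <- shuffle_intervals(strs, genome_sizes, excluded = strs, seed = seed)
  if (!nrow(shuf)) return(list(fraction = NA_real_, n = 0L, intervals = shuf))
  hits <- window_overlap(shuf, anchors, w = w)
  frac <- length(unique(hits$a_idx)) / nrow(shuf)
  list(fraction = frac, n = nrow(shuf), intervals = shuf)
}

#' Assign expression to a subcellular compartment
#'
#' @param expr_nuclear,expr_cytoplasmic non-negative expression values;
#'   vectorised.
#' @return character vector in `{"nucleus", "cytoplasm", "both",
#'   "undetected"}`.
#' @export
compartment_assignment <- function(expr_nuclear, expr_cytoplasmic) {
  if (any(expr_nuclear < 0) || any(expr_cytoplasmic < 0))
    stop("expression values must be non-negative")
  ifelse(expr_nuclear > 0 & expr_cytoplasmic > 0, "both",
         ifelse(expr_nuclear > 0, "nucleus",
                ifelse(expr_cytoplasmic > 0, "cytoplasm", "undetected")))
}

#' Write oriented STR signals as TSV
#'
#' Layout mirrors the published signal file: chrom, start, end,
#' `name;motif;strand`, signal, strand.
#'
#' @param oriented oriented STR data frame from [orient_strs()].
#' @param path output path.
#' @export
write_signal_table <- function(oriented, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_comment("signal_table"), con)
  writeLines(paste(oriented$chrom,
                   format(oriented$start, scientific = FALSE, trim = TRUE),
                   format(oriented$end, scientific = FALSE, trim = TRUE),
                   paste(oriented$name, oriented$effective_motif,
                         oriented$strand, sep = ";"),
                   format(oriented$signal, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   oriented$strand, sep = "\t"), con)
  invisible(path)
}
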