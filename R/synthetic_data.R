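#' Closed-form sequence-to-signal model for synthetic worlds
#'
#' The expected initiation signal of an oriented STR is
#' `exp(mu)` with `mu = baseline(class) + sum of planted-motif effects
#' present in the 101-bp window`; observed signals multiply `exp(mu)` by
#' lognormal noise (`exp(N(0, sigma^2))`), plus unit-count scatter along the
#' repeat body. The closed form makes the Bayes-optimal predictor available
#' to every test.
#'
#' @param baselines named numeric vector, class key (effective motif) ->
#'   log-scale baseline for orientations reading the repeat as that motif.
#' @param antisense_baseline baseline for class keys not listed (the
#'   antisense orientations of directional classes).
#' @param motifs data frame with `seq`, `effect` (additive on `mu`),
#'   `freq` (planting probability per STR), `offset` (fixed position of the
#'   motif start relative to the 3'-end base, in transcript orientation of
#'   the sense strand).
#' @param noise_sigma lognormal noise standard deviation on `mu`.
#' @param scatter_rate per-bp probability of a unit count along the STR
#'   body, emulating the low scattered counts seen along repeats.
#' @return list of class `signal_model`.
#' @export
signal_model <- function(
    baselines = c(AC = -0.5, AT = -1.2, AG = -0.9, AAAG = -1.6),
    antisense_baseline = -3.3,
    motifs = data.frame(seq = c("TTATATAA", "ACGCGCGT"),
                        effect = c(1.5, -1.2),
                        freq = c(0.30, 0.20),
                        offset = c(-45L, 20L),
                        stringsAsFactors = FALSE),
    noise_sigma = 0.3, scatter_rate = 0.02) {
  # both default motifs are reverse-complement palindromes, so a planted
  # instance is seen by the windows of both orientations and directionality
  # stays a pure class property
  structure(list(baselines = baselines,
                 antisense_baseline = antisense_baseline,
                 motifs = motifs, noise_sigma = noise_sigma,
                 scatter_rate = scatter_rate),
            class = "signal_model")
}

#' Log-scale expected signal of windows under the closed form
#'
#' @param windows character vector of window sequences.
#' @param class_keys effective motif of each window's orientation.
#' @param model a [signal_model()].
#' @return numeric vector of `mu` values; `exp(mu)` is the expected signal.
#' @export
signal_model_mu <- function(windows, class_keys, model) {
  base <- model$baselines[class_keys]
  base[is.na(base)] <- model$antisense_baseline
  mu <- as.numeric(base)
  for (i in seq_len(nrow(model$motifs)))
    mu <- mu + model$motifs$effect[i] *
      grepl(model$motifs$seq[i], windows, fixed = TRUE)
  mu
}

#' Default synthetic world dimensions
#'
#' Two chromosomes of 1.8 Mb holding 20,000 STRs from 4 classes: one
#' strongly directional dinucleotide class with GC-rich flanks (AC), one
#' balanced palindromic-motif class with AT-rich flanks (AT), and two
#' classes with identically generated flanks (AG, AAAG) giving a
#' chance-level classification pair.
#'
#' @param n_str number of STRs.
#' @param chrom_lengths named chromosome lengths.
#' @param classes data frame: `motif`, `flank_gc` (flank GC fraction).
#' @param min_len,max_len STR length bounds in bp.
#' @return list of class `world_spec`.
#' @export
world_spec <- function(n_str = 20000L,
                       chrom_lengths = c(chr1 = 1800000, chr2 = 1800000),
                       classes = data.frame(
                         motif = c("AC", "AT", "AG", "AAAG"),
                         flank_gc = c(0.62, 0.38, 0.50, 0.50),
                         stringsAsFactors = FALSE),
                       min_len = 12L, max_len = 36L) {
  structure(list(n_str = as.integer(n_str), chrom_lengths = chrom_lengths,
                 classes = classes, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "world_spec")
}

#' Generate a synthetic genome, STR catalog and ground truth
#'
#' Places non-overlapping STRs on a random-uniform genome, rewrites their
#' flanks (+/- 50 bp) with class-specific base composition, plants effect
#' motifs at fixed offsets from the 3' end in a stated fraction of loci, and
#' tabulates the closed-form expected signal of both orientations of every
#' STR. Deterministic per seed.
#'
#' @param spec a [world_spec()].
#' @param model a [signal_model()].
#' @param seed integer seed.
#' @return list of class `synthetic_world`: `store`, `catalog`,
#'   `truth` (one row per orientation: `name`, `strand`, `class_key`,
#'   `three_prime_end`, `mu`, `expected_signal`, `has_motif` flags),
#'   `chrom_lengths`, `spec`, `model`, `seed`.
#' @export
generate_world <- function(spec = world_spec(), model = signal_model(),
                           seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  chroms <- lapply(spec$chrom_lengths, function(L)
    sample(bases, L, replace = TRUE))
  if (spec$n_str == 0L) {
    store <- vapply(chroms, paste, character(1), collapse = "")
    return(structure(list(store = store, catalog = .empty_catalog(),
                          truth = NULL, chrom_lengths = spec$chrom_lengths,
                          spec = spec, model = model,
                          seed = as.integer(seed)),
                     class = "synthetic_world"))
  }
  slot_w <- 160L
  slots <- do.call(rbind, lapply(names(spec$chrom_lengths), function(ch) {
    ns <- floor(spec$chrom_lengths[[ch]] / slot_w)
    data.frame(chrom = ch, slot0 = (seq_len(ns) - 1) * slot_w)
  }))
  if (nrow(slots) < spec$n_str)
    stop("genome too small: ", nrow(slots), " slots for ", spec$n_str,
         " STRs")
  slots <- slots[sample.int(nrow(slots), spec$n_str), , drop = FALSE]
  cls_idx <- sample.int(nrow(spec$classes), spec$n_str, replace = TRUE)
  motif <- spec$classes$motif[cls_idx]
  period <- nchar(motif)
  reps <- integer(spec$n_str)
  for (p in unique(period)) {
    k <- period == p
    lo <- ceiling(spec$min_len / p); hi <- floor(spec$max_len / p)
    reps[k] <- sample(lo:hi, sum(k), replace = TRUE)
  }
  len <- period * reps
  start <- slots$slot0 + 60L + sample(-10:10, spec$n_str, replace = TRUE)
  end <- start + len
  gc <- spec$classes$flank_gc[cls_idx]
  plant <- matrix(FALSE, spec$n_str, nrow(model$motifs))
  for (mi in seq_len(nrow(model$motifs)))
    plant[, mi] <- stats::runif(spec$n_str) < model$motifs$freq[mi]
  for (ch in unique(slots$chrom)) {
    g <- chroms[[ch]]
    chroms[[ch]] <- NULL  # drop the list reference so writes stay in place
    for (i in which(slots$chrom == ch)) {
      body <- rep(strsplit(motif[i], "")[[1]], reps[i])
      g[(start[i] + 1):end[i]] <- body
      # class-composition flanks
      pr <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      fl <- sample(bases, 100, replace = TRUE, prob = pr)
      g[(start[i] - 49):start[i]] <- fl[1:50]
      g[(end[i] + 1):(end[i] + 50)] <- fl[51:100]
      t0 <- end[i] - 1  # 0-based 3'-end base of the (+) orientation
      for (mi in seq_len(nrow(model$motifs))) {
        if (!plant[i, mi]) next
        off <- model$motifs$offset[mi]
        mseq <- strsplit(model$motifs$seq[mi], "")[[1]]
        g[(t0 + off + 1):(t0 + off + length(mseq))] <- mseq
      }
    }
    chroms[[ch]] <- g
  }
  chroms <- chroms[names(spec$chrom_lengths)]
  store <- vapply(chroms, paste, character(1), collapse = "")
  names(store) <- names(spec$chrom_lengths)
  catalog <- data.frame(chrom = slots$chrom, start = start, end = end,
                        period = period, repeat_count = reps,
                        name = sprintf("Syn_STR_%d", seq_len(spec$n_str)),
                        motif = motif, str_class = motif, strand = "*",
                        stringsAsFactors = FALSE)
  o <- order(catalog$chrom, catalog$start)
  catalog <- catalog[o, , drop = FALSE]
  plant <- plant[o, , drop = FALSE]
  rownames(catalog) <- NULL
  truth <- .world_truth(store, catalog, model)
  truth$planted_up <- rep(plant[, 1], each = 2)
  truth$planted_down <- rep(plant[, 2], each = 2)
  structure(list(store = store, catalog = catalog, truth = truth,
                 chrom_lengths = spec$chrom_lengths, spec = spec,
                 model = model, seed = as.integer(seed)),
            class = "synthetic_world")
}

# closed-form truth table for both orientations of every catalog STR
.world_truth <- function(store, catalog, model, width = 101L) {
  n <- nrow(catalog)
  oriented <- catalog[rep(seq_len(n), each = 2), , drop = FALSE]
  oriented$strand <- rep(c("+", "-"), n)
  oriented$three_prime_end <- ifelse(oriented$strand == "+",
                                     oriented$end, oriented$start + 1)
  oriented$class_key <- ifelse(oriented$strand == "+", oriented$motif,
                               revcomp(oriented$motif))
  win <- .windows_vectorized(store, oriented, width, "none")
  mu <- rep(NA_real_, nrow(oriented))
  ok <- !is.na(win)
  mu[ok] <- signal_model_mu(win[ok], oriented$class_key[ok], model)
  truth <- oriented[, c("chrom", "start", "end", "name", "motif", "strand",
                        "three_prime_end", "class_key")]
  truth$mu <- mu
  truth$expected_signal <- exp(mu)
  rownames(truth) <- NULL
  truth
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nrow(x$catalog), "STRs on",
      length(x$store), "chromosome(s), classes:",
      paste(unique(x$catalog$motif), collapse = ", "), "\n")
  invisible(x)
}

#' Generate strand-specific coverage realizing the world's truth
#'
#' Each orientation draws an observed signal
#' `s = expected_signal * exp(N(0, sigma^2))` and deposits mass
#' `s * (L + 10)` into five bins around its 3' end (transcript-orientation
#' offsets 0, -1, +1, -2, +2 with weights .6/.15/.1/.1/.05), plus unit
#' counts scattered along the repeat body at `scatter_rate` per bp on the
#' oriented strand. With zero noise and zero scatter, [cage_signal()]
#' recovers `expected_signal` exactly.
#'
#' @param world a `synthetic_world`.
#' @param seed integer seed.
#' @return list: `plus`, `minus` (two `coverage_track`s), and `truth` (the
#'   world truth with the realized `s_obs` column appended).
#' @export
generate_coverage <- function(world, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  model <- world$model
  tr <- world$truth
  plus <- coverage_track(world$chrom_lengths, n_libraries = 1L)
  minus <- coverage_track(world$chrom_lengths, n_libraries = 1L)
  if (is.null(tr) || !nrow(tr)) return(list(plus = plus, minus = minus,
                                            truth = tr))
  s_obs <- tr$expected_signal *
    exp(stats::rnorm(nrow(tr), 0, model$noise_sigma))
  s_obs[is.na(tr$mu)] <- 0
  wts <- c(0.6, 0.15, 0.10, 0.10, 0.05)
  offs <- c(0L, -1L, 1L, -2L, 2L)
  L <- tr$end - tr$start
  mass <- s_obs * (L + 10)
  t0 <- tr$three_prime_end - 1
  sgn <- ifelse(tr$strand == "+", 1L, -1L)
  # peak mass: 5 bins per oriented STR, vectorized
  peak_pos <- rep(t0, each = length(offs)) +
    rep(sgn, each = length(offs)) * rep(offs, nrow(tr))
  peak_val <- rep(mass, each = length(wts)) * rep(wts, nrow(tr))
  peak_chrom <- rep(tr$chrom, each = length(offs))
  peak_strand <- rep(tr$strand, each = length(offs))
  # unit-count scatter along the repeat body on the oriented strand
  if (model$scatter_rate > 0) {
    body_pos <- sequence(L) - 1 + rep(tr$start, L)
    hit <- stats::runif(length(body_pos)) < model$scatter_rate
    sc_pos <- body_pos[hit]
    sc_chrom <- rep(tr$chrom, L)[hit]
    sc_strand <- rep(tr$strand, L)[hit]
    peak_pos <- c(peak_pos, sc_pos)
    peak_val <- c(peak_val, rep(1, length(sc_pos)))
    peak_chrom <- c(peak_chrom, sc_chrom)
    peak_strand <- c(peak_strand, sc_strand)
  }
  for (ch in unique(tr$chrom)) {
    for (st in c("+", "-")) {
      k <- peak_chrom == ch & peak_strand == st
      if (!any(k)) next
      agg <- rowsum(peak_val[k], peak_pos[k])
      idx <- as.numeric(rownames(agg)) + 1
      trk <- if (st == "+") plus else minus
      trk$values[[ch]][idx] <- trk$values[[ch]][idx] + agg[, 1]
      if (st == "+") plus <- trk else minus <- trk
    }
  }
  tr$s_obs <- s_obs
  list(plus = plus, minus = minus, truth = tr)
}

#' Generate SAM-like alignment fixtures with controlled first-base G bias
#'
#' "Capped" fixtures carry a template-mismatched G as the 5'-most base at
#' rate `cap_g_rate`; `uniform_mismatch_rate` instead draws the 5' read base
#' uniformly among the non-reference bases (the uncapped control). The MD
#' descriptors are internally consistent with the read sequences and
#' round-trip through [read_alignments()].
#'
#' @param anchors anchor intervals; each read's 5' end sits at its anchor's
#'   start position (anchor strand used when stranded, else sampled).
#' @param n_per_anchor reads per anchor.
#' @param cap_g_rate probability of a capped-G first-base mismatch.
#' @param uniform_mismatch_rate probability of a uniform first-base
#'   mismatch (mutually exclusive draw, applied after the cap draw).
#' @param seed integer seed.
#' @param read_len read length in bp.
#' @return data frame of alignment records (`chrom`, `pos` 0-based leftmost,
#'   `strand`, `seq`, `md`) accepted by [write_alignments()].
#' @export
generate_alignments <- function(anchors, n_per_anchor = 10L, cap_g_rate = 0,
                                uniform_mismatch_rate = 0, seed = 1L,
                                read_len = 25L) {
  stopifnot(cap_g_rate >= 0, cap_g_rate <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  n <- nrow(anchors) * n_per_anchor
  ai <- rep(seq_len(nrow(anchors)), each = n_per_anchor)
  strand <- anchors$strand[ai]
  strand[!strand %in% c("+", "-")] <- sample(c("+", "-"),
                                             sum(!strand %in% c("+", "-")),
                                             replace = TRUE)
  five <- anchors$start[ai]  # 0-based 5'-end position
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, read_len, replace = TRUE), collapse = ""),
    character(1))
  u <- stats::runif(n)
  capped <- u < cap_g_rate
  unif <- !capped & u < cap_g_rate + uniform_mismatch_rate
  md <- rep(as.character(read_len), n)
  for (i in which(capped | unif)) {
    if (capped[i]) {
      b5 <- "G"; ref <- sample(setdiff(bases, "G"), 1)
    } else {
      ref <- sample(bases, 1); b5 <- sample(setdiff(bases, ref), 1)
    }
    if (strand[i] == "+") {
      substr(seqs[i], 1, 1) <- b5
      md[i] <- paste0("0", ref, read_len - 1)
    } else {
      # stored on the reference strand: 5' base is the rightmost, complemented
      substr(seqs[i], read_len, read_len) <- chartr("ACGT", "TGCA", b5)
      ref_plus <- chartr("ACGT", "TGCA", ref)
      md[i] <- paste0(read_len - 1, ref_plus, "0")
    }
  }
  pos <- ifelse(strand == "+", five, five - (read_len - 1))
  data.frame(chrom = anchors$chrom[ai], pos = pos, strand = strand,
             seq = seqs, md = md, stringsAsFactors = FALSE)
}

#' Bayes-optimal predictor under the closed-form signal model
#'
#' A model-like object whose predictions are the generative expectation
#' `exp(mu)` of each window: the class key is read off the four repeat bases
#' ending at the window center and the planted-motif terms from the window
#' sequence itself. The correlation this oracle achieves against observed
#' signals is the ceiling against which trained networks are judged.
#'
#' @param model a [signal_model()].
#' @param width window width the oracle accepts (default 101).
#' @return object of class `signal_oracle` with a [predict.signal_oracle()]
#'   method.
#' @export
bayes_predictor <- function(model, width = 101L) {
  keys <- unique(c(names(model$baselines), revcomp(names(model$baselines))))
  last4 <- vapply(keys, function(k) {
    s <- strrep(k, ceiling(4 / nchar(k)) + 1)
    substr(s, nchar(s) - 3, nchar(s))
  }, character(1))
  structure(list(spec = list(input_width = as.integer(width),
                             task = "regression"),
                 signal_model = model,
                 key_by_last4 = stats::setNames(keys, last4),
                 target_transform = "identity"),
            class = "signal_oracle")
}

#' @rdname bayes_predictor
#' @param object a `signal_oracle`.
#' @param X design matrix of one-hot windows (or `str_dataset`).
#' @param type `"response"` (expected signal) or `"raw"` (`mu`).
#' @param ... unused.
#' @export
predict.signal_oracle <- function(object, X, type = c("response", "raw"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(X, "str_dataset")) X <- X$X
  W <- object$spec$input_width
  if (ncol(X) != 4L * W) stop("input width mismatch")
  wins <- decode_windows(X, W)
  center <- (W + 1) / 2
  l4 <- substr(wins, center - 3, center)
  keys <- object$key_by_last4[l4]
  keys[is.na(keys)] <- "?"
  mu <- signal_model_mu(wins, keys, object$signal_model)
  if (type == "raw") mu else exp(mu)
}

#' Decode a design matrix of one-hot windows back to sequences
#' @param X n x 4W matrix as built by [encode_windows()].
#' @param W window width.
#' @return character vector of sequences (zero columns decode to `N`).
#' @export
decode_windows <- function(X, W) {
  n <- nrow(X)
  chars <- matrix("N", n, W)
  bases <- c("A", "C", "G", "T")
  for (b in 1:4) {
    hit <- X[, (seq_len(W) - 1) * 4 + b, drop = FALSE] == 1
    chars[hit] <- bases[b]
  }
  apply(chars, 1, paste, collapse = "")
}

#' Generate SNVs around STR 3' ends with closed-form true effects
#'
#' A fraction of variants is targeted at planted motif instances (so the
#' variant-effect surface has enough nonzero-effect cases; the default
#' targets the downstream motif, the one lying inside the -15/+30 eQTL
#' selection window); the rest draw their offset from the 3' end under
#' `P(o) ~ exp(-|o|/10)`, `o in [-50, 50]`. The true effect of each variant
#' is the closed-form `mu(mutated window) - mu(reference window)` of the
#' sense orientation; eQTL-style slopes equal the true effect, with an
#' optional probability of a sign flip. Variants without any expression
#' effect are not eQTLs and carry an `NA` slope.
#'
#' @param world a `synthetic_world`.
#' @param n number of variants.
#' @param seed integer seed.
#' @param targeted_fraction fraction aimed at planted motif instances.
#' @param targeted_motif row index into the signal model's motif table of
#'   the motif to target (default 2, the downstream motif).
#' @param sign_noise probability of flipping a slope's sign.
#' @return list: `variants` (data frame `chrom`, `pos` 1-based, `ref`,
#'   `alt`, `slope`, `gene`, `true_effect`, `str_name`),
#'   `gene_starts` (`chrom`, `pos`, `gene`: one proxy gene per STR at its
#'   (+)-orientation 3' end).
#' @export
generate_variants <- function(world, n = 200L, seed = 1L,
                              targeted_fraction = 0.7, sign_noise = 0,
                              targeted_motif = 2L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  cat <- world$catalog
  truth_plus <- world$truth[world$truth$strand == "+", , drop = FALSE]
  motif_a <- world$model$motifs[targeted_motif, , drop = FALSE]
  planted_col <- if (targeted_motif == 1L) truth_plus$planted_up else
    truth_plus$planted_down
  targeted <- stats::runif(n) < targeted_fraction & any(planted_col)
  str_idx <- integer(n)
  str_idx[targeted] <- sample(which(planted_col), sum(targeted),
                              replace = TRUE)
  str_idx[!targeted] <- sample.int(nrow(cat), sum(!targeted), replace = TRUE)
  offsets <- integer(n)
  law <- -50:50
  pl <- exp(-abs(law) / 10); pl <- pl / sum(pl)
  offsets[!targeted] <- sample(law, sum(!targeted), replace = TRUE,
                               prob = pl)
  if (any(targeted))
    offsets[targeted] <- motif_a$offset +
      sample(0:(nchar(motif_a$seq) - 1), sum(targeted), replace = TRUE)
  t0 <- cat$end[str_idx] - 1
  pos0 <- t0 + offsets
  refb <- unname(substring(world$store[cat$chrom[str_idx]], pos0 + 1,
                           pos0 + 1))
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1),
                 character(1), USE.NAMES = FALSE)
  # closed-form effect on the sense orientation
  true_effect <- numeric(n)
  for (i in seq_len(n)) {
    ostr <- truth_plus[str_idx[i], , drop = FALSE]
    win <- extract_window(world$store, ostr, 101L)
    if (is.na(win)) { true_effect[i] <- NA_real_; next }
    relwin <- offsets[i] + 51  # window column of the variant
    mwin <- win
    substr(mwin, relwin, relwin) <- altb[i]
    true_effect[i] <- signal_model_mu(mwin, ostr$class_key, world$model) -
      signal_model_mu(win, ostr$class_key, world$model)
  }
  # variants with no expression effect are not eQTLs: slope is NA there
  slope <- ifelse(abs(true_effect) > 1e-12, true_effect, NA_real_)
  flip <- stats::runif(n) < sign_noise & !is.na(slope)
  slope[flip] <- -slope[flip]
  gene <- paste0("g_", cat$name[str_idx])
  variants <- data.frame(chrom = cat$chrom[str_idx], pos = pos0 + 1,
                         ref = refb, alt = altb, slope = slope,
                         gene = gene, true_effect = true_effect,
                         str_name = cat$name[str_idx],
                         stringsAsFactors = FALSE)
  gene_starts <- data.frame(chrom = cat$chrom, pos = cat$end,
                            gene = paste0("g_", cat$name),
                            stringsAsFactors = FALSE)
  list(variants = variants, gene_starts = gene_starts)
}
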