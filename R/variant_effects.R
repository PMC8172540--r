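#' Pair variants with STRs within a window
#'
#' A variant (1-based position) is paired with every STR whose interval
#' extended by `w` bp contains it (`bedtools window -w` semantics). The
#' unpaired STR set is returned too, for with/without-variant signal
#' contrasts.
#'
#' @param variants data frame: `chrom`, `pos` (1-based), `ref`, `alt`, plus
#'   annotation columns.
#' @param strs STR data frame (0-based half-open interval columns).
#' @param w window extension in bp (default 50).
#' @return list: `pairs` (data frame `variant_idx`, `str_idx`),
#'   `unpaired_strs` (integer indices of STRs with no variant in window).
#' @export
map_variants_to_strs <- function(variants, strs, w = 50L) {
  if (w < 0) stop("window must be >= 0")
  if (!nrow(variants) || !nrow(strs))
    return(list(pairs = data.frame(variant_idx = integer(0),
                                   str_idx = integer(0)),
                unpaired_strs = seq_len(nrow(strs))))
  v <- gintervals(variants$chrom, variants$pos - 1, variants$pos)
  hits <- window_overlap(strs, v, w = w)
  pairs <- data.frame(variant_idx = hits$b_idx, str_idx = hits$a_idx)
  pairs <- pairs[order(pairs$variant_idx, pairs$str_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_strs = setdiff(seq_len(nrow(strs)), hits$a_idx))
}

#' Predicted effect of a single-nucleotide variant at an oriented STR
#'
#' The alternative allele is substituted into the genome (alleles are given
#' on the (+) strand; the (-) orientation sees the complement through
#' reverse-complemented window extraction), the window around the STR 3'
#' end is re-extracted, and delta = predict(reference) - predict(mutated).
#' The variant's position is reported relative to the 3'-end base in
#' transcript orientation (0 = the 3'-end base, negative = upstream).
#'
#' @param model trained `str_cnn`.
#' @param store sequence store.
#' @param oriented_str one-row oriented STR.
#' @param variant one-row variant data frame (`chrom`, `pos` 1-based,
#'   `ref`, `alt`).
#' @return list: `delta`, `relative_position`, `status` (`"ok"`,
#'   `"not_snv"`, `"ref_mismatch"`, `"outside_window"`).
#' @export
variant_delta <- function(model, store, oriented_str, variant) {
  if (nchar(variant$ref[1]) != 1 || nchar(variant$alt[1]) != 1)
    return(list(delta = NA_real_, relative_position = NA_real_,
                status = "not_snv"))
  W <- model$spec$input_width
  h <- (W - 1) / 2
  ch <- variant$chrom[1]
  p0 <- variant$pos[1] - 1
  t0 <- oriented_str$three_prime_end[1] - 1
  rel <- if (oriented_str$strand[1] == "+") p0 - t0 else t0 - p0
  if (abs(rel) > h)
    return(list(delta = NA_real_, relative_position = rel,
                status = "outside_window"))
  genome_base <- substr(store[[ch]], p0 + 1, p0 + 1)
  if (genome_base != toupper(variant$ref[1]))
    return(list(delta = NA_real_, relative_position = rel,
                status = "ref_mismatch"))
  ref_win <- extract_window(store, oriented_str, W)
  mut_store <- store[ch]
  substr(mut_store[[ch]], p0 + 1, p0 + 1) <- toupper(variant$alt[1])
  mut_win <- extract_window(mut_store, oriented_str, W)
  if (is.na(ref_win) || is.na(mut_win))
    return(list(delta = NA_real_, relative_position = rel,
                status = "outside_window"))
  list(delta = prediction_delta(model, ref_win, mut_win),
       relative_position = rel, status = "ok")
}

#' Compare signal distributions across annotation groups
#'
#' One-way ANOVA for an overall difference, then all ordered pairwise
#' one-sided Mann-Whitney rank tests (alternative: first group greater) with
#' Benjamini-Hochberg adjustment across the pairwise tests.
#'
#' @param groups named list, label -> numeric signal vector (>= 2 groups,
#'   each n >= 2).
#' @return list: `anova_p`, `anova_F`, `pairwise` (data frame `greater`,
#'   `lesser`, `p`, `p_adj`).
#' @export
signal_group_comparison <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("degenerate group (n < 2)")
  labels <- names(groups)
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(labels, lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  combos <- expand.grid(greater = labels, lesser = labels,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$greater != combos$lesser, , drop = FALSE]
  combos$p <- vapply(seq_len(nrow(combos)), function(i)
    suppressWarnings(stats::wilcox.test(groups[[combos$greater[i]]],
                                        groups[[combos$lesser[i]]],
                                        alternative = "greater"))$p.value,
    numeric(1))
  combos$p_adj <- stats::p.adjust(combos$p, method = "BH")
  rownames(combos) <- NULL
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       pairwise = combos)
}

#' Sign concordance between predicted allele effects and eQTL slopes
#'
#' Pipeline: (1) keep STRs within `promoter_window` bp of a gene start;
#' (2) keep eQTL SNVs inside `[-upstream, +downstream]` of the STR 3' end
#' in transcript orientation; (3) per case, compare
#' sign(predict(alt) - predict(ref)) with sign(slope); (4) stratify by the
#' model's prediction error on the reference genome,
#' eps = |predicted - observed| <= `error_cut` versus > `error_cut`;
#' (5) binomial test of the concordant count against p = 0.5 per stratum.
#' Cases are deduplicated on (variant, STR, gene).
#'
#' @param model trained `str_cnn` (accuracy gating is the caller's job).
#' @param store sequence store.
#' @param eqtls data frame: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `slope`, `gene`.
#' @param oriented oriented STR data frame with observed `signal`.
#' @param gene_starts data frame: `chrom`, `pos` (1-based gene start),
#'   `gene`.
#' @param promoter_window bp around a gene start defining a promoter
#'   (default 1000).
#' @param upstream,downstream eQTL selection window around the 3' end in
#'   transcript orientation (defaults 15 and 30).
#' @param error_cut stratification cut on the reference-genome prediction
#'   error (default 0.2, natural signal scale).
#' @param alternative sidedness of the binomial test (default `"greater"`:
#'   excess concordance).
#' @return list: `cases` (one row per evaluated case with `concordant`,
#'   `error`, `stratum`), `strata` (per-stratum `n_same`, `n_different`,
#'   `p_value`), `n_skipped` (named counts).
#' @export
eqtl_sign_concordance <- function(model, store, eqtls, oriented, gene_starts,
                                  promoter_window = 1000L, upstream = 15L,
                                  downstream = 30L, error_cut = 0.2,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  skipped <- c(not_promoter = 0L, outside_window = 0L, not_snv = 0L,
               ref_mismatch = 0L)
  eqtls <- eqtls[!is.na(eqtls$slope), , drop = FALSE]
  # (1) promoter STRs: 3' end within promoter_window of a gene start
  # (only genes that carry eQTLs can yield cases)
  gene_starts <- gene_starts[gene_starts$gene %in% unique(eqtls$gene), ,
                             drop = FALSE]
  if (!nrow(gene_starts))
    return(list(cases = NULL, strata = NULL, n_skipped = skipped,
                reason = "zero eligible cases"))
  tp0 <- oriented$three_prime_end - 1
  gs <- gintervals(gene_starts$chrom,
                   pmax(gene_starts$pos - 1 - promoter_window, 0),
                   gene_starts$pos + promoter_window)
  tp <- gintervals(oriented$chrom, tp0, tp0 + 1)
  prom_hits <- window_overlap(tp, gs, w = 0L)
  cases <- list()
  if (nrow(prom_hits) && nrow(eqtls)) {
    for (k in seq_len(nrow(prom_hits))) {
      i <- prom_hits$a_idx[k]; g <- gene_starts$gene[prom_hits$b_idx[k]]
      ostr <- oriented[i, , drop = FALSE]
      ev <- eqtls[eqtls$gene == g & eqtls$chrom == ostr$chrom, , drop = FALSE]
      if (!nrow(ev)) next
      # (2) transcript-orientation window around the 3' end
      rel <- if (ostr$strand == "+") (ev$pos - 1) - tp0[i] else
        tp0[i] - (ev$pos - 1)
      ev <- ev[rel >= -upstream & rel <= downstream, , drop = FALSE]
      if (!nrow(ev)) next
      for (j in seq_len(nrow(ev))) {
        vd <- variant_delta(model, store, ostr, ev[j, , drop = FALSE])
        if (vd$status != "ok") {
          if (vd$status %in% names(skipped))
            skipped[vd$status] <- skipped[vd$status] + 1L
          next
        }
        # paper convention: alternative - reference vs slope
        pred_sign <- sign(-vd$delta)
        cases[[length(cases) + 1]] <- data.frame(
          chrom = ostr$chrom, pos = ev$pos[j], gene = g,
          str_name = ostr$name, strand = ostr$strand,
          delta_alt_minus_ref = -vd$delta, slope = ev$slope[j],
          concordant = pred_sign == sign(ev$slope[j]),
          error = abs(predict(model, encode_windows(
            extract_window(store, ostr, model$spec$input_width),
            model$spec$input_width)) - ostr$signal),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cases))
    return(list(cases = NULL, strata = NULL,
                n_skipped = skipped, reason = "zero eligible cases"))
  cases <- do.call(rbind, cases)
  cases <- cases[!duplicated(cases[, c("chrom", "pos", "str_name", "gene")]), ,
                 drop = FALSE]
  cases$stratum <- ifelse(cases$error <= error_cut, "low_error", "high_error")
  strata <- lapply(split(cases, cases$stratum), function(d) {
    ns <- sum(d$concordant); nd <- sum(!d$concordant)
    data.frame(stratum = d$stratum[1], n_same = ns, n_different = nd,
               p_value = stats::binom.test(ns, ns + nd, 0.5,
                                           alternative = alternative)$p.value,
               stringsAsFactors = FALSE)
  })
  strata <- do.call(rbind, strata)
  rownames(strata) <- NULL
  list(cases = cases, strata = strata, n_skipped = skipped)
}

#' Label enrichment of a member set against a background
#'
#' For each label, a two-sided Fisher exact test on the 2x2 table
#' (members with/without the label vs background with/without), with
#' Benjamini-Hochberg adjustment across all labels tested.
#'
#' @param member_labels character vector of labels of the member set (one
#'   entry per member; multiple labels per member may be pre-expanded).
#' @param background_labels labels of the background set.
#' @param labels labels to test (default: union of observed labels).
#' @return data frame: `label`, `odds_ratio` (cross-product ratio), `p`,
#'   `p_adj`, `testable`.
#' @export
set_enrichment <- function(member_labels, background_labels, labels = NULL) {
  if (is.null(labels))
    labels <- sort(unique(c(member_labels, background_labels)))
  res <- lapply(labels, function(lb) {
    a <- sum(member_labels == lb); b <- sum(member_labels != lb)
    c_ <- sum(background_labels == lb); d <- sum(background_labels != lb)
    testable <- (a + b) > 0 && (c_ + d) > 0 && (a + c_) > 0 && (b + d) > 0
    orat <- if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
    p <- if (testable)
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    else NA_real_
    data.frame(label = lb, a = a, b = b, c = c_, d = d, odds_ratio = orat,
               p = p, testable = testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
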