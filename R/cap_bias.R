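#' Tally first-base mismatches of tags anchored at positions of interest
#'
#' Reverse transcription of the 7-methylguanosine cap adds an extra,
#' template-mismatched G at the 5' end of CAGE tags, so a G excess among
#' first-base mismatches evidences genuinely capped transcripts. A tag
#' "intersects" an anchor when its 5'-end base falls inside the anchor
#' interval (same strand if `same_strand`). The tag is "mismatched" when its
#' 5'-most aligned base differs from the reference: on the (+) strand the MD
#' descriptor starts with a zero-length match (`MD:Z:0...`); on the (-)
#' strand, symmetrically, it ends in a substitution followed by a zero-length
#' match. The tallied base is the read's 5' base in read orientation
#' (reverse-complemented for (-) tags).
#'
#' @param alignments result of [read_alignments()] (or its `records` element).
#' @param anchors anchor intervals, data frame with `strand` when
#'   `same_strand` is set.
#' @param same_strand require tag and anchor strand to match.
#' @param plus_only count (+)-strand tags only (strict replication of the
#'   printed one-liner, which handles only `$6 == "+"`).
#' @return list of class `first_base_tally`: `mismatch_counts` (named A/C/G/T),
#'   `matched`, `total`, `skipped_parse`.
#' @export
first_base_tally <- function(alignments, anchors, same_strand = TRUE,
                             plus_only = FALSE) {
  recs <- if (is.data.frame(alignments)) alignments else alignments$records
  if (nrow(recs) && is.null(recs$five_prime)) {
    alen <- vapply(recs$md, function(m) parse_md(m)$aln_len, numeric(1),
                   USE.NAMES = FALSE)
    recs$five_prime <- ifelse(recs$strand == "+", recs$pos,
                              recs$pos + alen - 1)
  }
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  matched <- 0L; skipped <- 0L
  if (nrow(recs)) {
    fp <- gintervals(recs$chrom, recs$five_prime, recs$five_prime + 1,
                     strand = recs$strand)
    hits <- window_overlap(fp, anchors, w = 0L, same_strand = same_strand)
    sel <- unique(hits$a_idx)
    if (plus_only) sel <- sel[recs$strand[sel] == "+"]
    for (i in sel) {
      md <- parse_md(recs$md[i])
      if (is.null(md)) { skipped <- skipped + 1L; next }
      if (recs$strand[i] == "+") {
        mm <- length(md$sub_bases) > 0 && md$match_lens[1] == 0
        base <- substr(recs$seq[i], 1, 1)
      } else {
        nl <- length(md$match_lens)
        mm <- length(md$sub_bases) > 0 && md$match_lens[nl] == 0
        last <- substr(recs$seq[i], nchar(recs$seq[i]), nchar(recs$seq[i]))
        base <- chartr("ACGTN", "TGCAN", last)
      }
      if (mm) {
        if (base %in% names(counts)) counts[base] <- counts[base] + 1L
      } else matched <- matched + 1L
    }
  }
  structure(list(mismatch_counts = counts, matched = matched,
                 total = matched + sum(counts), skipped_parse = skipped),
            class = "first_base_tally")
}

#' Summarize a first-base mismatch tally
#'
#' @param tally a `first_base_tally`.
#' @return data frame with the total intersecting tag count, the fraction of
#'   tags with a mismatched first base, and each base's share among all
#'   intersecting tags (`share_of_total`) and among mismatched tags only
#'   (`share_of_mismatched`) — both conventions are reported.
#' @export
g_bias_report <- function(tally) {
  if (tally$total == 0) stop("empty tally: no intersecting tags")
  mm <- sum(tally$mismatch_counts)
  data.frame(
    base = names(tally$mismatch_counts),
    count = as.integer(tally$mismatch_counts),
    share_of_total = as.numeric(tally$mismatch_counts) / tally$total,
    share_of_mismatched = if (mm > 0)
      as.numeric(tally$mismatch_counts) / mm else rep(NA_real_, 4),
    mismatch_fraction = mm / tally$total,
    total = tally$total,
    stringsAsFactors = FALSE)
}

#' @export
print.first_base_tally <- function(x, ...) {
  cat("first_base_tally:", x$total, "intersecting tags,",
      sum(x$mismatch_counts), "with mismatched first base (",
      paste(names(x$mismatch_counts), x$mismatch_counts, sep = "=",
            collapse = " "), ")\n")
  invisible(x)
}
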