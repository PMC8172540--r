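#' Genomic intervals in BED convention
#'
#' All interval storage in this package is 0-based half-open (`[start, end)`),
#' the convention of BED and of the STR catalog dialect. Human-facing 3'-end
#' coordinates are 1-based and converted explicitly at the boundary.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @param name optional identifiers; recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, one row per interval.
#' @export
gintervals <- function(chrom, start, end, strand = "*", name = NA_character_) {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == n, length(end) == n)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start (half-open, length > 0)")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, name = rep_len(name, n),
             stringsAsFactors = FALSE)
}

#' Overlap pairs between two interval sets with symmetric window extension
#'
#' Emits an (a, b) index pair whenever `[a$start - w, a$end + w)` shares at
#' least one base with `[b$start, b$end)` on the same chromosome, the
#' semantics of `bedtools window -w`.
#'
#' @param a,b interval data frames as built by [gintervals()].
#' @param w non-negative window extension in bp applied to `a`.
#' @param same_strand if `TRUE`, additionally require equal strand.
#' @return `data.frame` with integer columns `a_idx`, `b_idx` (1-based row
#'   indices into `a` and `b`).
#' @export
window_overlap <- function(a, b, w = 0L, same_strand = FALSE) {
  if (w < 0) stop("window extension w must be >= 0")
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  out_a <- integer(0); out_b <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    # convert half-open 0-based to closed 1-based for IRanges
    ra <- IRanges::IRanges(start = a$start[ia] + 1 - w, end = a$end[ia] + w)
    rb <- IRanges::IRanges(start = b$start[ib] + 1, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    out_a <- c(out_a, ia[S4Vectors::queryHits(hits)])
    out_b <- c(out_b, ib[S4Vectors::subjectHits(hits)])
  }
  keep <- if (same_strand && length(out_a))
    a$strand[out_a] == b$strand[out_b] else rep(TRUE, length(out_a))
  o <- order(out_a[keep], out_b[keep])
  data.frame(a_idx = out_a[keep][o], b_idx = out_b[keep][o])
}

#' Length-preserving random relocation of intervals avoiding exclusions
#'
#' Places each interval uniformly at random on the genome (chromosome chosen
#' with probability proportional to the space that can hold it), rejecting
#' placements that overlap an excluded interval. Semantics of
#' `bedtools shuffle -excl`; the random stream is this package's own.
#'
#' @param intervals intervals to relocate (lengths are preserved).
#' @param genome_sizes named numeric vector, chromosome -> length in bp.
#' @param excluded intervals no output may overlap; may be `NULL`.
#' @param seed integer seed; the operation is deterministic given it.
#' @param max_rounds rejection-sampling rounds before giving up.
#' @return intervals data frame with the same lengths, in input order.
#' @export
shuffle_intervals <- function(intervals, genome_sizes, excluded = NULL,
                              seed = 1L, max_rounds = 200L) {
  n <- nrow(intervals)
  if (n == 0L) return(intervals[0, ])
  chroms <- names(genome_sizes)
  if (is.null(chroms)) stop("genome_sizes must be a named vector")
  excl <- vector("list", length(chroms)); names(excl) <- chroms
  if (!is.null(excluded) && nrow(excluded)) {
    for (ch in chroms) {
      k <- excluded$chrom == ch
      excl[[ch]] <- IRanges::reduce(IRanges::IRanges(
        start = excluded$start[k] + 1, end = excluded$end[k]))
    }
  }
  lens <- intervals$end - intervals$start
  res_chrom <- character(n); res_start <- numeric(n)
  pending <- seq_len(n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (round in seq_len(max_rounds)) {
    if (!length(pending)) break
    L <- lens[pending]
    # placeable space per chromosome for each pending length
    space <- vapply(chroms, function(ch) pmax(genome_sizes[[ch]] - L + 1, 0),
                    numeric(length(L)))
    space <- matrix(space, nrow = length(L))
    tot <- rowSums(space)
    if (any(tot <= 0))
      stop("genome too small to place interval(s) of length ",
           paste(unique(L[tot <= 0]), collapse = ","))
    u <- stats::runif(length(L)) * tot
    cs <- t(apply(space, 1, cumsum))
    if (length(chroms) == 1L) cs <- matrix(cs, ncol = 1L)
    ci <- max.col(cs >= u, ties.method = "first")
    ch_pick <- chroms[ci]
    start_pick <- floor(stats::runif(length(L)) *
                          (genome_sizes[ch_pick] - L + 1))
    ok <- rep(TRUE, length(L))
    for (ch in unique(ch_pick)) {
      if (is.null(excl[[ch]]) || length(excl[[ch]]) == 0L) next
      k <- which(ch_pick == ch)
      q <- IRanges::IRanges(start = start_pick[k] + 1, end = start_pick[k] + L[k])
      ok[k] <- IRanges::countOverlaps(q, excl[[ch]]) == 0L
    }
    res_chrom[pending[ok]] <- ch_pick[ok]
    res_start[pending[ok]] <- start_pick[ok]
    pending <- pending[!ok]
  }
  if (length(pending))
    stop("failed to place ", length(pending),
         " interval(s) after ", max_rounds, " rounds; first length: ",
         lens[pending[1]])
  gintervals(res_chrom, res_start, res_start + lens,
             strand = intervals$strand, name = intervals$name)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Reverse complement of DNA strings
#'
#' Vectorised over the input; accepts the alphabet `{A,C,G,T,N}`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}
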