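#' Read an STR catalog (7-column HipSTR BED dialect)
#'
#' Columns: chrom, start (0-based), end (exclusive), period, repeat count,
#' name, motif. The catalog is defined on the (+) strand; `str_class` is the
#' motif as printed, with no canonicalization.
#'
#' @param path path to a whitespace-delimited 7-column file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `period`,
#'   `repeat_count`, `name`, `motif`, `str_class`, `strand` (always `"*"`).
#' @export
read_str_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_catalog())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("STR catalog parse error at line ", which(nf != 7L)[1],
         ": expected 7 columns, got ", nf[nf != 7L][1])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  period <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(period))
  if (length(bad))
    stop("STR catalog parse error at line ", bad[1], ": non-numeric coordinate")
  motif <- toupper(m[, 7])
  badm <- which(!grepl("^[ACGT]+$", motif))
  if (length(badm))
    stop("STR catalog parse error at line ", badm[1], ": motif not ACGT")
  if (any(period != nchar(motif)))
    warning("period differs from motif length for ",
            sum(period != nchar(motif)), " record(s)")
  if (any(period < 1 | period > 6))
    warning("period outside [1, 6] for ", sum(period < 1 | period > 6),
            " record(s)")
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    period = period,
                    repeat_count = suppressWarnings(as.numeric(m[, 5])),
                    name = m[, 6], motif = motif, str_class = motif,
                    strand = "*", stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$end <= out$start))
    stop("STR catalog parse error: invalid interval at line ",
         which(out$start < 0 | out$end <= out$start)[1])
  out
}

.empty_catalog <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             period = numeric(0), repeat_count = numeric(0),
             name = character(0), motif = character(0),
             str_class = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Write an STR catalog in the 7-column dialect
#'
#' @param catalog data frame as returned by [read_str_catalog()].
#' @param path output path.
#' @export
write_str_catalog <- function(catalog, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_comment("str_catalog"), con)
  if (nrow(catalog))
    writeLines(paste(catalog$chrom, format(catalog$start, scientific = FALSE, trim = TRUE),
                     format(catalog$end, scientific = FALSE, trim = TRUE),
                     catalog$period, catalog$repeat_count, catalog$name,
                     catalog$motif, sep = "\t"), con)
  invisible(path)
}

.header_comment <- function(what, params = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("strinit")),
                error = function(e) "dev")
  p <- if (length(params)) paste0(" ", paste(names(params), params,
                                             sep = "=", collapse = " ")) else ""
  sprintf("# strinit %s %s%s", v, what, p)
}

# ---- coverage tracks --------------------------------------------------------

#' Construct an empty coverage track
#'
#' A coverage track stores a per-chromosome dense vector of non-negative
#' 1-bp-binned signal (mean tag count) for one strand, plus provenance: the
#' number of libraries averaged and a mapping-quality filter label.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param n_libraries number of libraries the values average over.
#' @param quality_filter free-text label of the mapping-quality filter.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_lengths, n_libraries = 1L,
                           quality_filter = "Q3") {
  values <- lapply(chrom_lengths, function(L) numeric(L))
  structure(list(values = values, chrom_lengths = chrom_lengths,
                 n_libraries = n_libraries, quality_filter = quality_filter),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s),",
      format(sum(unlist(lapply(x$values, sum))), digits = 6), "total mass,",
      x$n_libraries, "library(ies),", x$quality_filter, "filter\n")
  invisible(x)
}

#' Read 1-bp coverage from a 4-column bedGraph
#'
#' Each record's value is assigned to every base of `[start, end)`.
#' Overlapping records and negative values are errors.
#'
#' @param path bedGraph path.
#' @param chrom_lengths optional named lengths; inferred from the maximal end
#'   per chromosome when absent.
#' @param n_libraries,quality_filter provenance, stored verbatim.
#' @return a `coverage_track`.
#' @export
read_coverage <- function(path, chrom_lengths = NULL, n_libraries = 1L,
                          quality_filter = "Q3") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    if (is.null(chrom_lengths)) chrom_lengths <- numeric(0)
    return(coverage_track(chrom_lengths, n_libraries, quality_filter))
  }
  f <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(f) < 4L)) stop("bedGraph record with fewer than 4 columns")
  m <- do.call(rbind, lapply(f, `[`, 1:4))
  df <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                   end = as.numeric(m[, 3]), value = as.numeric(m[, 4]),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$value)))
    stop("bedGraph parse error: non-numeric field")
  if (any(df$value < 0)) stop("bedGraph contains negative coverage values")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(df$end, df$chrom, max)
  cl <- as.numeric(chrom_lengths); names(cl) <- names(chrom_lengths)
  trk <- coverage_track(cl, n_libraries, quality_filter)
  for (ch in unique(df$chrom)) {
    k <- df$chrom == ch
    o <- order(df$start[k])
    s <- df$start[k][o]; e <- df$end[k][o]
    if (any(s[-1] < e[-length(e)]))
      stop("overlapping bedGraph records on ", ch)
    if (!ch %in% names(trk$values))
      stop("bedGraph chromosome not in chrom_lengths: ", ch)
    v <- trk$values[[ch]]
    for (i in seq_along(s)) v[(s[i] + 1):e[i]] <- df$value[k][o][i]
    trk$values[[ch]] <- v
  }
  trk
}

#' Write a coverage track as bedGraph (non-zero runs only)
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_comment("bedGraph",
                             c(libraries = track$n_libraries,
                               filter = track$quality_filter)), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                         as.integer(ends[keep]),
                         format(r$values[keep], digits = 10, trim = TRUE,
                                scientific = FALSE)), con)
  }
  invisible(path)
}

# ---- genome sequence --------------------------------------------------------

#' Load a genome FASTA into an in-memory sequence store
#'
#' @param path FASTA path.
#' @return named character vector, chromosome -> uppercase sequence.
#' @export
read_sequence_store <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a sequence store as FASTA
#' @param store named character vector of sequences.
#' @param path output path.
#' @export
write_sequence_store <- function(store, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(store), filepath = path, width = 70L)
  invisible(path)
}

#' Extract a (possibly reverse-complemented) genomic slice
#'
#' @param store sequence store (named character vector).
#' @param interval one-row interval data frame (0-based half-open).
#' @param strand `"+"` for the forward slice, `"-"` for its reverse complement.
#' @return character scalar.
#' @export
extract_sequence <- function(store, interval, strand = "+") {
  ch <- interval$chrom[1]
  if (!ch %in% names(store)) stop("unknown chromosome: ", ch)
  L <- nchar(store[[ch]])
  s <- interval$start[1]; e <- interval$end[1]
  if (s < 0 || e > L) stop("interval [", s, ",", e, ") out of bounds for ",
                           ch, " (length ", L, ")")
  seq <- substr(store[[ch]], s + 1, e)
  if (strand == "-") revcomp(seq) else seq
}

# ---- SAM-like alignments ----------------------------------------------------

#' Read SAM-format text alignments with MD mismatch descriptors
#'
#' Only flags 0 (+) and 16 (-) are kept; other flags are skipped and counted.
#' Records whose MD descriptor contains an indel (`^`) or fails to parse are
#' skipped and counted. The 5'-end position is the leftmost mapped base for
#' (+) reads and the rightmost for (-) reads, reported 0-based.
#'
#' @param path SAM text path (headers allowed).
#' @return list with `records` (data.frame: `chrom`, `pos` 0-based leftmost,
#'   `strand`, `seq`, `md`, `five_prime` 0-based 5'-end position, `aln_len`)
#'   and `skipped` (named counts: `other_flag`, `bad_md`, `indel`).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  skipped <- c(other_flag = 0L, bad_md = 0L, indel = 0L)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) { skipped["bad_md"] <- skipped["bad_md"] + 1L; next }
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag) || !flag %in% c(0L, 16L)) {
      skipped["other_flag"] <- skipped["other_flag"] + 1L; next
    }
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f[-(1:11)], value = TRUE)[1])
    if (is.na(md)) { skipped["bad_md"] <- skipped["bad_md"] + 1L; next }
    parsed <- parse_md(md)
    if (is.null(parsed)) { skipped["bad_md"] <- skipped["bad_md"] + 1L; next }
    if (parsed$has_indel) { skipped["indel"] <- skipped["indel"] + 1L; next }
    strand <- if (flag == 0L) "+" else "-"
    pos0 <- as.numeric(f[4]) - 1
    alen <- parsed$aln_len
    recs[[i]] <- data.frame(
      chrom = f[3], pos = pos0, strand = strand, seq = toupper(f[10]),
      md = md, five_prime = if (strand == "+") pos0 else pos0 + alen - 1,
      aln_len = alen, stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(0), pos = numeric(0), strand = character(0),
               seq = character(0), md = character(0), five_prime = numeric(0),
               aln_len = numeric(0), stringsAsFactors = FALSE)
  list(records = records, skipped = skipped)
}

#' Parse an MD-style mismatch descriptor
#'
#' The descriptor alternates match lengths and substituted reference bases
#' (`^` introduces a deletion, flagged but not expanded).
#'
#' @param md descriptor string, e.g. `"0A24"`.
#' @return `NULL` on parse failure, else a list with `match_lens`,
#'   `sub_bases` (reference bases at substitutions, in order), `aln_len`,
#'   `has_indel`.
#' @export
parse_md <- function(md) {
  if (!grepl("^[0-9]+([A-Z^][A-Z]*[0-9]+)*$", md)) {
    if (!grepl("^([0-9]+|[A-Z]|\\^[A-Z]+)+$", md)) return(NULL)
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != md) return(NULL)
  has_indel <- any(startsWith(toks, "^"))
  nums <- suppressWarnings(as.numeric(toks[grepl("^[0-9]+$", toks)]))
  subs <- toks[grepl("^[A-Z]$", toks)]
  list(match_lens = nums, sub_bases = subs,
       aln_len = sum(nums) + length(subs), has_indel = has_indel)
}

#' Write alignment fixtures as SAM text
#'
#' @param records data frame with `chrom`, `pos` (0-based leftmost), `strand`,
#'   `seq`, `md`.
#' @param path output path.
#' @param chrom_lengths optional named lengths for `@SQ` headers.
#' @export
write_alignments <- function(records, path, chrom_lengths = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  if (nrow(records)) {
    flag <- ifelse(records$strand == "+", 0L, 16L)
    writeLines(sprintf("read%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tMD:Z:%s",
                       seq_len(nrow(records)), flag, records$chrom,
                       as.integer(records$pos) + 1L, nchar(records$seq),
                       records$seq, records$md), con)
  }
  invisible(path)
}
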