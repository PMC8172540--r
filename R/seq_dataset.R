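#' Extract the sequence window centered on an STR 3' end
#'
#' The window spans `(width-1)/2` bases upstream of, plus, and `(width-1)/2`
#' bases downstream of the 3'-end base, in transcript orientation ((-)-strand
#' windows are reverse-complemented, so the center column is always the
#' 3'-end base and upstream is always to the left).
#'
#' @param store sequence store (named character vector).
#' @param oriented_str one-row oriented STR (needs `chrom`, `strand`,
#'   `three_prime_end` 1-based).
#' @param width odd window width in bp (default 101).
#' @return character scalar, or `NA` when the window extends past a
#'   chromosome edge (skip-and-log contract).
#' @export
extract_window <- function(store, oriented_str, width = 101L) {
  if (width %% 2 == 0) stop("window width must be odd")
  h <- (width - 1) / 2
  t0 <- oriented_str$three_prime_end[1] - 1   # 0-based 3'-end base
  ch <- oriented_str$chrom[1]
  L <- nchar(store[[ch]])
  lo <- t0 - h; hi <- t0 + h + 1
  if (lo < 0 || hi > L) return(NA_character_)
  seq <- substr(store[[ch]], lo + 1, hi)
  if (oriented_str$strand[1] == "-") revcomp(seq) else seq
}

#' One-hot encode a DNA sequence
#'
#' Fixed row order A, C, G, T; `N` (and masked bases) become all-zero
#' columns.
#'
#' @param seq character scalar over `{A,C,G,T,N}`.
#' @return numeric 4 x nchar(seq) matrix with rownames A/C/G/T.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N"))
    stop("one_hot: invalid character(s): ",
         paste(unique(chars[is.na(idx) & chars != "N"]), collapse = ","))
  m <- matrix(0, nrow = 4, ncol = length(chars),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- 1
  m
}

#' Decode a one-hot matrix back to sequence
#' @param m 4 x W one-hot matrix (zero columns decode to `N`).
#' @return character scalar.
#' @export
one_hot_decode <- function(m) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(ncol(m)), function(j) {
    k <- which(m[, j] == 1)
    if (length(k) == 1) bases[k] else "N"
  }, character(1)), collapse = "")
}

#' Mask a window according to a masking scheme
#'
#' * `none`: identity.
#' * `downstream7`: the 7 bases immediately 3' of the STR end (window
#'   positions center+1 .. center+7) become `N` — they can contain repeat
#'   bases, a trivially learnable give-away for classification.
#' * `flank_only`: rebuilt layout of 50 bp upstream flank + 9 `N` (the whole
#'   STR, regardless of its true length) + 7 `N` + 43 bp downstream flank,
#'   total 109 bp; needs `store` to reach the upstream flank of STRs longer
#'   than the window.
#'
#' @param seq_window window from [extract_window()] (ignored for
#'   `flank_only`).
#' @param oriented_str the one-row oriented STR the window belongs to.
#' @param scheme one of `"none"`, `"downstream7"`, `"flank_only"`.
#' @param store sequence store; required for `flank_only`.
#' @return masked sequence (length 109 for `flank_only`), or `NA` if a
#'   flank extends past a chromosome edge.
#' @export
apply_mask <- function(seq_window, oriented_str, scheme = "none",
                       store = NULL) {
  scheme <- match.arg(scheme, c("none", "downstream7", "flank_only"))
  if (scheme == "none") return(seq_window)
  if (scheme == "downstream7") {
    w <- nchar(seq_window)
    if (w %% 2 == 0) stop("downstream7 expects an odd-width window")
    center <- (w + 1) / 2
    if (center + 7 > w) stop("window too narrow for downstream7 mask")
    substr(seq_window, center + 1, center + 7) <-
      paste(rep("N", 7), collapse = "")
    return(seq_window)
  }
  # flank_only
  if (is.null(store)) stop("flank_only masking needs the sequence store")
  ch <- oriented_str$chrom[1]
  L <- nchar(store[[ch]])
  if (oriented_str$strand[1] == "+") {
    up_lo <- oriented_str$start[1] - 50; up_hi <- oriented_str$start[1]
    dn_lo <- oriented_str$end[1] + 7; dn_hi <- oriented_str$end[1] + 50
    if (up_lo < 0 || dn_hi > L) return(NA_character_)
    up <- substr(store[[ch]], up_lo + 1, up_hi)
    dn <- substr(store[[ch]], dn_lo + 1, dn_hi)
  } else {
    up_lo <- oriented_str$end[1]; up_hi <- oriented_str$end[1] + 50
    dn_lo <- oriented_str$start[1] - 50; dn_hi <- oriented_str$start[1] - 7
    if (dn_lo < 0 || up_hi > L) return(NA_character_)
    up <- revcomp(substr(store[[ch]], up_lo + 1, up_hi))
    dn <- revcomp(substr(store[[ch]], dn_lo + 1, dn_hi))
  }
  paste0(up, paste(rep("N", 16), collapse = ""), dn)
}

#' Build an encoded dataset of STR windows
#'
#' Extracts, masks and one-hot encodes one window per oriented STR; rows of
#' the design matrix hold the flattened 4 x W encoding (columns grouped by
#' position: `(pos-1)*4 + base`). STRs whose window leaves the chromosome
#' are skipped and logged in the `skipped` attribute.
#'
#' @param store sequence store.
#' @param oriented oriented STR data frame (needs `signal`).
#' @param width window width (ignored for `flank_only`, which is 109).
#' @param mask masking scheme, see [apply_mask()].
#' @param target_transform `"identity"` or `"log1p"` applied to the signal
#'   to form the regression target.
#' @param labels optional class labels overriding the regression target.
#' @return object of class `str_dataset`: `X` (n x 4W matrix), `y`, `meta`
#'   (metadata rows of `oriented` kept), `width`, `mask`,
#'   `target_transform`.
#' @export
build_dataset <- function(store, oriented, width = 101L, mask = "none",
                          target_transform = c("identity", "log1p"),
                          labels = NULL) {
  target_transform <- match.arg(target_transform)
  n <- nrow(oriented)
  seqs <- .windows_vectorized(store, oriented, width, mask)
  keep <- !is.na(seqs)
  seqs <- seqs[keep]
  W <- if (length(seqs)) nchar(seqs[1]) else
    if (mask == "flank_only") 109L else width
  X <- encode_windows(seqs, W)
  y <- if (!is.null(labels)) labels[keep] else
    switch(target_transform, identity = oriented$signal[keep],
           log1p = log1p(oriented$signal[keep]))
  structure(list(X = X, y = y, meta = oriented[keep, , drop = FALSE],
                 width = W, mask = mask,
                 target_transform = if (is.null(labels)) target_transform
                 else "identity",
                 task = if (is.null(labels)) "regression" else
                   "classification"),
            class = "str_dataset",
            skipped = sum(!keep))
}

# Vectorised window construction; agrees with extract_window()/apply_mask()
# applied row-by-row (asserted in the test suite).
.windows_vectorized <- function(store, oriented, width, mask) {
  n <- nrow(oriented)
  seqs <- rep(NA_character_, n)
  if (!n) return(seqs)
  if (width %% 2 == 0) stop("window width must be odd")
  h <- (width - 1) / 2
  revcomp_vec <- function(x) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x)
    out[ok] <- revcomp(x[ok])
    out
  }
  if (mask != "flank_only") {
    t0 <- oriented$three_prime_end - 1
    lo <- t0 - h; hi <- t0 + h + 1
    for (ch in unique(oriented$chrom)) {
      L <- nchar(store[[ch]])
      k <- which(oriented$chrom == ch & lo >= 0 & hi <= L)
      if (!length(k)) next
      s <- substring(store[[ch]], lo[k] + 1, hi[k])
      neg <- oriented$strand[k] == "-"
      s[neg] <- revcomp_vec(s[neg])
      seqs[k] <- s
    }
    if (mask == "downstream7") {
      center <- h + 1
      ok <- !is.na(seqs)
      tmp <- seqs[ok]
      substr(tmp, center + 1, center + 7) <- strrep("N", 7)
      seqs[ok] <- tmp
    }
    return(seqs)
  }
  # flank_only: 50 upstream-flank + 16 N + 43 downstream-flank
  pos <- oriented$strand == "+"
  up_lo <- ifelse(pos, oriented$start - 50, oriented$end)
  up_hi <- ifelse(pos, oriented$start, oriented$end + 50)
  dn_lo <- ifelse(pos, oriented$end + 7, oriented$start - 50)
  dn_hi <- ifelse(pos, oriented$end + 50, oriented$start - 7)
  for (ch in unique(oriented$chrom)) {
    L <- nchar(store[[ch]])
    k <- which(oriented$chrom == ch & pmin(up_lo, dn_lo) >= 0 &
                 pmax(up_hi, dn_hi) <= L)
    if (!length(k)) next
    up <- substring(store[[ch]], up_lo[k] + 1, up_hi[k])
    dn <- substring(store[[ch]], dn_lo[k] + 1, dn_hi[k])
    neg <- !pos[k]
    up[neg] <- revcomp_vec(up[neg])
    dn[neg] <- revcomp_vec(dn[neg])
    seqs[k] <- paste0(up, strrep("N", 16), dn)
  }
  seqs
}

#' One-hot encode many equal-width windows into a design matrix
#'
#' @param seqs character vector of equal-length sequences.
#' @param W their common width.
#' @return numeric `length(seqs)` x `4*W` matrix, columns grouped by
#'   position.
#' @export
encode_windows <- function(seqs, W) {
  n <- length(seqs)
  X <- matrix(0, nrow = n, ncol = 4 * W)
  if (!n) return(X)
  if (any(nchar(seqs) != W)) stop("windows of unequal width")
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  idx <- match(chars, c("A", "C", "G", "T"))
  pos <- rep(seq_len(W), times = n)
  row <- rep(seq_len(n), each = W)
  ok <- !is.na(idx)
  X[cbind(row[ok], (pos[ok] - 1) * 4 + idx[ok])] <- 1
  X
}

#' Seeded train/validation/test split with a reproducibility manifest
#'
#' Sizes follow largest-remainder rounding of the fractions; re-running with
#' the manifest's seed and fractions reproduces the identical partition.
#'
#' @param n number of examples (or an `str_dataset`).
#' @param fractions length-3 positive vector summing to 1
#'   (train/validation/test).
#' @param seed integer seed.
#' @param manifest_path optional path; the manifest is written there as JSON.
#' @return list of class `dataset_split`: integer index vectors `train`,
#'   `validation`, `test`, plus `manifest`.
#' @export
make_split <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                       manifest_path = NULL) {
  if (inherits(n, "str_dataset")) n <- nrow(n$X)
  if (length(fractions) != 3L) stop("fractions must have length 3")
  if (any(fractions < 0) || fractions[1] <= 0)
    stop("fractions must be non-negative with a positive train fraction")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * fractions - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  split <- list(
    train = sort(perm[seq_len(sizes[1])]),
    validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  manifest <- list(n = n, fractions = fractions, seed = as.integer(seed),
                   sizes = as.integer(sizes))
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  structure(c(split, list(manifest = manifest)), class = "dataset_split")
}

#' Rebuild a split from its manifest
#' @param manifest manifest list or path to a manifest JSON.
#' @return the identical `dataset_split`.
#' @export
split_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  make_split(manifest$n, manifest$fractions, manifest$seed)
}

#' Subset a dataset by example indices
#' @param dataset an `str_dataset`.
#' @param idx integer indices.
#' @return the subset `str_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$X <- dataset$X[idx, , drop = FALSE]
  out$y <- dataset$y[idx]
  out$meta <- dataset$meta[idx, , drop = FALSE]
  out
}

#' Downsample the majority class to the minority size (seeded)
#' @param labels 0/1 vector.
#' @param seed integer seed.
#' @return integer indices of the balanced subset, sorted.
#' @export
balance_classes <- function(labels, seed = 1L) {
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (length(i0) > length(i1)) i0 <- sample(i0, length(i1))
  else if (length(i1) > length(i0)) i1 <- sample(i1, length(i0))
  sort(c(i0, i1))
}
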