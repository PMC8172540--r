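make_track <- function(lens, vals = list()) {
  trk <- coverage_track(lens)
  for (ch in names(vals)) trk$values[[ch]][seq_along(vals[[ch]])] <- vals[[ch]]
  trk
}

test_that("mean_coverage averages position-wise with absent positions as zero", {
  t1 <- make_track(c(c1 = 10), list(c1 = c(2, 0, 4)))
  expect_equal(mean_coverage(list(t1))$values$c1, t1$values$c1)
  t2 <- make_track(c(c1 = 10), list(c1 = c(4, 0, 0)))
  m <- mean_coverage(list(t1, t2))
  expect_equal(m$values$c1[1], 3)
  expect_equal(m$n_libraries, 2)
  expect_error(mean_coverage(list()), "at least one")
  # dense-array oracle on sparse random tracks
  set.seed(5)
  trks <- lapply(1:5, function(i) {
    trk <- coverage_track(c(c1 = 50))
    trk$values$c1[sample.int(50, 10)] <- runif(10)
    trk
  })
  dense <- Reduce(`+`, lapply(trks, function(t) t$values$c1)) / 5
  expect_equal(mean_coverage(trks)$values$c1, dense)
})

test_that("cage_signal implements sum over STR +/- 5 bp divided by L + 10", {
  str <- data.frame(chrom = "c1", start = 100, end = 110)  # L = 10
  trk <- make_track(c(c1 = 300))
  expect_equal(cage_signal(str, trk), 0)
  # single spike of mean count m inside the window: S = m / (L + 10)
  trk$values$c1[101] <- 3.5
  expect_equal(cage_signal(str, trk), 3.5 / 20)
  # uniform coverage c over the window gives S = c for any L
  for (L in c(4, 10, 37)) {
    s2 <- data.frame(chrom = "c1", start = 50, end = 50 + L)
    t2 <- make_track(c(c1 = 300))
    t2$values$c1[(50 - 5 + 1):(50 + L + 5)] <- 0.73
    expect_equal(cage_signal(s2, t2), 0.73)
  }
  # window half-open: position end+5 (0-based) is outside
  t3 <- make_track(c(c1 = 300))
  t3$values$c1[110 + 5 + 1] <- 9   # 0-based position 115 = end + 5
  expect_equal(cage_signal(str, t3), 0)
  t3$values$c1[110 + 5] <- 9       # 0-based position 114 = last in window
  expect_equal(cage_signal(str, t3), 9 / 20)
  # vectorised path agrees
  set.seed(6)
  trkr <- make_track(c(c1 = 300), list(c1 = runif(300)))
  strs <- data.frame(chrom = "c1", start = c(20, 100, 250),
                     end = c(30, 137, 260))
  expect_equal(cage_signal_many(strs, trkr),
               vapply(1:3, function(i)
                 cage_signal(strs[i, ], trkr), numeric(1)))
})

test_that("orientation reports the reference 3' ends and reverse-complemented class", {
  cat <- data.frame(chrom = "chr1", start = 10001, end = 10468, period = 6,
                    repeat_count = 78, name = "Human_STR_1", motif = "AACCCT",
                    str_class = "AACCCT", strand = "*",
                    stringsAsFactors = FALSE)
  trk <- coverage_track(c(chr1 = 11000))
  o <- orient_strs(cat, trk, trk)
  expect_equal(nrow(o), 2L)
  expect_equal(o$three_prime_end[o$strand == "+"], 10468)
  expect_equal(o$three_prime_end[o$strand == "-"], 10002)
  expect_equal(o$effective_motif[o$strand == "-"], "AGGGTT")
  expect_equal(o$class_key[o$strand == "-"], "AGGGTT")
  # n STRs -> exactly 2n oriented records
  ww <- small_world()
  o2 <- orient_strs(ww$world$catalog, ww$cov$plus, ww$cov$minus)
  expect_equal(nrow(o2), 2L * nrow(ww$world$catalog))
})

test_that("directionality follows (S+ - S-)/(S+ + S-) with the undefined marker", {
  expect_equal(directionality(1, 0), 1)
  expect_equal(directionality(0, 1), -1)
  expect_equal(directionality(0.4, 0.4), 0)
  expect_true(is.na(directionality(0, 0)))
  # the two signal values printed for the reference STR
  expect_equal(directionality(0.410901, 0.354298),
               (0.410901 - 0.354298) / (0.410901 + 0.354298), tolerance = 1e-12)
  expect_error(directionality(-1, 0), "non-negative")
  # antisymmetry and strand exchange
  set.seed(7)
  a <- runif(50); b <- runif(50)
  expect_equal(directionality(a, b), -directionality(b, a))
})

test_that("strand exchange swaps oriented signals and negates directionality", {
  ww <- small_world()
  cat10 <- ww$world$catalog[1:10, ]
  o1 <- orient_strs(cat10, ww$cov$plus, ww$cov$minus)
  o2 <- orient_strs(cat10, ww$cov$minus, ww$cov$plus)
  expect_equal(o1$signal[o1$strand == "+"], o2$signal[o2$strand == "-"])
  d1 <- directionality(o1$signal[o1$strand == "+"], o1$signal[o1$strand == "-"])
  d2 <- directionality(o2$signal[o2$strand == "+"], o2$signal[o2$strand == "-"])
  expect_equal(d1, -d2)
})

test_that("per-class anchor fractions use Wilson intervals and match brute force", {
  o <- data.frame(chrom = "c1", start = c(10, 50, 90, 130), end = c(20, 60, 100, 140),
                  strand = "+", class_key = "AC", name = letters[1:4],
                  stringsAsFactors = FALSE)
  anchors <- gintervals("c1", 12, 15)
  res <- class_peak_fraction(o, anchors, w = 0)
  expect_equal(res$fraction, 0.25)
  expect_equal(res$n, 4L)
  # Wilson interval, zero successes: lower bound 0
  wz <- wilson_ci(0, 10)
  expect_equal(wz[1], 0)
  z <- qnorm(0.975)
  expect_equal(wz[2], (z^2 / 10) / (1 + z^2 / 10) / 2 +
                 z * sqrt(z^2 / (4 * 100)) / (1 + z^2 / 10), tolerance = 1e-10)
  # random instance vs brute-force overlap counting
  set.seed(8)
  om <- random_intervals(80)
  om$class_key <- sample(c("AC", "AG"), 80, replace = TRUE)
  an <- random_intervals(30)
  got <- class_peak_fraction(om, an, w = 5)
  bo <- brute_overlap(om, an, w = 5)
  for (k in got$class_key) {
    sel <- which(om$class_key == k)
    expect_equal(got$n_overlap[got$class_key == k],
                 sum(sel %in% bo$a_idx))
  }
})

test_that("random baseline matches planted anchor density and edge cases", {
  strs <- gintervals(rep("c1", 50), (0:49) * 100, (0:49) * 100 + 10)
  strs$name <- paste0("s", 1:50)
  # anchors tiling the whole genome -> fraction 1
  tile <- gintervals("c1", 0, 6000)
  expect_equal(random_overlap_baseline(strs, tile, c(c1 = 6000),
                                       seed = 2)$fraction, 1)
  # empty anchor set -> fraction 0
  expect_equal(random_overlap_baseline(strs, tile[0, ], c(c1 = 6000),
                                       seed = 2)$fraction, 0)
  # anchors covering ~10% of a large genome -> fraction near 0.10
  set.seed(9)
  gs <- c(c1 = 2e5)
  anch <- gintervals(rep("c1", 100), (0:99) * 2000, (0:99) * 2000 + 190)
  iv <- gintervals(rep("c1", 400), 1:400, 2:401)  # lengths 1
  frac <- random_overlap_baseline(iv, anch, gs, seed = 3, w = 0)$fraction
  expect_gt(frac, 0.06); expect_lt(frac, 0.14)
})

test_that("compartment assignment covers the four detection cases", {
  expect_equal(compartment_assignment(1.2, 0), "nucleus")
  expect_equal(compartment_assignment(0, 0.7), "cytoplasm")
  expect_equal(compartment_assignment(0.5, 0.5), "both")
  expect_equal(compartment_assignment(0, 0), "undetected")
  expect_error(compartment_assignment(-1, 0), "non-negative")
  set.seed(10)
  nuc <- rbinom(200, 1, 0.5) * runif(200)
  cyt <- rbinom(200, 1, 0.5) * runif(200)
  got <- table(compartment_assignment(nuc, cyt))
  want <- table(ifelse(nuc > 0 & cyt > 0, "both",
                       ifelse(nuc > 0, "nucleus",
                              ifelse(cyt > 0, "cytoplasm", "undetected"))))
  expect_equal(got, want)
})

test_that("uniform coverage makes the signal independent of STR length", {
  for (L in c(6, 12, 24, 48)) {
    s <- data.frame(chrom = "c1", start = 100, end = 100 + L)
    trk <- coverage_track(c(c1 = 500))
    trk$values$c1[] <- 1.7
    expect_equal(cage_signal(s, trk), 1.7)
  }
})

test_that("oriented signal tables round-trip through the TSV writer", {
  ww <- small_world()
  o <- orient_strs(ww$world$catalog[1:5, ], ww$cov$plus, ww$cov$minus)
  f <- withr::local_tempfile()
  write_signal_table(o, f)
  back <- strinit:::.read_signal_table(f)
  expect_equal(back$signal, o$signal, tolerance = 1e-9)
  expect_equal(back$three_prime_end, o$three_prime_end)
  expect_equal(back$class_key, o$class_key)
})
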