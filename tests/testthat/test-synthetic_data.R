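test_that("an empty world has an empty catalog and zero coverage", {
  w0 <- generate_world(world_spec(n_str = 0,
                                  chrom_lengths = c(chr1 = 5000)), seed = 1)
  expect_equal(nrow(w0$catalog), 0L)
  cov0 <- generate_coverage(w0, seed = 2)
  expect_equal(sum(cov0$plus$values$chr1) + sum(cov0$minus$values$chr1), 0)
})

test_that("generated catalogs round-trip through the catalog reader", {
  ww <- small_world()
  f <- withr::local_tempfile()
  write_str_catalog(ww$world$catalog, f)
  back <- read_str_catalog(f)
  expect_equal(back$start, ww$world$catalog$start)
  expect_equal(back$motif, ww$world$catalog$motif)
  # STR bodies actually spell the motif
  i <- 5
  body <- extract_sequence(ww$world$store, ww$world$catalog[i, ], "+")
  expect_equal(body, strrep(ww$world$catalog$motif[i],
                            ww$world$catalog$repeat_count[i]))
  # STRs do not overlap
  o <- order(ww$world$catalog$chrom, ww$world$catalog$start)
  cc <- ww$world$catalog[o, ]
  same <- cc$chrom[-1] == cc$chrom[-nrow(cc)]
  expect_true(all(cc$start[-1][same] >= cc$end[-nrow(cc)][same]))
})

test_that("the noiseless limit reproduces the truth table exactly", {
  spec <- world_spec(n_str = 150, chrom_lengths = c(chr1 = 60000))
  m0 <- signal_model(noise_sigma = 0, scatter_rate = 0)
  w <- generate_world(spec, m0, seed = 3)
  cov <- generate_coverage(w, seed = 4)
  o <- orient_strs(w$catalog, cov$plus, cov$minus)
  key <- paste(o$name, o$strand)
  tkey <- paste(w$truth$name, w$truth$strand)
  expect_equal(o$signal, w$truth$expected_signal[match(key, tkey)],
               tolerance = 1e-9)
})

test_that("recomputed signals track the truth within the noise law", {
  ww <- small_world()
  o <- orient_strs(ww$world$catalog, ww$cov$plus, ww$cov$minus)
  key <- paste(o$name, o$strand)
  tkey <- paste(ww$cov$truth$name, ww$cov$truth$strand)
  s_obs <- ww$cov$truth$s_obs[match(key, tkey)]
  # the realized lognormal draw is recovered up to body scatter
  expect_true(all(o$signal >= s_obs - 1e-9))
  L <- o$end - o$start
  expect_true(all(o$signal - s_obs <= L / (L + 10) + 1e-9))
  # and correlates strongly with the generative expectation
  mu <- ww$cov$truth$mu[match(key, tkey)]
  expect_gt(cor(log(s_obs), mu), 0.9)
})

test_that("different seeds give different worlds with similar statistics", {
  s1 <- generate_world(world_spec(n_str = 300,
                                  chrom_lengths = c(chr1 = 80000)), seed = 5)
  s2 <- generate_world(world_spec(n_str = 300,
                                  chrom_lengths = c(chr1 = 80000)), seed = 6)
  expect_false(identical(s1$catalog$start, s2$catalog$start))
  expect_false(identical(s1$store, s2$store))
  # same class composition scale and signal distribution scale
  expect_equal(mean(s1$truth$mu), mean(s2$truth$mu), tolerance = 0.15)
  expect_equal(table(s1$catalog$motif) / 300, table(s2$catalog$motif) / 300,
               tolerance = 0.15)
  expect_identical(generate_world(world_spec(n_str = 50,
                                             chrom_lengths = c(chr1 = 30000)),
                                  seed = 7)$store,
                   generate_world(world_spec(n_str = 50,
                                             chrom_lengths = c(chr1 = 30000)),
                                  seed = 7)$store)
})

test_that("directional and balanced classes show the planted directionality", {
  ww <- small_world()
  o <- orient_strs(ww$world$catalog, ww$cov$plus, ww$cov$minus)
  d <- directionality(o$signal[o$strand == "+"], o$signal[o$strand == "-"])
  cls <- ww$world$catalog$motif
  expect_gt(median(abs(d[cls == "AC"]), na.rm = TRUE), 0.8)
  expect_lt(median(abs(d[cls == "AT"]), na.rm = TRUE), 0.2)
})

test_that("class flank composition is planted as specified", {
  ww <- small_world()
  cat <- ww$world$catalog
  gc_of <- function(rows) {
    fl <- vapply(rows, function(i) {
      up <- gintervals(cat$chrom[i], cat$start[i] - 50, cat$start[i])
      extract_sequence(ww$world$store, up, "+")
    }, character(1))
    mean(strsplit(paste(fl, collapse = ""), "")[[1]] %in% c("G", "C"))
  }
  gc_ac <- gc_of(which(cat$motif == "AC")[1:40])
  gc_at <- gc_of(which(cat$motif == "AT")[1:40])
  gc_ag <- gc_of(which(cat$motif == "AG")[1:40])
  gc_a4 <- gc_of(which(cat$motif == "AAAG")[1:40])
  expect_gt(gc_ac, 0.55); expect_lt(gc_at, 0.45)
  expect_equal(gc_ag, 0.5, tolerance = 0.08)
  expect_equal(gc_a4, 0.5, tolerance = 0.08)
})

test_that("variant truth follows the closed form and the positional law", {
  ww <- small_world()
  gv <- generate_variants(ww$world, n = 600, seed = 8,
                          targeted_fraction = 0)
  v <- gv$variants
  # variants outside any planted motif and outside the STR have zero effect
  expect_true(any(v$true_effect == 0))
  # destroying the planted upstream (activating) motif lowers the signal
  # (a chance second motif occurrence can leave a rare zero effect)
  gvu <- generate_variants(ww$world, n = 200, seed = 9,
                           targeted_fraction = 1, targeted_motif = 1)
  expect_true(all(gvu$variants$true_effect <= 0))
  expect_gt(mean(gvu$variants$true_effect < 0), 0.95)
  # destroying the planted downstream (repressive) motif raises it
  gvd <- generate_variants(ww$world, n = 200, seed = 10,
                           targeted_fraction = 1, targeted_motif = 2)
  expect_true(all(gvd$variants$true_effect >= 0))
  expect_gt(mean(gvd$variants$true_effect > 0), 0.95)
  # reference alleles always match the genome they were drawn from
  refs <- unname(substring(ww$world$store[v$chrom], v$pos, v$pos))
  expect_equal(refs, v$ref)
  expect_true(all(v$alt != v$ref))
  # untargeted offsets follow the exp(-|o|/10) law (chi-squared check)
  t0 <- ww$world$catalog$end[match(v$str_name, ww$world$catalog$name)] - 1
  off <- (v$pos - 1) - t0
  law <- -50:50
  pl <- exp(-abs(law) / 10); pl <- pl / sum(pl)
  bins <- cut(off, c(-51, -15, -5, 5, 15, 51))
  pbin <- tapply(pl, cut(law, c(-51, -15, -5, 5, 15, 51)), sum)
  chi <- suppressWarnings(chisq.test(table(bins), p = pbin))
  expect_gt(chi$p.value, 1e-4)
})

test_that("alignment fixtures are internally consistent at any rate", {
  anchors <- gintervals(rep("chr1", 50), (1:50) * 40 + 100,
                        (1:50) * 40 + 101, strand = "+")
  al <- generate_alignments(anchors, n_per_anchor = 4, cap_g_rate = 0.5,
                            seed = 11)
  # MD descriptors agree with the read lengths
  lens <- vapply(al$md, function(m) parse_md(m)$aln_len, numeric(1),
                 USE.NAMES = FALSE)
  expect_true(all(lens == nchar(al$seq)))
  # rate 0 fixtures carry no mismatch descriptors
  al0 <- generate_alignments(anchors, n_per_anchor = 4, seed = 12)
  expect_true(all(al0$md == "25"))
  expect_error(generate_alignments(anchors, cap_g_rate = 2), "cap_g_rate")
})

test_that("the Bayes predictor reproduces the generative expectation", {
  ww <- small_world()
  o <- orient_strs(ww$world$catalog, ww$cov$plus, ww$cov$minus)
  ds <- build_dataset(ww$world$store, o, 101)
  orc <- bayes_predictor(ww$world$model)
  p <- predict(orc, ds$X)
  tru <- ww$world$truth$expected_signal[match(
    paste(ds$meta$name, ds$meta$strand),
    paste(ww$world$truth$name, ww$world$truth$strand))]
  expect_equal(p, tru)
  # decode inverts the encoding
  expect_equal(decode_windows(ds$X[1:5, , drop = FALSE], 101),
               strinit:::.windows_vectorized(ww$world$store, o[1:5, ],
                                             101L, "none"))
})
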