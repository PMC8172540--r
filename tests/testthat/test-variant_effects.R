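test_that("variant-to-STR pairing follows the 50-bp window boundary", {
  strs <- gintervals("c1", 100, 110)  # 0-based [100, 110)
  # 1-based position end + 50 = 160 is the last in-window base
  v_in <- data.frame(chrom = "c1", pos = 160, ref = "A", alt = "C")
  v_out <- data.frame(chrom = "c1", pos = 161, ref = "A", alt = "C")
  expect_equal(nrow(map_variants_to_strs(v_in, strs)$pairs), 1L)
  m_out <- map_variants_to_strs(v_out, strs)
  expect_equal(nrow(m_out$pairs), 0L)
  expect_equal(m_out$unpaired_strs, 1L)
  # upstream boundary: start - 50 + 1 in 1-based coordinates
  v_up <- data.frame(chrom = "c1", pos = 51, ref = "A", alt = "C")
  expect_equal(nrow(map_variants_to_strs(v_up, strs)$pairs), 1L)
  v_up2 <- data.frame(chrom = "c1", pos = 50, ref = "A", alt = "C")
  expect_equal(nrow(map_variants_to_strs(v_up2, strs)$pairs), 0L)
  # random instance equals the brute-force scan
  set.seed(61)
  strs_r <- random_intervals(60)
  vpos <- sample.int(520, 80, replace = TRUE)
  vr <- data.frame(chrom = sample(c("c1", "c2"), 80, replace = TRUE),
                   pos = vpos, ref = "A", alt = "C")
  got <- map_variants_to_strs(vr, strs_r, w = 10)$pairs
  got <- got[order(got$str_idx, got$variant_idx), ]
  vint <- gintervals(vr$chrom, vr$pos - 1, vr$pos)
  want <- brute_overlap(strs_r, vint, w = 10)
  expect_equal(got$str_idx, want$a_idx, ignore_attr = TRUE)
  expect_equal(got$variant_idx, want$b_idx, ignore_attr = TRUE)
})

test_that("variant deltas respect alleles, strand and window membership", {
  ww <- small_world()
  world <- ww$world
  o <- orient_strs(world$catalog, ww$cov$plus, ww$cov$minus)
  orc <- bayes_predictor(world$model)
  # pick an STR carrying the planted downstream motif
  i <- which(world$truth$planted_down & world$truth$strand == "+")[1]
  ostr <- world$truth[i, ]
  t0 <- ostr$three_prime_end - 1
  p1 <- t0 + 20 + 2  # inside the planted motif
  refb <- substr(world$store[[ostr$chrom]], p1 + 1, p1 + 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  v <- data.frame(chrom = ostr$chrom, pos = p1 + 1, ref = refb, alt = altb)
  vd <- variant_delta(orc, world$store, ostr, v)
  expect_equal(vd$status, "ok")
  expect_equal(vd$relative_position, 22)
  # destroying the repressive downstream motif raises the prediction:
  # delta = ref - mut < 0
  expect_lt(vd$delta, 0)
  # alt equal to ref gives exactly zero
  v0 <- v; v0$alt <- refb
  expect_equal(variant_delta(orc, world$store, ostr, v0)$delta, 0)
  # reference mismatch is flagged and skipped
  vbad <- v; vbad$ref <- setdiff(c("A", "C", "G", "T"), c(refb, altb))[1]
  expect_equal(variant_delta(orc, world$store, ostr, vbad)$status,
               "ref_mismatch")
  # non-SNV skipped
  vind <- v; vind$alt <- "AC"
  expect_equal(variant_delta(orc, world$store, ostr, vind)$status, "not_snv")
  # outside the model window
  vfar <- v; vfar$pos <- v$pos + 200
  expect_equal(variant_delta(orc, world$store, ostr, vfar)$status,
               "outside_window")
  # a minus-strand twin mirrors the relative position
  j <- which(world$truth$name == ostr$name & world$truth$strand == "-")
  mstr <- world$truth[j, ]
  vdm <- variant_delta(orc, world$store, mstr, v)
  expect_equal(vdm$relative_position, (mstr$three_prime_end - 1) - p1)
})

test_that("group comparisons combine ANOVA with one-sided rank tests", {
  set.seed(62)
  g1 <- rnorm(60); g2 <- rnorm(60)
  res <- signal_group_comparison(list(a = g1, b = g2))
  expect_gt(res$pairwise$p[1], 0.05)  # identical distributions
  expect_equal(nrow(res$pairwise), 2L)
  # small-instance U statistic equals pair-counting enumeration
  x <- c(3, 1, 4, 1, 5); y <- c(2, 6, 2)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  w <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  expect_equal(unname(w$statistic), u)
  # planted one-SD shift is detected at FDR 0.05 in nearly all replicates
  hits <- mean(replicate(30, {
    hi <- rnorm(200, 1); lo <- rnorm(200, 0)
    r <- signal_group_comparison(list(high = hi, low = lo))
    p <- r$pairwise$p_adj[r$pairwise$greater == "high"]
    p < 0.05
  }))
  expect_gte(hits, 0.95)
  expect_error(signal_group_comparison(list(a = 1:5)), "at least 2")
  expect_error(signal_group_comparison(list(a = 1:5, b = 2)), "degenerate")
})

test_that("all-concordant sign tests reproduce the closed-form binomial p", {
  # one-sided binomial: 10 concordant out of 10 -> p = 2^-10
  expect_equal(binom.test(10, 10, 0.5, alternative = "greater")$p.value,
               2^-10)
  ww <- small_world()
  world <- ww$world
  o <- orient_strs(world$catalog, ww$cov$plus, ww$cov$minus)
  gv <- generate_variants(world, n = 120, seed = 63, targeted_fraction = 1)
  orc <- bayes_predictor(world$model)
  res <- eqtl_sign_concordance(orc, world$store, gv$variants, o,
                               gv$gene_starts)
  expect_false(is.null(res$cases))
  # conservation: strata counts sum to the evaluated cases
  expect_equal(sum(res$strata$n_same + res$strata$n_different),
               nrow(res$cases))
  # the oracle gets essentially every targeted sign right
  conc <- sum(res$strata$n_same) / nrow(res$cases)
  expect_gt(conc, 0.9)
  expect_true(all(res$strata$p_value >= 0 & res$strata$p_value <= 1))
  # reference-allele mismatches cannot occur on self-generated data
  expect_equal(unname(res$n_skipped["ref_mismatch"]), 0L)
  # empty eligible set is reported with a reason
  res0 <- eqtl_sign_concordance(orc, world$store,
                                gv$variants[0, ], o, gv$gene_starts)
  expect_equal(res0$reason, "zero eligible cases")
})

test_that("concordance degrades monotonically with sign noise", {
  ww <- small_world()
  world <- ww$world
  o <- orient_strs(world$catalog, ww$cov$plus, ww$cov$minus)
  orc <- bayes_predictor(world$model)
  conc <- vapply(c(0, 0.25, 0.5), function(sn) {
    gv <- generate_variants(world, n = 150, seed = 64,
                            targeted_fraction = 1, sign_noise = sn)
    r <- eqtl_sign_concordance(orc, world$store, gv$variants, o,
                               gv$gene_starts)
    sum(r$strata$n_same) / nrow(r$cases)
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
  expect_lt(conc[3], 0.65)  # full sign noise sits near chance
})

test_that("label enrichment uses Fisher tests with BH adjustment", {
  # table (2,8 ; 10,80): cross-product odds ratio 2.0
  members <- c(rep("x", 2), rep("other", 8))
  background <- c(rep("x", 10), rep("other", 80))
  res <- set_enrichment(members, background, labels = "x")
  expect_equal(res$odds_ratio, 2.0)
  expect_equal(res$p, fisher.test(matrix(c(2, 8, 10, 80), 2,
                                         byrow = TRUE))$p.value)
  # Fisher p is symmetric under transposition of the 2x2 table
  expect_equal(fisher.test(matrix(c(2, 8, 10, 80), 2))$p.value,
               fisher.test(t(matrix(c(2, 8, 10, 80), 2)))$p.value)
  # null calibration: p roughly uniform under independence
  set.seed(65)
  ps <- replicate(200, {
    mem <- sample(c("x", "y"), 40, replace = TRUE)
    bg <- sample(c("x", "y"), 400, replace = TRUE)
    set_enrichment(mem, bg, labels = "x")$p
  })
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
})
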