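tiny_reg_data <- function(n = 400, width = 41, seed = 1) {
  # planted additive motif effect: presence of an 6-mer raises the target
  set.seed(seed)
  seqs <- random_dna(n, width)
  plant <- runif(n) < 0.5
  pos <- sample(1:(width - 6), n, replace = TRUE)
  for (i in which(plant)) substr(seqs[i], pos[i], pos[i] + 5) <- "TATAAT"
  y <- ifelse(grepl("TATAAT", seqs, fixed = TRUE), 1, 0) + rnorm(n, 0, 0.1)
  list(X = encode_windows(seqs, width), y = y, seqs = seqs)
}

test_that("model building is deterministic and task-agnostic in size", {
  sr <- model_spec(101, "regression")
  sc <- model_spec(101, "classification")
  mr <- build_model(sr, seed = 4); mc <- build_model(sc, seed = 4)
  expect_equal(mr$n_parameters, mc$n_parameters)
  expect_identical(mr$weights, build_model(sr, seed = 4)$weights)
  expect_false(identical(mr$weights, build_model(sr, seed = 5)$weights))
  # forward pass on an all-zero matrix returns a finite scalar
  z <- matrix(0, 1, 4 * 101)
  expect_true(is.finite(predict(mr, z)))
  expect_error(model_spec(101, dropout = 1), "dropout")
  expect_error(model_spec(10, kernel_width = 12), "wider")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(31)
  spec <- model_spec(21, n_filters = 3, kernel_width = 5, pool_width = 2,
                     fc_sizes = c(4), dropout = 0)
  m <- build_model(spec, seed = 2)
  Xt <- t(encode_windows(random_dna(6, 21), 21))
  y <- rnorm(6)
  fw <- strinit:::.forward(m, Xt, keep_cache = TRUE)
  lg <- strinit:::.loss_grad(m, fw$out, y)
  gr <- strinit:::.backward(m, lg$dout, fw$cache)
  for (nm in names(m$weights)) {
    for (i in sample(length(m$weights[[nm]]), min(4, length(m$weights[[nm]])))) {
      eps <- 1e-6; w2 <- m
      w2$weights[[nm]][i] <- w2$weights[[nm]][i] + eps
      l1 <- strinit:::.loss_grad(w2, strinit:::.forward(w2, Xt)$out, y)$loss
      w2$weights[[nm]][i] <- w2$weights[[nm]][i] - 2 * eps
      l0 <- strinit:::.loss_grad(w2, strinit:::.forward(w2, Xt)$out, y)$loss
      expect_equal(gr[[nm]][i], (l1 - l0) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training fits constant targets and stops by patience", {
  d <- tiny_reg_data(120, seed = 2)
  const <- list(X = d$X, y = rep(2.5, 120))
  fit <- train_model(build_model(model_spec(41, fc_sizes = c(8),
                                            dropout = 0), 1),
                     const, const, train_config(max_epochs = 60,
                                                batch_size = 32, seed = 1))
  expect_lt(utils::tail(fit$log$train_loss, 1), 0.01)
  # zero learning rate: validation never improves after epoch 1,
  # so training stops at exactly 1 + patience epochs
  fit0 <- train_model(build_model(model_spec(41, dropout = 0), 1),
                      const, const,
                      train_config(learning_rate = 0, max_epochs = 50,
                                   patience = 5, seed = 1))
  expect_equal(fit0$stopped_epoch, 6L)
  expect_equal(nrow(fit0$log), 6L)
  expect_error(train_config(patience = 0), "patience")
})

test_that("training is reproducible run-to-run with a fixed seed", {
  d <- tiny_reg_data(200, seed = 3)
  tr <- list(X = d$X[1:150, ], y = d$y[1:150])
  va <- list(X = d$X[151:200, ], y = d$y[151:200])
  cfg <- train_config(max_epochs = 4, patience = 10, batch_size = 64, seed = 7)
  f1 <- train_model(build_model(model_spec(41), 1), tr, va, cfg)
  f2 <- train_model(build_model(model_spec(41), 1), tr, va, cfg)
  expect_equal(f1$log, f2$log, tolerance = 1e-6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-8)
})

test_that("prediction is deterministic, order-preserving and batch-invariant", {
  d <- tiny_reg_data(50, seed = 4)
  m <- build_model(model_spec(41), 1)
  p1 <- predict(m, d$X); p2 <- predict(m, d$X)
  expect_identical(p1, p2)
  perm <- sample(50)
  expect_equal(predict(m, d$X[perm, ]), p1[perm])
  expect_equal(predict(m, d$X, batch_size = 7), p1)
  expect_error(predict(m, d$X[, 1:40]), "width mismatch")
})

test_that("rank-correlation evaluation matches the explicit rank formula", {
  expect_equal(eval_regression(c(1, 2, 3), c(10, 20, 30))$value, 1)
  expect_equal(eval_regression(c(1, 2, 3), c(3, 2, 1))$value, -1)
  expect_true(is.na(eval_regression(rep(1, 5), 1:5)$value))
  set.seed(41)
  for (i in 1:20) {
    x <- sample(1:8, 20, replace = TRUE)  # forces ties
    y <- rnorm(20)
    expect_equal(eval_regression(x, y)$value, naive_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(eval_regression(1:2, 1:2), "at least 3")
})

test_that("AUC equals exhaustive concordant-pair counting", {
  expect_equal(eval_classification(c(1, 2, 9, 10), c(0, 0, 1, 1))$value, 1)
  expect_equal(eval_classification(rep(1, 6), c(0, 1, 0, 1, 0, 1))$value, 0.5)
  expect_error(eval_classification(1:3, c(1, 1, 1)), "both classes")
  set.seed(42)
  for (i in 1:20) {
    sc <- sample(1:6, 30, replace = TRUE)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(eval_classification(sc, lb)$value, naive_auc(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("the randomized baseline collapses to the null scale", {
  set.seed(43)
  y <- rnorm(10000)
  rhos <- randomized_baseline(y, reps = 10, seed = 3)
  expect_lt(max(rhos), 0.05)
  expect_identical(rhos, randomized_baseline(y, reps = 10, seed = 3))
  # identity permutation hook gives exactly 1
  expect_equal(randomized_baseline(y, reps = 1, seed = 1,
                                   perm_fn = function(n) seq_len(n)), 1)
})

test_that("grid search trains every combination and returns the max", {
  d <- tiny_reg_data(240, seed = 5)
  tr <- list(X = d$X[1:160, ], y = d$y[1:160])
  va <- list(X = d$X[161:240, ], y = d$y[161:240])
  cfg <- train_config(max_epochs = 3, patience = 10, batch_size = 64, seed = 2)
  one <- grid_search(list(n_filters = 8), tr, va, 41, config = cfg)
  expect_equal(one$best_spec$n_filters, 8L)
  expect_equal(nrow(one$leaderboard), 1L)
  gs <- grid_search(list(n_filters = c(4, 8), kernel_width = c(6, 10)),
                    tr, va, 41, config = cfg)
  expect_equal(nrow(gs$leaderboard), 4L)
  best_val <- max(gs$leaderboard$validation_metric)
  got <- gs$leaderboard$validation_metric[
    gs$leaderboard$n_filters == gs$best_spec$n_filters &
      gs$leaderboard$kernel_width == gs$best_spec$kernel_width]
  expect_equal(got, best_val)
  expect_error(grid_search(list(), tr, va, 41), "empty")
})

test_that("cross-apply fills the model-by-dataset matrix in both orders", {
  d1 <- tiny_reg_data(150, seed = 6); d2 <- tiny_reg_data(150, seed = 7)
  cfg <- train_config(max_epochs = 2, patience = 10, batch_size = 64, seed = 1)
  m1 <- train_model(build_model(model_spec(41), 1),
                    list(X = d1$X[1:100, ], y = d1$y[1:100]),
                    list(X = d1$X[101:150, ], y = d1$y[101:150]), cfg)
  m2 <- train_model(build_model(model_spec(41), 2),
                    list(X = d2$X[1:100, ], y = d2$y[1:100]),
                    list(X = d2$X[101:150, ], y = d2$y[101:150]), cfg)
  mats <- cross_apply(list(a = m1, b = m2),
                      list(a = list(X = d1$X, y = d1$y),
                           b = list(X = d2$X, y = d2$y)))
  expect_equal(dim(mats), c(2L, 2L))
  expect_true(all(is.finite(mats)))
  # the matrix is not assumed symmetric: both orders are computed
  expect_false(isTRUE(all.equal(mats["a", "b"], mats["b", "a"])))
  # 1x1 case reduces to eval_regression
  one <- cross_apply(list(a = m1), list(a = list(X = d1$X, y = d1$y)))
  expect_equal(one[1, 1],
               eval_regression(predict(m1, d1$X, type = "raw"), d1$y)$value)
  # width-incompatible cells are NA, run continues
  d3 <- tiny_reg_data(20, width = 21, seed = 8)
  mats2 <- cross_apply(list(a = m1), list(a = list(X = d1$X, y = d1$y),
                                          w = list(X = d3$X, y = d3$y)))
  expect_true(is.na(mats2[1, "w"]))
  expect_false(is.na(mats2[1, "a"]))
})

test_that("a planted-motif regression task is recovered near its ceiling", {
  d <- tiny_reg_data(2000, seed = 9)
  tr <- list(X = d$X[1:1400, ], y = d$y[1:1400])
  va <- list(X = d$X[1401:1700, ], y = d$y[1401:1700])
  te <- list(X = d$X[1701:2000, ], y = d$y[1701:2000])
  spec <- model_spec(41, n_filters = 20, kernel_width = 6, pool_width = 36,
                     fc_sizes = c(16), dropout = 0)
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 100,
                      batch_size = 64, seed = 3)
  fit <- train_model(build_model(spec, 3), tr, va, cfg)
  rho <- eval_regression(predict(fit, te$X, type = "raw"), te$y)$value
  # the binary planted indicator ties the achievable Spearman; compare
  # against the ceiling the noiseless indicator itself reaches
  pres <- as.numeric(grepl("TATAAT", d$seqs[1701:2000], fixed = TRUE))
  ceiling_rho <- cor(pres, te$y, method = "spearman")
  expect_gt(rho, 0.78 * ceiling_rho)
  # shuffled labels: no signal to learn
  set.seed(10)
  trs <- list(X = tr$X, y = sample(tr$y))
  fit0 <- train_model(build_model(spec, 3), trs, va,
                      train_config(max_epochs = 5, batch_size = 64,
                                   seed = 3))
  rho0 <- eval_regression(predict(fit0, te$X, type = "raw"), te$y)$value
  expect_lt(abs(rho0), 0.15)
})

test_that("models persist to a versioned text archive and reload exactly", {
  d <- tiny_reg_data(100, seed = 11)
  fit <- train_model(build_model(model_spec(41), 1),
                     list(X = d$X[1:80, ], y = d$y[1:80]),
                     list(X = d$X[81:100, ], y = d$y[81:100]),
                     train_config(max_epochs = 2, batch_size = 32, seed = 1),
                     target_transform = "log1p")
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  expect_equal(predict(back, d$X), predict(fit, d$X))
  expect_equal(back$target_transform, "log1p")
  expect_equal(back$spec$n_filters, fit$spec$n_filters)
})
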