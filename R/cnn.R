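#' Specification of a small sequence convolutional network
#'
#' One convolution stage over the one-hot sequence (rectifier activation,
#' max-pooling), fully-connected stages with dropout, and a single output
#' unit: linear for signal regression, sigmoid for pairwise classification.
#' The two tasks differ only in that final unit, so their parameter counts
#' are identical.
#'
#' @param input_width window width in bp.
#' @param task `"regression"` or `"classification"`.
#' @param n_filters first-stage filter count (default 50).
#' @param kernel_width filter width in bp (default 12).
#' @param pool_width max-pooling width (default 4).
#' @param fc_sizes sizes of the fully-connected stages (default `c(64, 16)`).
#' @param dropout dropout probability on fully-connected layers (default
#'   0.30).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(input_width, task = c("regression", "classification"),
                       n_filters = 50L, kernel_width = 12L, pool_width = 4L,
                       fc_sizes = c(64L, 16L), dropout = 0.30) {
  task <- match.arg(task)
  if (n_filters < 1) stop("need at least one convolution filter")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (kernel_width > input_width) stop("kernel wider than input")
  n_conv <- input_width - kernel_width + 1
  n_pool <- n_conv %/% pool_width
  if (n_pool < 1) stop("pooling width exceeds the convolution output")
  structure(list(input_width = as.integer(input_width), task = task,
                 n_filters = as.integer(n_filters),
                 kernel_width = as.integer(kernel_width),
                 pool_width = as.integer(pool_width),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout,
                 n_conv = as.integer(n_conv), n_pool = as.integer(n_pool)),
            class = "model_spec")
}

#' Build an untrained model with deterministic initialization
#'
#' He-scaled normal initialization for rectified layers; the same seed gives
#' bit-identical initial weights.
#'
#' @param spec a `model_spec`.
#' @param seed integer seed for the initialization.
#' @return list of class `str_cnn` with `spec`, `weights`,
#'   `n_parameters`, `target_transform` (set at training time).
#' @export
build_model <- function(spec, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  k4 <- 4L * spec$kernel_width
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  weights <- list(Wc = he(k4, spec$n_filters), bc = numeric(spec$n_filters))
  nin <- spec$n_pool * spec$n_filters
  for (i in seq_along(spec$fc_sizes)) {
    weights[[paste0("W", i)]] <- he(nin, spec$fc_sizes[i])
    weights[[paste0("b", i)]] <- numeric(spec$fc_sizes[i])
    nin <- spec$fc_sizes[i]
  }
  weights$Wout <- he(nin, 1L)
  weights$bout <- 0
  npar <- sum(vapply(weights, length, numeric(1)))
  structure(list(spec = spec, weights = weights, n_parameters = npar,
                 target_transform = "identity", init_seed = as.integer(seed)),
            class = "str_cnn")
}

#' @export
print.str_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "str_cnn (%s): %d-bp input, %d filters x %d bp, pool %d, fc [%s], dropout %.2f, %d parameters%s\n",
    s$task, s$input_width, s$n_filters, s$kernel_width, s$pool_width,
    paste(s$fc_sizes, collapse = ", "), s$dropout, x$n_parameters,
    if (!is.null(x$log)) sprintf(", trained %d epoch(s)", nrow(x$log)) else
      " (untrained)"))
  invisible(x)
}

.conv_index <- function(spec) {
  # column indices gathering each kernel placement from the flattened
  # (position-major, 4 bases per position) design matrix
  k4 <- 4L * spec$kernel_width
  outer(seq_len(k4), (seq_len(spec$n_conv) - 1L) * 4L, `+`)
}

# Internally examples live in columns (transposed layout): the convolution
# gather, pooling and bias additions then work along the fast (first)
# dimension with no aperm/array copies on the hot path. Xt is 4W x m.
.forward <- function(model, Xt, dropout_masks = NULL, ablate = NULL,
                     keep_cache = FALSE) {
  s <- model$spec; w <- model$weights
  m <- ncol(Xt)
  k4 <- 4L * s$kernel_width
  idx <- .conv_index(s)
  Xc <- Xt[as.vector(idx), , drop = FALSE]     # (k4*n_conv) x m
  dim(Xc) <- c(k4, s$n_conv * m)
  P <- crossprod(w$Wc, Xc) + w$bc              # F x (n_conv*m)
  A <- P * (P > 0)
  if (!is.null(ablate)) A[ablate, ] <- 0
  used <- s$n_pool * s$pool_width
  if (used < s$n_conv) {
    dim(A) <- c(s$n_filters, s$n_conv, m)
    Au <- A[, seq_len(used), , drop = FALSE]
    dim(A) <- c(s$n_filters, s$n_conv * m)
  } else Au <- A
  dim(Au) <- c(s$n_filters * s$pool_width, s$n_pool * m)
  Fi <- s$n_filters
  M <- Au[seq_len(Fi), , drop = FALSE]
  for (r in seq_len(s$pool_width)[-1])
    M <- pmax(M, Au[(r - 1L) * Fi + seq_len(Fi), , drop = FALSE])
  Mflat <- M
  dim(Mflat) <- c(Fi * s$n_pool, m)
  H <- Mflat
  Hs <- list()
  for (i in seq_along(s$fc_sizes)) {
    Z <- crossprod(w[[paste0("W", i)]], H) + w[[paste0("b", i)]]
    H <- Z * (Z > 0)
    if (!is.null(dropout_masks)) H <- H * dropout_masks[[i]]
    Hs[[i]] <- H
  }
  out <- drop(crossprod(w$Wout, H)) + w$bout
  res <- list(out = out)
  if (keep_cache)
    res$cache <- list(Xc = Xc, P = P, Au = Au, M = M, Mflat = Mflat,
                      Hs = Hs, m = m, used = used)
  res
}

# dout is a 1 x m matrix of loss gradients w.r.t. the output
.backward <- function(model, dout, cache, dropout_masks = NULL) {
  s <- model$spec; w <- model$weights
  m <- cache$m; Fi <- s$n_filters
  grads <- list()
  H_last <- if (length(s$fc_sizes)) cache$Hs[[length(s$fc_sizes)]] else
    cache$Mflat
  grads$Wout <- tcrossprod(H_last, dout)
  grads$bout <- sum(dout)
  dH <- w$Wout %*% dout
  for (i in rev(seq_along(s$fc_sizes))) {
    H <- cache$Hs[[i]]
    if (!is.null(dropout_masks)) dH <- dH * dropout_masks[[i]]
    dZ <- dH * (H > 0)
    H_prev <- if (i > 1) cache$Hs[[i - 1]] else cache$Mflat
    grads[[paste0("W", i)]] <- tcrossprod(H_prev, dZ)
    grads[[paste0("b", i)]] <- rowSums(dZ)
    dH <- w[[paste0("W", i)]] %*% dZ
  }
  dM <- dH
  dim(dM) <- c(Fi, s$n_pool * m)
  # route pooled gradients back to (tied) maxima
  masks <- vector("list", s$pool_width)
  cnt <- 0
  for (r in seq_len(s$pool_width)) {
    masks[[r]] <- (cache$Au[(r - 1L) * Fi + seq_len(Fi), , drop = FALSE] ==
                     cache$M)
    cnt <- cnt + masks[[r]]
  }
  share <- dM / cnt
  dAu <- matrix(0, Fi * s$pool_width, s$n_pool * m)
  for (r in seq_len(s$pool_width))
    dAu[(r - 1L) * Fi + seq_len(Fi), ] <- share * masks[[r]]
  if (cache$used < s$n_conv) {
    dA <- array(0, dim = c(Fi, s$n_conv, m))
    dim(dAu) <- c(Fi, cache$used, m)
    dA[, seq_len(cache$used), ] <- dAu
    dim(dA) <- c(Fi, s$n_conv * m)
  } else {
    dA <- dAu
    dim(dA) <- c(Fi, s$n_conv * m)
  }
  dP <- dA * (cache$P > 0)
  grads$Wc <- tcrossprod(cache$Xc, dP)
  grads$bc <- rowSums(dP)
  grads
}

.loss_grad <- function(model, out, y) {
  m <- length(y)
  if (model$spec$task == "regression") {
    diff <- out - y
    list(loss = mean(diff^2), dout = matrix(2 * diff / m, nrow = 1))
  } else {
    p <- 1 / (1 + exp(-out))
    eps <- 1e-12
    list(loss = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
         dout = matrix((p - y) / m, nrow = 1))
  }
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size minibatch size (default 256).
#' @param max_epochs epoch cap (default 100).
#' @param patience epochs without validation improvement before stopping
#'   (default 5; the weights from the best validation epoch are kept).
#' @param seed seed governing shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256L,
                         max_epochs = 100L, patience = 5L, seed = 1L) {
  if (patience < 1) stop("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Train a model with Adam, minibatches and early stopping
#'
#' Training stops when the validation loss has failed to improve on its best
#' value for `patience` consecutive epochs, or at `max_epochs`; the weights
#' of the best-validation epoch are retained. Non-finite losses abort with
#' diagnostics. Fully deterministic given `config$seed`.
#'
#' @param model an untrained (or trained) `str_cnn`.
#' @param train_data,val_data lists with `X` (n x 4W matrix) and `y`.
#' @param config a [train_config()].
#' @param target_transform transform already applied to `y` (recorded so
#'   [predict.str_cnn()] can invert it): `"identity"` or `"log1p"`.
#' @return the trained `str_cnn`, with `log` (per-epoch train/validation
#'   loss data frame) and `stopped_epoch`.
#' @export
train_model <- function(model, train_data, val_data, config = train_config(),
                        target_transform = c("identity", "log1p")) {
  target_transform <- match.arg(target_transform)
  if (!nrow(train_data$X) || !nrow(val_data$X))
    stop("train and validation sets must be non-empty")
  s <- model$spec
  w <- model$weights
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  mstate <- lapply(w, function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0
  n <- nrow(train_data$X)
  Xt_train <- t(train_data$X)
  Xt_val <- t(val_data$X)
  best_val <- Inf; best_w <- w; bad <- 0L
  log_tr <- numeric(0); log_va <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      rows <- perm[((bi - 1) * config$batch_size + 1):
                     min(bi * config$batch_size, n)]
      Xb <- Xt_train[, rows, drop = FALSE]
      yb <- train_data$y[rows]
      masks <- NULL
      if (s$dropout > 0) {
        keep <- 1 - s$dropout
        masks <- lapply(s$fc_sizes, function(sz)
          matrix(stats::rbinom(length(rows) * sz, 1, keep) / keep,
                 sz, length(rows)))
      }
      model$weights <- w
      fw <- .forward(model, Xb, dropout_masks = masks, keep_cache = TRUE)
      lg <- .loss_grad(model, fw$out, yb)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
             " (learning rate ", config$learning_rate, ")")
      ep_loss <- ep_loss + lg$loss * length(rows)
      grads <- .backward(model, lg$dout, fw$cache, dropout_masks = masks)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in names(w)) {
        g <- grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        w[[nm]] <- w[[nm]] - config$learning_rate * corr * mstate[[nm]] /
          (sqrt(vstate[[nm]]) + eps)
      }
    }
    model$weights <- w
    val_out <- .forward(model, Xt_val)$out
    val_loss <- .loss_grad(model, val_out, val_data$y)$loss
    log_tr <- c(log_tr, ep_loss / n); log_va <- c(log_va, val_loss)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_w <- w; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model$weights <- best_w
  model$target_transform <- target_transform
  model$log <- data.frame(epoch = seq_along(log_tr), train_loss = log_tr,
                          validation_loss = log_va)
  model$stopped_epoch <- length(log_tr)
  model$best_validation_loss <- best_val
  model
}

#' Predict from a trained model
#'
#' Deterministic (dropout disabled) and order-preserving.
#'
#' @param object a `str_cnn`.
#' @param X design matrix (n x 4W) or an `str_dataset`.
#' @param type `"response"` (natural signal scale / class probability) or
#'   `"raw"` (model output before inverse transform / sigmoid).
#' @param ablate optional first-stage filter indices whose activation maps
#'   are zeroed.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.str_cnn <- function(object, X, type = c("response", "raw"),
                            ablate = NULL, batch_size = 4096L, ...) {
  type <- match.arg(type)
  if (inherits(X, "str_dataset")) X <- X$X
  if (ncol(X) != 4L * object$spec$input_width)
    stop("input width mismatch: model expects ", object$spec$input_width,
         "-bp windows")
  n <- nrow(X)
  out <- numeric(n)
  for (lo in seq(1, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1, n)
    out[lo:hi] <- .forward(object, t(X[lo:hi, , drop = FALSE]),
                           ablate = ablate)$out
  }
  if (type == "raw") return(out)
  if (object$spec$task == "classification") return(1 / (1 + exp(-out)))
  if (identical(object$target_transform, "log1p")) expm1(out) else out
}

#' Rank-correlation evaluation of regression predictions
#'
#' Spearman correlation with average ranks for ties; the accuracy metric for
#' signal regression.
#'
#' @param predictions,targets equal-length numeric vectors (n >= 3).
#' @return list of class `eval_report`: `metric`, `value` (`NA` when either
#'   vector is constant), `n`.
#' @export
eval_regression <- function(predictions, targets) {
  n <- length(predictions)
  if (n != length(targets)) stop("length mismatch")
  if (n < 3) stop("need at least 3 pairs")
  value <- if (stats::sd(predictions) == 0 || stats::sd(targets) == 0)
    NA_real_ else stats::cor(predictions, targets, method = "spearman")
  structure(list(metric = "spearman_rho", value = value, n = n),
            class = "eval_report")
}

#' Area under the ROC curve, exact with ties
#'
#' AUC = P(score_pos > score_neg) + P(tie)/2, computed by the rank formula
#' (equivalent to normalized pairwise concordance counting).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return list of class `eval_report`: `metric = "auc"`, `value`, `n`.
#' @export
eval_classification <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(metric = "auc", value = auc, n = n1 + n0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s = %s on n = %d\n", x$metric,
              formatC(x$value, digits = 4, format = "f"), x$n))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per combination of the supplied hyperparameter values
#' (all with the shared seed), selects by validation metric (Spearman rho or
#' AUC), and returns the winning spec with the full leaderboard.
#'
#' @param space named list of vectors over `model_spec` arguments (e.g.
#'   `list(n_filters = c(20, 50), kernel_width = c(8, 12))`).
#' @param train_data,val_data lists with `X`, `y`.
#' @param input_width window width of the data.
#' @param task `"regression"` or `"classification"`.
#' @param config a [train_config()].
#' @param target_transform transform already applied to the targets.
#' @return list: `best_spec`, `best_model`, `leaderboard` (data frame with
#'   one row per combination, validation metric, stopping epoch).
#' @export
grid_search <- function(space, train_data, val_data, input_width,
                        task = "regression", config = train_config(),
                        target_transform = "identity") {
  if (!length(space)) stop("empty search space")
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  metric <- numeric(nrow(grid)); epochs <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- c(list(input_width = input_width, task = task),
              lapply(grid[i, , drop = FALSE], function(col)
                if (is.list(col)) col[[1]] else col))
    spec <- do.call(model_spec, args)
    fit <- train_model(build_model(spec, seed = config$seed),
                       train_data, val_data, config,
                       target_transform = target_transform)
    pred <- predict(fit, val_data$X, type = "raw")
    metric[i] <- if (task == "regression")
      eval_regression(pred, val_data$y)$value else
        eval_classification(pred, val_data$y)$value
    epochs[i] <- fit$stopped_epoch
    results[[i]] <- fit
  }
  leaderboard <- cbind(grid, validation_metric = metric,
                       stopped_epoch = epochs)
  leaderboard <- leaderboard[order(-leaderboard$validation_metric), ,
                             drop = FALSE]
  best <- which.max(metric)
  list(best_spec = results[[best]]$spec, best_model = results[[best]],
       leaderboard = leaderboard)
}

#' Cross-apply class-specific models to class-specific test sets
#'
#' `matrix[i, j]` holds the evaluation of model `i` on test set `j`
#' (Spearman for regression models, AUC for classifiers); the diagonal is
#' per-class self-evaluation. Width-incompatible cells are `NA` and the run
#' continues.
#'
#' @param models named list of trained `str_cnn`s.
#' @param datasets named list of lists with `X`, `y`.
#' @return numeric matrix, rows = models, columns = datasets.
#' @export
cross_apply <- function(models, datasets) {
  out <- matrix(NA_real_, length(models), length(datasets),
                dimnames = list(names(models), names(datasets)))
  for (i in seq_along(models)) for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    if (ncol(d$X) != 4L * models[[i]]$spec$input_width) next
    pred <- predict(models[[i]], d$X, type = "raw")
    out[i, j] <- if (models[[i]]$spec$task == "regression")
      eval_regression(pred, d$y)$value else
        eval_classification(pred, d$y)$value
  }
  out
}

#' Rank correlations between targets and random permutations of themselves
#'
#' The chance baseline for regression accuracy: with the target/sequence
#' association destroyed, the Spearman correlation collapses to the
#' ~1/sqrt(n) null scale.
#'
#' @param targets numeric vector.
#' @param reps number of permutations (default 10).
#' @param seed integer seed.
#' @param perm_fn permutation generator (for testing); defaults to a uniform
#'   random permutation.
#' @return numeric vector of `reps` absolute Spearman correlations.
#' @export
randomized_baseline <- function(targets, reps = 10L, seed = 1L,
                                perm_fn = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (is.null(perm_fn)) perm_fn <- function(n) sample.int(n)
  vapply(seq_len(reps), function(r)
    abs(stats::cor(targets, targets[perm_fn(length(targets))],
                   method = "spearman")), numeric(1))
}

#' Persist a trained model as a versioned plain-text archive
#'
#' @param model a `str_cnn`.
#' @param path output path (JSON).
#' @export
save_model <- function(model, path) {
  obj <- list(format = "strinit_cnn/1",
              spec = unclass(model$spec),
              target_transform = model$target_transform,
              init_seed = model$init_seed,
              weights = lapply(model$weights, function(w)
                if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
                else list(dim = NULL, data = as.vector(w))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path archive path.
#' @return the `str_cnn`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "strinit_cnn/1"))
    stop("unrecognized model archive format")
  spec <- do.call(model_spec, obj$spec[c("input_width", "task", "n_filters",
                                         "kernel_width", "pool_width",
                                         "fc_sizes", "dropout")])
  weights <- lapply(obj$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  structure(list(spec = spec, weights = weights,
                 n_parameters = sum(vapply(weights, length, numeric(1))),
                 target_transform = obj$target_transform,
                 init_seed = obj$init_seed),
            class = "str_cnn")
}
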