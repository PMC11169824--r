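#' Regression evaluation metrics
#'
#' Computes the coefficient of determination
#' \deqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2,}
#' the root mean square error with the n - 1 denominator
#' \deqn{RMSE = \sqrt{\sum_i (y_i - \hat y_i)^2 / (n - 1)},}
#' and the relative RMSE, \eqn{RMSE\% = RMSE / \bar y \times 100}.
#'
#' @param predicted predicted values.
#' @param observed measured values (same length, >= 2).
#' @return class `pg_metrics`: r2, rmse, rmse_pct (NA with a warning when
#'   the observed mean is zero), n, y_bar.
#' @export
evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed)) pg_stop("lengths must match")
  n <- length(observed)
  if (n < 2) pg_stop("need at least 2 observations")
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  rmse <- sqrt(ss_res / (n - 1))
  y_bar <- mean(observed)
  if (y_bar == 0) {
    warning("observed mean is zero: RMSE% undefined")
    rmse_pct <- NA_real_
  } else rmse_pct <- rmse / y_bar * 100
  structure(list(r2 = r2, rmse = rmse, rmse_pct = rmse_pct,
                 n = n, y_bar = y_bar), class = "pg_metrics")
}

#' @export
print.pg_metrics <- function(x, ...) {
  cat(sprintf("<pg_metrics> n = %d: R2 = %.4f, RMSE = %.4f, RMSE%% = %.2f\n",
              x$n, x$r2, x$rmse, x$rmse_pct))
  invisible(x)
}

#' Deep-network configuration for phenomic prediction
#'
#' The default architecture is a feedforward fully connected network with
#' five hidden layers of 64, 128, 256, 512 and 1024 units, each hidden
#' layer ordered dense -> batch normalization -> ReLU -> dropout (rate
#' 0.3), a single linear output unit per target trait, mean-squared-error
#' loss and the Adam optimizer. The hyperparameter search of [dnn_tune()]
#' spans epochs \{50, 100, 150, 200, 250\} and batch sizes
#' \{16, 24, 32, 64\}.
#'
#' @param hidden_sizes hidden-layer widths (non-empty).
#' @param dropout dropout rate in \[0, 1).
#' @param batch_norm use batch normalization in hidden layers.
#' @param activation hidden activation, `"relu"` or `"identity"`.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param split_fraction training fraction of the plot-level 70/30 split.
#' @param seed integer seed governing split, initialization, batching and
#'   dropout; fixed-seed runs are bit-identical.
#' @return class `pg_dnncfg` list.
#' @export
dnn_config <- function(hidden_sizes = c(64, 128, 256, 512, 1024),
                       dropout = 0.3, batch_norm = TRUE,
                       activation = c("relu", "identity"),
                       learning_rate = 1e-3, epochs = 100, batch_size = 32,
                       split_fraction = 0.7, seed = 1L) {
  if (length(hidden_sizes) == 0) pg_stop("`hidden_sizes` must be non-empty")
  pg_check_number(dropout, "dropout", lower = 0, upper = 1, strict_upper = TRUE)
  pg_check_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  pg_check_number(split_fraction, "split_fraction", lower = 0, upper = 1,
                  strict_lower = TRUE, strict_upper = TRUE)
  activation <- match.arg(activation)
  structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 batch_norm = isTRUE(batch_norm), activation = activation,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "pg_dnncfg")
}

#' Build (initialize) a feedforward network
#'
#' He-uniform initialization of the dense layers; batch-normalization
#' scale/shift initialized to 1/0 with zeroed running statistics.
#'
#' @param cfg a [dnn_config()].
#' @param n_features input width (>= 1).
#' @param n_outputs output units (default 1; one trait per model).
#' @return class `pg_dnn` model handle.
#' @export
build_model <- function(cfg, n_features, n_outputs = 1L) {
  stopifnot(inherits(cfg, "pg_dnncfg"))
  if (n_features < 1) pg_stop("`n_features` must be >= 1")
  set.seed(pg_seed(cfg$seed, "dnninit"))
  sizes <- c(n_features, cfg$hidden_sizes, n_outputs)
  n_layers <- length(sizes) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / fan_in)
    layer <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out),
      hidden = l < n_layers)
    if (layer$hidden && cfg$batch_norm) {
      layer$gamma <- rep(1, fan_out); layer$beta <- rep(0, fan_out)
      layer$run_mean <- rep(0, fan_out); layer$run_var <- rep(1, fan_out)
    }
    layers[[l]] <- layer
  }
  structure(list(layers = layers, cfg = cfg, n_features = n_features,
                 n_outputs = n_outputs, trained = FALSE,
                 center = NULL, scl = NULL), class = "pg_dnn")
}

#' @export
print.pg_dnn <- function(x, ...) {
  cat(sprintf("<pg_dnn> %d -> %s -> %d (%s%d parameters)%s\n",
              x$n_features, paste(x$cfg$hidden_sizes, collapse = "-"),
              x$n_outputs, if (x$cfg$batch_norm) "BN, " else "",
              count_params(x), if (x$trained) " [trained]" else ""))
  invisible(x)
}

#' Trainable parameter count of a network
#'
#' Dense-layer arithmetic: sum over layers of (fan_in + 1) * fan_out, plus
#' two batch-normalization parameters (scale, shift) per hidden unit.
#'
#' @param model a `pg_dnn`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    n <- length(l$W) + length(l$b)
    if (!is.null(l$gamma)) n <- n + length(l$gamma) + length(l$beta)
    n
  }, numeric(1)))
}

dnn_act <- function(z, kind) if (kind == "relu") pmax(z, 0) else z
dnn_act_grad <- function(z, kind) if (kind == "relu") (z > 0) * 1 else
  matrix(1, nrow(z), ncol(z))

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# Forward pass. training = TRUE uses batch statistics, applies dropout and
# records the caches needed for backprop; FALSE uses running statistics
# with dropout disabled (evaluation mode).
dnn_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  a <- x
  caches <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    z <- a %*% ly$W + rep(1, nrow(a)) %*% t(ly$b)
    cache <- list(input = a)
    if (ly$hidden) {
      if (!is.null(ly$gamma)) {
        if (training) {
          mu <- colMeans(z)
          v <- colMeans(z^2) - mu^2
          model$layers[[l]]$run_mean <- .bn_momentum * ly$run_mean +
            (1 - .bn_momentum) * mu
          model$layers[[l]]$run_var <- .bn_momentum * ly$run_var +
            (1 - .bn_momentum) * v
        } else {
          mu <- ly$run_mean; v <- ly$run_var
        }
        zc <- sweep(z, 2, mu)
        inv_sd <- 1 / sqrt(v + .bn_eps)
        zhat <- sweep(zc, 2, inv_sd, "*")
        zbn <- sweep(sweep(zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
        cache$z <- z; cache$zhat <- zhat; cache$inv_sd <- inv_sd
      } else zbn <- z
      act <- dnn_act(zbn, cfg$activation)
      cache$pre_act <- zbn
      if (training && cfg$dropout > 0) {
        mask <- matrix(stats::rbinom(length(act), 1, 1 - cfg$dropout),
                       nrow(act), ncol(act)) / (1 - cfg$dropout)
        act <- act * mask
        cache$mask <- mask
      }
      a <- act
    } else a <- z
    caches[[l]] <- cache
  }
  list(output = a, caches = caches, model = model)
}

# One Adam update given gradients; state holds first/second moments.
adam_step <- function(param, grad, state, key, lr, t_step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state[[key]])) state[[key]] <- list(m = param * 0, v = param * 0)
  s <- state[[key]]
  s$m <- beta1 * s$m + (1 - beta1) * grad
  s$v <- beta2 * s$v + (1 - beta2) * grad^2
  state[[key]] <- s
  mhat <- s$m / (1 - beta1^t_step)
  vhat <- s$v / (1 - beta2^t_step)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# One mini-batch gradient step (forward, backprop, Adam).
dnn_train_batch <- function(model, x, y, state, t_step) {
  cfg <- model$cfg
  fw <- dnn_forward(model, x, training = TRUE)
  model <- fw$model
  pred <- fw$output
  m_b <- nrow(x)
  delta <- 2 * (pred - y) / (m_b * ncol(pred))   # d MSE / d pred
  lr <- cfg$learning_rate
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    cache <- fw$caches[[l]]
    if (ly$hidden) {
      if (!is.null(cache$mask)) delta <- delta * cache$mask
      delta <- delta * dnn_act_grad(cache$pre_act, cfg$activation)
      if (!is.null(ly$gamma)) {
        # batch-normalization backward
        dgamma <- colSums(delta * cache$zhat)
        dbeta <- colSums(delta)
        dzhat <- sweep(delta, 2, ly$gamma, "*")
        t1 <- sweep(dzhat, 2, colMeans(dzhat))
        t2 <- sweep(cache$zhat, 2, colMeans(dzhat * cache$zhat), "*")
        delta <- sweep(t1 - t2, 2, cache$inv_sd, "*")
        up <- adam_step(ly$gamma, dgamma, state, paste0("g", l), lr, t_step)
        model$layers[[l]]$gamma <- up$param; state <- up$state
        up <- adam_step(ly$beta, dbeta, state, paste0("be", l), lr, t_step)
        model$layers[[l]]$beta <- up$param; state <- up$state
        ly <- model$layers[[l]]
      }
    }
    dW <- crossprod(cache$input, delta)
    db <- colSums(delta)
    if (l > 1) delta <- tcrossprod(delta, ly$W)
    up <- adam_step(ly$W, dW, state, paste0("W", l), lr, t_step)
    model$layers[[l]]$W <- up$param; state <- up$state
    up <- adam_step(ly$b, db, state, paste0("b", l), lr, t_step)
    model$layers[[l]]$b <- up$param; state <- up$state
  }
  loss <- mean((pred - y)^2)
  if (!is.finite(loss))
    pg_stop(sprintf("non-finite training loss at step %d; lower the learning rate",
                    t_step))
  list(model = model, state = state, loss = loss)
}

# Full training loop over epochs with seed-deterministic shuffling.
dnn_fit <- function(model, x, y, verbose = FALSE) {
  cfg <- model$cfg
  set.seed(pg_seed(cfg$seed, "dnntrain"))
  n <- nrow(x)
  st <- list()          # Adam moment estimates, keyed per parameter
  t_step <- 0L
  last_loss <- NA_real_
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      if (length(idx) < 2) next   # batch statistics need >= 2 rows
      t_step <- t_step + 1L
      step <- dnn_train_batch(model, x[idx, , drop = FALSE],
                              y[idx, , drop = FALSE], st, t_step)
      model <- step$model
      st <- step$state
      last_loss <- step$loss
    }
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d: batch MSE %.5f", ep, last_loss))
  }
  model$trained <- TRUE
  model
}

#' Predict from a trained network
#'
#' Evaluation mode: dropout disabled, batch-normalization frozen at the
#' running statistics. Feature standardization learned at training time is
#' applied automatically.
#'
#' @param object a trained `pg_dnn`.
#' @param x feature matrix (raw scale).
#' @param ... unused.
#' @return matrix of predictions (n x n_outputs).
#' @export
predict.pg_dnn <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2, object$center), 2, object$scl, "/")
  out <- dnn_forward(object, x, training = FALSE)$output
  if (!is.null(object$y_center))
    out <- out * object$y_scale + object$y_center
  out
}

# Targets are z-scored for training (gradient scales independent of trait
# units) and predictions mapped back; the scaling is learned on training
# data only and stored on the model.
scale_target <- function(y) {
  m <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  list(center = m, scale = s, y = (y - m) / s)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scl = scl)
}

#' Train the phenomic DNN and evaluate on a held-out split
#'
#' Randomly splits the plots into training (70% by default) and testing
#' sets, z-scores every feature on the training plots only, trains the
#' network, and reports Eq-style metrics ([evaluate()]) on the held-out
#' set. Split, initialization, batching and dropout are all deterministic
#' given `cfg$seed`.
#'
#' @param features a `pg_features` from [build_feature_matrix()].
#' @param target trait name among the feature targets.
#' @param cfg a [dnn_config()].
#' @return list: `model` (trained `pg_dnn`), `metrics` (`pg_metrics` on
#'   the test set), `train_metrics`, `split` (train/test indices),
#'   `predictions` (test-set data.frame).
#' @export
train_predict <- function(features, target, cfg = dnn_config()) {
  stopifnot(inherits(features, "pg_features"))
  if (!target %in% colnames(features$y))
    pg_stop("target `", target, "` not among feature-matrix targets")
  x <- features$x
  y <- features$y[, target]
  n <- nrow(x)
  if (n < 20) pg_stop("need at least 20 plots")
  set.seed(pg_seed(cfg$seed, "split"))
  n_train <- floor(cfg$split_fraction * n)
  tr <- sort(sample.int(n, n_train))
  te <- setdiff(seq_len(n), tr)
  std <- standardize_fit(x[tr, , drop = FALSE])
  xs <- sweep(sweep(x, 2, std$center), 2, std$scl, "/")
  yt <- scale_target(y[tr])
  model <- build_model(cfg, ncol(x))
  model <- dnn_fit(model, xs[tr, , drop = FALSE],
                   matrix(yt$y, ncol = 1))
  model$center <- std$center; model$scl <- std$scl
  model$y_center <- yt$center; model$y_scale <- yt$scale
  pred_te <- as.numeric(predict(model, x[te, , drop = FALSE]))
  pred_tr <- as.numeric(predict(model, x[tr, , drop = FALSE]))
  list(model = model,
       metrics = evaluate(pred_te, y[te]),
       train_metrics = evaluate(pred_tr, y[tr]),
       split = list(train = tr, test = te),
       predictions = data.frame(plot_id = features$plot_id[te],
                                observed = y[te], predicted = pred_te,
                                stringsAsFactors = FALSE))
}

#' Hyperparameter grid search over epochs and batch size
#'
#' Carves a validation fifth from the training split, trains one model per
#' (epochs, batch size) grid cell, and returns the configuration with the
#' smallest validation MSE. Ties are broken toward fewer epochs, then
#' smaller batches. A failing cell is logged and skipped.
#'
#' @param features a `pg_features`.
#' @param target trait name.
#' @param epochs_grid epoch values (default 50, 100, 150, 200, 250).
#' @param batch_grid batch sizes (default 16, 24, 32, 64).
#' @param base a [dnn_config()] supplying every other hyperparameter.
#' @return list: `best` (a `pg_dnncfg`), `grid` (data.frame of
#'   epochs, batch_size, val_mse).
#' @export
dnn_tune <- function(features, target,
                     epochs_grid = c(50, 100, 150, 200, 250),
                     batch_grid = c(16, 24, 32, 64),
                     base = dnn_config()) {
  if (!length(epochs_grid) || !length(batch_grid))
    pg_stop("tuning grid must be non-empty")
  x <- features$x
  y <- features$y[, target]
  n <- nrow(x)
  set.seed(pg_seed(base$seed, "split"))
  n_train <- floor(base$split_fraction * n)
  tr <- sort(sample.int(n, n_train))
  set.seed(pg_seed(base$seed, "tunesplit"))
  n_val <- max(2L, floor(0.2 * length(tr)))
  val <- sort(sample(tr, n_val))
  fit_idx <- setdiff(tr, val)
  std <- standardize_fit(x[fit_idx, , drop = FALSE])
  xs <- sweep(sweep(x, 2, std$center), 2, std$scl, "/")
  grid <- expand.grid(epochs = epochs_grid, batch_size = batch_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$val_mse <- NA_real_
  yt <- scale_target(y[fit_idx])
  yv <- (y[val] - yt$center) / yt$scale
  for (i in seq_len(nrow(grid))) {
    cfg_i <- base
    cfg_i$epochs <- as.integer(grid$epochs[i])
    cfg_i$batch_size <- as.integer(grid$batch_size[i])
    res <- tryCatch({
      m <- build_model(cfg_i, ncol(x))
      m <- dnn_fit(m, xs[fit_idx, , drop = FALSE],
                   matrix(yt$y, ncol = 1))
      pred <- dnn_forward(m, xs[val, , drop = FALSE])$output
      mean((as.numeric(pred) - yv)^2)
    }, error = function(e) {
      message(sprintf("grid cell (epochs=%d, batch=%d) failed: %s",
                      cfg_i$epochs, cfg_i$batch_size, conditionMessage(e)))
      NA_real_
    })
    grid$val_mse[i] <- res
  }
  ok <- which(is.finite(grid$val_mse))
  if (!length(ok)) pg_stop("every grid cell failed")
  ord <- ok[order(grid$val_mse[ok], grid$epochs[ok], grid$batch_size[ok])]
  best <- base
  best$epochs <- as.integer(grid$epochs[ord[1]])
  best$batch_size <- as.integer(grid$batch_size[ord[1]])
  list(best = best, grid = grid)
}

#' Forward prediction: advanced trials to preliminary trials
#'
#' Trains on every advanced-trial plot (no internal split), then predicts
#' the preliminary-trial plots. Standardization parameters are learned on
#' the training features only and applied unchanged to the test features.
#'
#' @param train_features `pg_features` from the advanced (ELITE/AYT) plots.
#' @param test_features `pg_features` from the preliminary (PYT) plots;
#'   feature columns must be identical.
#' @param target trait name present in both.
#' @param cfg a [dnn_config()].
#' @return list: `model`, `metrics` (`pg_metrics` on the preliminary
#'   plots), `predictions`.
#' @export
forward_predict <- function(train_features, test_features, target,
                            cfg = dnn_config()) {
  stopifnot(inherits(train_features, "pg_features"),
            inherits(test_features, "pg_features"))
  if (!identical(colnames(train_features$x), colnames(test_features$x)))
    pg_stop("train and test feature columns must be identical")
  x_tr <- train_features$x
  y_tr <- train_features$y[, target]
  x_te <- test_features$x
  y_te <- test_features$y[, target]
  std <- standardize_fit(x_tr)
  xs_tr <- sweep(sweep(x_tr, 2, std$center), 2, std$scl, "/")
  yt <- scale_target(y_tr)
  model <- build_model(cfg, ncol(x_tr))
  model <- dnn_fit(model, xs_tr, matrix(yt$y, ncol = 1))
  model$center <- std$center; model$scl <- std$scl
  model$y_center <- yt$center; model$y_scale <- yt$scale
  pred <- as.numeric(predict(model, x_te))
  list(model = model, metrics = evaluate(pred, y_te),
       predictions = data.frame(plot_id = test_features$plot_id,
                                observed = y_te, predicted = pred,
                                stringsAsFactors = FALSE))
}

#' Growth-stage ablation for the phenomic DNN
#'
#' Trains one model per single flight and one on all flights jointly on
#' identical splits, reproducing the per-stage versus multitemporal
#' comparison structure.
#'
#' @param vi VI table.
#' @param pheno plot phenotype table.
#' @param target trait name.
#' @param cfg a [dnn_config()].
#' @param stages stages to ablate (default: all in the VI table).
#' @return data.frame: stage ("all" plus each flight), r2, rmse, rmse_pct.
#' @export
stage_ablation <- function(vi, pheno, target, cfg = dnn_config(),
                           stages = NULL) {
  if (is.null(stages)) stages <- unique(vi$stage)
  runs <- c(list(all = stages), stats::setNames(as.list(stages), stages))
  out <- lapply(names(runs), function(nm) {
    fm <- build_feature_matrix(vi, pheno, stages = runs[[nm]])
    m <- train_predict(fm, target, cfg)$metrics
    data.frame(stage = nm, r2 = m$r2, rmse = m$rmse, rmse_pct = m$rmse_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
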