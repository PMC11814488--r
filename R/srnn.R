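#' Sparse recurrent network specification
#'
#' Architecture and regularization configuration for the window classifier:
#' an LSTM runs over the `2N+1` window positions (each an `m`-dimensional
#' feature vector); its final hidden state (the context vector) passes
#' through a tanh dense stack and a 2-way softmax that outputs the
#' probability of the center site being O-GlcNAcylated. The training loss
#' is cross-entropy plus `lambda` times an L1 or sparse-group-Lasso penalty
#' on the input and/or hidden weight groups; zeroed input groups amount to
#' embedded feature selection, zeroed hidden groups to pruning.
#'
#' @param input_dim Per-position feature count `m`.
#' @param n_flank Window half-width N (the LSTM runs `2N+1` steps).
#' @param hidden_size LSTM hidden units.
#' @param dense_sizes Integer vector of dense-layer widths after the
#'   context vector (may be empty).
#' @param reg_input,reg_hidden `"none"`, `"l1"` or `"sgl"`; which penalty
#'   (if any) is applied to the input feature groups / hidden unit groups.
#' @param lambda Regularization strength (>= 0).
#' @param alpha SGL mixing weight in `[0, 1]` (1 = pure group Lasso).
#' @param group_size_scaling Scale group norms by sqrt(group size).
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs,patience Early-stopping budget: training stops when
#'   the validation loss has not improved for `patience` epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialization and batch shuffling.
#' @return An `srnn_spec` object.
#' @export
srnn_spec <- function(input_dim, n_flank, hidden_size = 16, dense_sizes = 8,
                      reg_input = c("none", "l1", "sgl"),
                      reg_hidden = c("none", "l1", "sgl"),
                      lambda = 0, alpha = 0.5, group_size_scaling = TRUE,
                      learning_rate = 0.001, max_epochs = 300, patience = 10,
                      batch_size = 256, seed = 1) {
  reg_input <- match.arg(reg_input)
  reg_hidden <- match.arg(reg_hidden)
  stopifnot(input_dim >= 1, n_flank >= 0, hidden_size >= 1,
            lambda >= 0, alpha >= 0, alpha <= 1,
            learning_rate > 0, max_epochs >= 1, patience >= 1,
            batch_size >= 1)
  structure(list(
    input_dim = as.integer(input_dim), n_flank = as.integer(n_flank),
    hidden_size = as.integer(hidden_size),
    dense_sizes = as.integer(dense_sizes),
    reg_input = reg_input, reg_hidden = reg_hidden,
    lambda = lambda, alpha = alpha,
    group_size_scaling = isTRUE(group_size_scaling),
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), batch_size = as.integer(batch_size),
    seed = as.integer(seed)), class = "srnn_spec")
}

#' Build an untrained model from a spec
#'
#' Weights are initialized uniformly in `+/- 1/sqrt(fan_in)` from the
#' spec's seed; the forget-gate bias starts at 1.
#'
#' @param spec An [srnn_spec()].
#' @param feature_names Optional length-`input_dim` feature names, carried
#'   through to importance rankings.
#' @return An `srnn_model`.
#' @export
build_model <- function(spec, feature_names = NULL) {
  stopifnot(inherits(spec, "srnn_spec"))
  m <- spec$input_dim; H <- spec$hidden_size
  if (!is.null(feature_names)) stopifnot(length(feature_names) == m)
  init <- function(r, c) {
    matrix(runif(r * c, -1, 1) / sqrt(r), r, c)
  }
  params <- withr::with_seed(spec$seed, {
    p <- list(Wx = init(m, 4 * H), Wh = init(H, 4 * H),
              b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),
              dense = list(), Wout = NULL, bout = NULL)
    d_in <- H
    for (d in spec$dense_sizes) {
      p$dense[[length(p$dense) + 1]] <- list(W = init(d_in, d), b = rep(0, d))
      d_in <- d
    }
    p$Wout <- init(d_in, 2)
    p$bout <- rep(0, 2)
    p
  })
  structure(list(spec = spec, params = params,
                 feature_names = feature_names),
            class = "srnn_model")
}

#' @export
print.srnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<srnn_model> LSTM(%d -> %d) x %d steps -> dense(%s) -> softmax(2)\n",
    s$input_dim, s$hidden_size, 2 * s$n_flank + 1,
    paste(s$dense_sizes, collapse = ",")))
  cat(sprintf("  reg: input=%s hidden=%s lambda=%g alpha=%g; %d parameters\n",
              s$reg_input, s$reg_hidden, s$lambda, s$alpha,
              length(flatten_params(x$params))))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; x is n x T x m. Returns list(p = n x 2 softmax, and when
# cache = TRUE the per-step activations needed for backprop).
srnn_forward <- function(params, x, cache = FALSE) {
  n <- dim(x)[1]; tt <- dim(x)[2]
  H <- nrow(params$Wh)
  i_ix <- seq_len(H); f_ix <- H + i_ix; g_ix <- 2 * H + i_ix; o_ix <- 3 * H + i_ix
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- if (cache) vector("list", tt)
  for (t in seq_len(tt)) {
    xt <- matrix(x[, t, ], nrow = n)
    z <- xt %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2, params$b, "+")
    ig <- sigmoid(z[, i_ix, drop = FALSE])
    fg <- sigmoid(z[, f_ix, drop = FALSE])
    gg <- tanh(z[, g_ix, drop = FALSE])
    og <- sigmoid(z[, o_ix, drop = FALSE])
    c_prev <- cc
    cc <- fg * cc + ig * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- og * tc
    if (cache) {
      steps[[t]] <- list(i = ig, f = fg, g = gg, o = og,
                         c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
  }
  # dense stack (tanh) and 2-way softmax
  a <- h
  acts <- if (cache) vector("list", length(params$dense))
  for (k in seq_along(params$dense)) {
    a_in <- a
    a <- tanh(sweep(a %*% params$dense[[k]]$W, 2, params$dense[[k]]$b, "+"))
    if (cache) acts[[k]] <- list(a_in = a_in, a_out = a)
  }
  logits <- sweep(a %*% params$Wout, 2, params$bout, "+")
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  p <- e / rowSums(e)
  out <- list(p = p)
  if (cache) {
    out$steps <- steps; out$acts <- acts; out$context <- h; out$a_last <- a
  }
  out
}

# gradient of the mean cross-entropy w.r.t. all parameters (BPTT);
# fw must come from srnn_forward(..., cache = TRUE)
srnn_backward <- function(params, x, y, fw) {
  n <- dim(x)[1]; tt <- dim(x)[2]
  H <- nrow(params$Wh)
  Y <- cbind(1 - y, y)
  dlogits <- (fw$p - Y) / n
  g <- zero_like_params(params)
  g$Wout <- t(fw$a_last) %*% dlogits
  g$bout <- colSums(dlogits)
  da <- dlogits %*% t(params$Wout)
  for (k in rev(seq_along(params$dense))) {
    act <- fw$acts[[k]]
    dz <- da * (1 - act$a_out^2)
    g$dense[[k]]$W <- t(act$a_in) %*% dz
    g$dense[[k]]$b <- colSums(dz)
    da <- dz %*% t(params$dense[[k]]$W)
  }
  dh <- da
  dc <- matrix(0, n, H)
  tWh <- t(params$Wh)
  for (t in rev(seq_len(tt))) {
    s <- fw$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dzi <- di * s$i * (1 - s$i)
    dzf <- df * s$f * (1 - s$f)
    dzg <- dg * (1 - s$g^2)
    dzo <- do * s$o * (1 - s$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    xt <- matrix(x[, t, ], nrow = n)
    g$Wx <- g$Wx + t(xt) %*% dz
    g$Wh <- g$Wh + t(s$h_prev) %*% dz
    g$b <- g$b + colSums(dz)
    dh <- dz %*% tWh
    dc <- dc * s$f
  }
  g
}

#' Binary cross-entropy
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with probabilities clipped to
#' `[eps, 1 - eps]`.
#'
#' @param y 0/1 labels.
#' @param y_hat Predicted probabilities of the positive class.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
cross_entropy <- function(y, y_hat, eps = 1e-7) {
  if (length(y) != length(y_hat)) abort("y and y_hat differ in length")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Regularized training objective
#'
#' Cross-entropy of the model on a batch plus `lambda` times the configured
#' penalty on the model's weight groups. At `lambda = 0` this is the plain
#' cross-entropy.
#'
#' @param model An `srnn_model` (or `srnn_fit`).
#' @param x Feature array `n x (2N+1) x m` (or an [og_dataset()]).
#' @param y 0/1 labels (taken from the dataset when `x` is one).
#' @return Scalar objective value.
#' @export
regularized_loss <- function(model, x, y = NULL) {
  if (inherits(x, "og_dataset")) {
    y <- x$labels; x <- x$x
  }
  p <- srnn_forward(model$params, x)$p[, 2]
  cross_entropy(y, p) +
    model$spec$lambda * model_penalty(model$params, model$spec)
}

# --- parameter flattening ---------------------------------------------------
flatten_params <- function(params) {
  unlist(list(params$Wx, params$Wh, params$b,
              lapply(params$dense, function(d) list(d$W, d$b)),
              params$Wout, params$bout), use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  out <- skeleton
  pos <- 0L
  take <- function(template) {
    k <- length(template)
    v <- flat[pos + seq_len(k)]
    pos <<- pos + k
    if (is.matrix(template)) matrix(v, nrow(template), ncol(template)) else v
  }
  out$Wx <- take(skeleton$Wx)
  out$Wh <- take(skeleton$Wh)
  out$b <- take(skeleton$b)
  for (k in seq_along(skeleton$dense)) {
    out$dense[[k]]$W <- take(skeleton$dense[[k]]$W)
    out$dense[[k]]$b <- take(skeleton$dense[[k]]$b)
  }
  out$Wout <- take(skeleton$Wout)
  out$bout <- take(skeleton$bout)
  stopifnot(pos == length(flat))
  out
}

zero_like_params <- function(params) {
  unflatten_params(numeric(length(flatten_params(params))), params)
}

# analytic gradient of the full objective (cross-entropy + lambda * R),
# returned as a flat vector in flatten_params() order
model_gradient <- function(model, x, y) {
  fw <- srnn_forward(model$params, x, cache = TRUE)
  g <- srnn_backward(model$params, x, y, fw)
  if (model$spec$lambda > 0) {
    pg <- model_penalty_grad(model$params, model$spec)
    g <- unflatten_params(
      flatten_params(g) + model$spec$lambda * flatten_params(pg), g)
  }
  flatten_params(g)
}

#' Compare the analytic gradient with central finite differences
#'
#' Diagnostic for the backpropagation implementation: evaluates the full
#' regularized objective's gradient analytically and by central differences
#' and returns the relative L2 discrepancy.
#'
#' @param model An `srnn_model`.
#' @param x Feature array (small!).
#' @param y Labels.
#' @param h Finite-difference step (default 1e-5).
#' @return Scalar relative error `||g_num - g_ana|| / ||g_num||`.
#' @export
check_gradient <- function(model, x, y, h = 1e-5) {
  theta <- flatten_params(model$params)
  obj <- function(v) {
    m2 <- model
    m2$params <- unflatten_params(v, model$params)
    regularized_loss(m2, x, y)
  }
  g_num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(1))
  g_ana <- model_gradient(model, x, y)
  sqrt(sum((g_num - g_ana)^2)) / max(sqrt(sum(g_num^2)), 1e-12)
}

#' Train a sparse recurrent model
#'
#' Minibatch Adam on the regularized objective with early stopping on the
#' validation cross-entropy: training stops once the validation loss has
#' not improved for `patience` epochs (or at `max_epochs`), and the
#' parameters from the best validation epoch are returned. The training set
#' should already be class-balanced (see [oversample_positives()]); the
#' validation set must be left untouched by oversampling.
#'
#' @param model An `srnn_model` from [build_model()].
#' @param train,validation [og_dataset()]s with matching feature schema.
#' @param verbose Print per-epoch losses.
#' @param restore_best Return the parameters of the best validation epoch
#'   (default). With `FALSE`, the final iterate is returned instead, which
#'   is the relevant state when inspecting the optimizer's sparsity
#'   behavior under strong penalties.
#' @return An `srnn_fit`: the trained model plus `training_log` (tibble of
#'   per-epoch train objective and validation cross-entropy),
#'   `stopped_epoch` and `best_epoch`.
#' @export
srnn_train <- function(model, train, validation, verbose = FALSE,
                       restore_best = TRUE) {
  stopifnot(inherits(model, "srnn_model"),
            inherits(train, "og_dataset"),
            inherits(validation, "og_dataset"))
  spec <- model$spec
  if (dim(train$x)[3] != spec$input_dim) {
    abort("training feature dimension does not match the spec")
  }
  if (n_samples(train) == 0L || n_samples(validation) == 0L) {
    abort("empty training or validation set")
  }
  theta <- flatten_params(model$params)
  mom <- numeric(length(theta)); vel <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  n <- n_samples(train)
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L
  wait <- 0L
  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  stopped <- spec$max_epochs
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- withr::with_seed(spec$seed * 1000L + epoch, sample.int(n))
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, n)]
      xb <- train$x[idx, , , drop = FALSE]
      yb <- train$labels[idx]
      params <- unflatten_params(theta, model$params)
      fw <- srnn_forward(params, xb, cache = TRUE)
      ce <- cross_entropy(yb, fw$p[, 2])
      g <- flatten_params(srnn_backward(params, xb, yb, fw))
      pen <- 0
      if (spec$lambda > 0) {
        pen <- model_penalty(params, spec)
        g <- g + spec$lambda * flatten_params(model_penalty_grad(params, spec))
      }
      batch_losses <- c(batch_losses, ce + spec$lambda * pen)
      step <- step + 1L
      mom <- beta1 * mom + (1 - beta1) * g
      vel <- beta2 * vel + (1 - beta2) * g^2
      mhat <- mom / (1 - beta1^step)
      vhat <- vel / (1 - beta2^step)
      theta <- theta - spec$learning_rate * mhat / (sqrt(vhat) + adam_eps)
    }
    params <- unflatten_params(theta, model$params)
    val_p <- srnn_forward(params, validation$x)$p[, 2]
    val_loss <- cross_entropy(validation$labels, val_p)
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, mean(batch_losses))
    log_val <- c(log_val, val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f",
                      epoch, mean(batch_losses), val_loss))
    }
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_theta <- theta
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  structure(list(
    spec = spec,
    params = unflatten_params(if (restore_best) best_theta else theta,
                              model$params),
    feature_names = model$feature_names,
    training_log = tibble::tibble(epoch = log_epoch, train_loss = log_train,
                                  val_loss = log_val),
    stopped_epoch = stopped, best_epoch = best_epoch,
    scaler = NULL), class = c("srnn_fit", "srnn_model"))
}

#' Predict site probabilities
#'
#' @param model A trained `srnn_fit` (or any `srnn_model`).
#' @param newdata An [og_dataset()] or a feature array. Unscaled datasets
#'   are scaled with the bounds stored on the fit (when present).
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, newdata) {
  if (inherits(newdata, "og_dataset")) {
    if (!isTRUE(newdata$scaled) && !is.null(model$scaler)) {
      newdata <- apply_dataset_scaler(newdata, model$scaler)
    }
    x <- newdata$x
  } else {
    x <- newdata
  }
  if (dim(x)[3] != model$spec$input_dim) {
    abort("feature dimension does not match the model")
  }
  srnn_forward(model$params, x)$p[, 2]
}

#' Threshold probabilities into class labels
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1); a site is called positive
#'   when `p >= threshold` (default 0.5).
#' @return Integer 0/1 vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  as.integer(probabilities >= threshold)
}

#' Fit the full training pipeline on a training dataset
#'
#' Carves a stratified validation split out of the training data, fits the
#' min-max scaler on the remaining training rows only (leak-free),
#' oversamples positives in the training portion, builds the model and
#' trains it. The fitted scaler travels with the returned fit so that
#' [predict_proba()] can be applied to raw test data.
#'
#' @param train Training [og_dataset()] (scaled or raw).
#' @param spec An [srnn_spec()].
#' @param val_fraction Fraction of `train` held out for early stopping.
#' @param seed Seed for the validation split and oversampling.
#' @param restore_best See [srnn_train()].
#' @return An `srnn_fit`.
#' @export
fit_site_model <- function(train, spec, val_fraction = 0.1,
                           seed = spec$seed, restore_best = TRUE) {
  parts <- split_train_test(train, test_fraction = val_fraction, seed = seed)
  inner <- parts$train; val <- parts$test
  scaler <- NULL
  if (!isTRUE(inner$scaled)) {
    scaler <- fit_dataset_scaler(inner)
    inner <- apply_dataset_scaler(inner, scaler)
    val <- apply_dataset_scaler(val, scaler)
  }
  inner <- oversample_positives(inner, seed = seed)
  model <- build_model(spec, feature_names = dimnames(train$x)[[3]])
  fit <- srnn_train(model, inner, val, restore_best = restore_best)
  fit$scaler <- scaler %||% train$scaler
  fit
}
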