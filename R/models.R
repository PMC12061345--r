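#' @title Classifiers over the 270-dimensional binary feature space
#'
#' @description
#' Three model families share one training contract: logistic regression (a
#' single affine map with logistic link) and a 1-D convolutional network
#' (conv -> ReLU -> global max pool -> dense sigmoid), both minimizing mean
#' sigmoid focal cross-entropy with the Adam update rule and a stratified
#' 20% validation split; and k-nearest neighbours by exact brute-force
#' Euclidean distance. All training is deterministic under a fixed seed.
#'
#' @name models
NULL

#' Model configuration
#'
#' Defaults follow common practice where the training recipe leaves a value
#' open: focal loss alpha 0.25 / gamma 2 (community defaults), k = 5
#' neighbours, 32 conv filters of width 3.
#'
#' @param model_kind `"lr"`, `"knn"` or `"cnn"`
#' @param threshold decision threshold on the predicted probability
#'   (default 0.50; ties classify positive — screening favors sensitivity)
#' @param validation_fraction held-out fraction of the training rows
#'   (default 0.20)
#' @param seed integer seed for the validation split, initialization and
#'   minibatch order
#' @param focal_alpha positive-class weight in the focal loss
#' @param focal_gamma focusing exponent in the focal loss
#' @param knn_k neighbour count (odd, >= 1)
#' @param cnn_filters number of 1-D convolution filters
#' @param cnn_kernel convolution kernel width
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param learning_rate Adam step size
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (`Inf` disables)
#' @return a `model_config`
#' @export
model_config <- function(model_kind = c("lr", "knn", "cnn"), threshold = 0.50,
                         validation_fraction = 0.20, seed = 1L,
                         focal_alpha = 0.25, focal_gamma = 2.0, knn_k = 5L,
                         cnn_filters = 32L, cnn_kernel = 3L, epochs = 100L,
                         batch_size = 32L, learning_rate = 1e-3,
                         early_stop_patience = 10L) {
  model_kind <- match.arg(model_kind)
  stopifnot(threshold > 0, threshold < 1,
            validation_fraction > 0, validation_fraction < 1,
            knn_k >= 1L, knn_k %% 2L == 1L,
            cnn_filters >= 1L, cnn_kernel >= 1L,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(model_kind = model_kind, threshold = threshold,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, knn_k = as.integer(knn_k),
                 cnn_filters = as.integer(cnn_filters),
                 cnn_kernel = as.integer(cnn_kernel),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = early_stop_patience),
            class = "model_config")
}

#' Sigmoid focal cross-entropy
#'
#' `FL(p, y) = -alpha * y * (1-p)^gamma * log p
#'             - (1-alpha) * (1-y) * p^gamma * log(1-p)`.
#' With `gamma = 0`, `alpha = 0.5` this is half the binary cross-entropy.
#'
#' @param p predicted probabilities
#' @param y 0/1 labels
#' @param alpha positive-class weight
#' @param gamma focusing exponent
#' @return per-observation losses
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2.0) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -alpha * y * (1 - p)^gamma * log(p) -
    (1 - alpha) * (1 - y) * p^gamma * log(1 - p)
}

# d(focal loss)/d(logit); derived analytically, verified numerically in the
# test suite.
focal_loss_grad_logit <- function(p, y, alpha, gamma) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  gpos <- alpha * (1 - p)^gamma * (gamma * p * log(p) - (1 - p))
  gneg <- -(1 - alpha) * p^gamma * (gamma * (1 - p) * log(1 - p) - p)
  y * gpos + (1 - y) * gneg
}

sigmoid <- function(z) 1 / (1 + exp(-z))

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_update <- function(param, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  out <- param - lr * mhat / (sqrt(vhat) + eps)
  if (is.null(dim(param))) out <- as.vector(out)
  list(param = out, state = state)
}

# Seeded stratified validation split: returns list(train=idx, val=idx).
validation_split <- function(labels, fraction, seed) {
  n <- length(labels)
  idx_val <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), labels), function(idx) {
      k <- max(1L, round(fraction * length(idx)))
      if (length(idx) <= 1L) integer(0) else sample(idx, min(k, length(idx) - 1L))
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_len(n), idx_val), val = sort(idx_val))
}

check_training_inputs <- function(features, labels, expect_width = 270L) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  if (!is.null(expect_width) && ncol(features) != expect_width) {
    stop(sprintf("feature width %d, expected %d", ncol(features),
                 expect_width), call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
}

new_trained_model <- function(kind, config, parameters, catalog_version,
                              history) {
  structure(list(model_kind = kind, config = config, parameters = parameters,
                 catalog_version = catalog_version,
                 training_history = history),
            class = c(paste0("hemobleed_", kind), "hemobleed_model"))
}

#' Train the focal-loss logistic regression
#'
#' A single affine map (one weight per feature plus bias) with logistic
#' link, trained by minibatch Adam on the mean sigmoid focal cross-entropy,
#' with a stratified 20% validation split monitored for early stopping.
#'
#' @param features n x 270 binary matrix
#' @param labels 0/1 vector
#' @param config a [model_config()]
#' @param catalog_version recorded for the feature-alignment contract
#' @return a `hemobleed_model`
#' @export
train_lr <- function(features, labels, config = model_config("lr"),
                     catalog_version = "catalog_v1") {
  check_training_inputs(features, labels, NULL)
  split <- validation_split(labels, config$validation_fraction, config$seed)
  Xt <- features[split$train, , drop = FALSE]
  yt <- labels[split$train]
  Xv <- features[split$val, , drop = FALSE]
  yv <- labels[split$val]
  d <- ncol(features)

  with_seed(config$seed + 1L, {
    w <- stats::rnorm(d, 0, 0.01)
    b <- 0
    st <- adam_state(list(w = d, b = 1))
    t <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(val = Inf, w = w, b = b, since = 0L)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xt))
      for (start in seq(1L, nrow(Xt), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(Xt))]
        Xb <- Xt[idx, , drop = FALSE]
        yb <- yt[idx]
        p <- sigmoid(drop(Xb %*% w) + b)
        g <- focal_loss_grad_logit(p, yb, config$focal_alpha,
                                   config$focal_gamma) / length(yb)
        gw <- drop(crossprod(Xb, g))
        gb <- sum(g)
        t <- t + 1L
        up <- adam_update(w, gw, st$w, config$learning_rate, t)
        w <- up$param; st$w <- up$state
        up <- adam_update(b, gb, st$b, config$learning_rate, t)
        b <- up$param; st$b <- up$state
      }
      tl <- mean(focal_loss(sigmoid(drop(Xt %*% w) + b), yt,
                            config$focal_alpha, config$focal_gamma))
      vl <- mean(focal_loss(sigmoid(drop(Xv %*% w) + b), yv,
                            config$focal_alpha, config$focal_gamma))
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                           val_loss = vl))
      if (vl < best$val - 1e-9) {
        best <- list(val = vl, w = w, b = b, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$early_stop_patience) break
      }
    }
    new_trained_model("lr", config,
                      list(weights = best$w, bias = best$b),
                      catalog_version, history)
  })
}

#' Train the k-nearest-neighbour classifier
#'
#' Stores the training matrix; prediction is the exact brute-force majority
#' vote of the k nearest rows under Euclidean distance, with the predicted
#' probability equal to the positive-neighbour fraction. Distance ties are
#' broken by row order (first stored row wins), which keeps predictions
#' deterministic.
#'
#' @inheritParams train_lr
#' @return a `hemobleed_model`
#' @export
train_knn <- function(features, labels, config = model_config("knn"),
                      catalog_version = "catalog_v1") {
  check_training_inputs(features, labels, NULL)
  if (config$knn_k > nrow(features)) {
    stop(sprintf("knn_k = %d exceeds n_train = %d", config$knn_k,
                 nrow(features)), call. = FALSE)
  }
  new_trained_model("knn", config,
                    list(X = features, y = as.integer(labels)),
                    catalog_version,
                    data.frame(epoch = integer(0), train_loss = numeric(0),
                               val_loss = numeric(0)))
}

# Build the im2col windows matrix for a 1-D convolution: rows are the
# (n * n_pos) sliding windows, columns the kernel taps.
conv_windows <- function(X, kernel) {
  d <- ncol(X)
  n_pos <- d - kernel + 1L
  A <- matrix(0, nrow(X) * n_pos, kernel)
  for (j in seq_len(kernel)) {
    A[, j] <- as.vector(t(X[, j:(j + n_pos - 1L), drop = FALSE]))
  }
  A
}

cnn_forward <- function(X, params, kernel) {
  n <- nrow(X)
  n_pos <- ncol(X) - kernel + 1L
  A <- conv_windows(X, kernel)                       # (n*n_pos) x kernel
  C <- sweep(A %*% params$W, 2L, params$bconv, `+`)  # (n*n_pos) x filters
  C <- pmax(C, 0)
  nf <- ncol(C)
  P <- matrix(0, n, nf)
  amax <- matrix(0L, n, nf)
  for (f in seq_len(nf)) {
    Cf <- matrix(C[, f], nrow = n, ncol = n_pos, byrow = TRUE)
    amax[, f] <- max.col(Cf, ties.method = "first")
    P[, f] <- Cf[cbind(seq_len(n), amax[, f])]
  }
  z <- drop(P %*% params$v) + params$bout
  list(A = A, C = C, P = P, amax = amax, z = z, p = sigmoid(z),
       n_pos = n_pos)
}

#' Train the 1-D convolutional classifier
#'
#' The catalog-ordered 270-vector is treated as a length-270 single-channel
#' sequence: `cnn_filters` filters of width `cnn_kernel` with ReLU, global
#' max pooling, then a single dense sigmoid unit. Trained like the logistic
#' model (focal loss, Adam, stratified 20% validation split). Predictions
#' depend on catalog order, which is why the catalog's ordering is frozen.
#'
#' @inheritParams train_lr
#' @return a `hemobleed_model`
#' @export
train_cnn <- function(features, labels, config = model_config("cnn"),
                      catalog_version = "catalog_v1") {
  check_training_inputs(features, labels, NULL)
  if (config$cnn_kernel > ncol(features)) {
    stop("cnn kernel wider than the feature axis", call. = FALSE)
  }
  split <- validation_split(labels, config$validation_fraction, config$seed)
  Xt <- features[split$train, , drop = FALSE]
  yt <- labels[split$train]
  Xv <- features[split$val, , drop = FALSE]
  yv <- labels[split$val]
  k <- config$cnn_kernel
  nf <- config$cnn_filters

  with_seed(config$seed + 1L, {
    # small positive conv bias keeps every filter initially active (global
    # max pooling + ReLU over sparse binary input is prone to dead filters)
    params <- list(W = matrix(stats::rnorm(k * nf, 0, 0.3), k, nf),
                   bconv = rep(0.1, nf),
                   v = stats::rnorm(nf, 0, 0.1),
                   bout = 0)
    st <- adam_state(list(W = c(k, nf), bconv = nf, v = nf, bout = 1))
    t <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(val = Inf, params = params, since = 0L)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xt))
      for (start in seq(1L, nrow(Xt), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(Xt))]
        Xb <- Xt[idx, , drop = FALSE]
        yb <- yt[idx]
        fw <- cnn_forward(Xb, params, k)
        nb <- nrow(Xb)
        g <- focal_loss_grad_logit(fw$p, yb, config$focal_alpha,
                                   config$focal_gamma) / nb
        gv <- drop(crossprod(fw$P, g))
        gbout <- sum(g)
        dP <- outer(g, params$v)                    # nb x filters
        gW <- matrix(0, k, nf)
        gbconv <- rep(0, nf)
        for (f in seq_len(nf)) {
          rows <- (seq_len(nb) - 1L) * fw$n_pos + fw$amax[, f]
          active <- fw$C[rows, f] > 0
          dc <- dP[, f] * active
          gW[, f] <- drop(crossprod(fw$A[rows, , drop = FALSE], dc))
          gbconv[f] <- sum(dc)
        }
        t <- t + 1L
        for (nm in names(params)) {
          grad <- switch(nm, W = gW, bconv = gbconv, v = gv, bout = gbout)
          up <- adam_update(params[[nm]], grad, st[[nm]],
                            config$learning_rate, t)
          params[[nm]] <- up$param; st[[nm]] <- up$state
        }
      }
      tl <- mean(focal_loss(cnn_forward(Xt, params, k)$p, yt,
                            config$focal_alpha, config$focal_gamma))
      vl <- mean(focal_loss(cnn_forward(Xv, params, k)$p, yv,
                            config$focal_alpha, config$focal_gamma))
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                           val_loss = vl))
      if (vl < best$val - 1e-9) {
        best <- list(val = vl, params = params, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$early_stop_patience) break
      }
    }
    new_trained_model("cnn", config, best$params, catalog_version, history)
  })
}

#' Train a model of the configured kind
#'
#' @inheritParams train_lr
#' @return a `hemobleed_model`
#' @export
train_model <- function(features, labels, config,
                        catalog_version = "catalog_v1") {
  switch(config$model_kind,
         lr = train_lr(features, labels, config, catalog_version),
         knn = train_knn(features, labels, config, catalog_version),
         cnn = train_cnn(features, labels, config, catalog_version))
}

predict_proba <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  switch(
    model$model_kind,
    lr = sigmoid(drop(features %*% model$parameters$weights) +
                   model$parameters$bias),
    cnn = cnn_forward(features, model$parameters,
                      model$config$cnn_kernel)$p,
    knn = {
      X <- model$parameters$X
      y <- model$parameters$y
      k <- model$config$knn_k
      apply(features, 1L, function(q) {
        d2 <- rowSums(sweep(X, 2L, q)^2)
        nb <- order(d2)[seq_len(k)]   # ties: first stored row wins
        mean(y[nb])
      })
    })
}

#' Predict major-bleeding probabilities and labels
#'
#' @param object a `hemobleed_model`
#' @param features feature matrix (rows aligned to the model's catalog
#'   version) or a single `feature_vector`
#' @param catalog_version optional version of the supplied features; must
#'   match the model's when given
#' @param ... unused
#' @return data.frame `visit_id`, `probability`, `label` (1 iff probability
#'   >= threshold; a tie at the threshold classifies positive)
#' @export
predict.hemobleed_model <- function(object, features,
                                    catalog_version = NULL, ...) {
  if (inherits(features, "feature_vector")) {
    features <- matrix(features$values, nrow = 1,
                       dimnames = list(features$visit_id, NULL))
  }
  if (!is.null(catalog_version) &&
      !identical(catalog_version, object$catalog_version)) {
    stop(sprintf("feature catalog '%s' does not match model catalog '%s'",
                 catalog_version, object$catalog_version), call. = FALSE)
  }
  expected <- if (object$model_kind == "knn") ncol(object$parameters$X)
              else if (object$model_kind == "lr")
                length(object$parameters$weights)
              else NULL
  if (!is.null(expected) && ncol(features) != expected) {
    stop(sprintf("feature width %d does not match model width %d (catalog %s)",
                 ncol(features), expected, object$catalog_version),
         call. = FALSE)
  }
  p <- predict_proba(object, features)
  data.frame(visit_id = rownames(features) %||% as.character(seq_along(p)),
             probability = p,
             label = as.integer(p >= object$config$threshold),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model as JSON
#'
#' A self-describing text archive: model kind, config, parameters and
#' catalog version. No cross-version loading guarantees.
#'
#' @param model a `hemobleed_model`
#' @param path destination
#' @return `path` invisibly
#' @export
save_model <- function(model, path) {
  payload <- list(model_kind = model$model_kind,
                  config = unclass(model$config),
                  catalog_version = model$catalog_version,
                  parameters = model$parameters,
                  training_history = model$training_history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, as.list(obj$config))
  pars <- obj$parameters
  if (obj$model_kind == "knn") {
    pars$X <- as.matrix(pars$X)
    pars$y <- as.integer(pars$y)
  }
  if (obj$model_kind == "cnn") pars$W <- as.matrix(pars$W)
  new_trained_model(obj$model_kind, cfg, pars, obj$catalog_version,
                    as.data.frame(obj$training_history))
}
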