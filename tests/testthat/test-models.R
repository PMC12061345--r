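# deterministic synthetic design: an informative 3-column block plus noise
make_design <- function(n, d = 40L, prev = 0.3, seed = 99L) {
  hemobleed:::with_seed(seed, {
    y <- rbinom(n, 1, prev)
    X <- matrix(rbinom(n * d, 1, 0.1), n, d)
    X[y == 1, 1:3] <- 1L
    list(X = X, y = y)
  })
}

# fully separable design: column 1 is a cat3-style indicator equal to the
# label; remaining columns are noise
make_separable <- function(n, d = 40L, prev = 0.3, seed = 99L) {
  hemobleed:::with_seed(seed, {
    y <- rbinom(n, 1, prev)
    X <- matrix(rbinom(n * d, 1, 0.1), n, d)
    X[, 1] <- y
    list(X = X, y = y)
  })
}

test_that("focal loss reduces to half binary cross-entropy at gamma=0, alpha=0.5", {
  p <- c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 0.33, 0.66, 0.5)
  y <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 1)
  fl <- focal_loss(p, y, alpha = 0.5, gamma = 0)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(fl, 0.5 * bce, tolerance = 1e-12)
})

test_that("focal loss down-weights well-classified points as gamma grows", {
  # well-classified positive: p = 0.9
  expect_lt(focal_loss(0.9, 1, gamma = 2), focal_loss(0.9, 1, gamma = 0))
  expect_lt(focal_loss(0.1, 0, gamma = 2), focal_loss(0.1, 0, gamma = 0))
})

test_that("analytic focal gradient matches finite differences", {
  grad <- hemobleed:::focal_loss_grad_logit
  sig <- hemobleed:::sigmoid
  for (y in c(0, 1)) for (z in c(-2, -0.5, 0, 0.7, 3)) {
    for (prm in list(c(0.25, 2), c(0.5, 0), c(0.7, 1))) {
      num <- (focal_loss(sig(z + 1e-6), y, prm[1], prm[2]) -
                focal_loss(sig(z - 1e-6), y, prm[1], prm[2])) / 2e-6
      expect_equal(grad(sig(z), y, prm[1], prm[2]), num, tolerance = 1e-5,
                   label = sprintf("y=%d z=%.1f a=%.2f g=%.0f",
                                   y, z, prm[1], prm[2]))
    }
  }
})

test_that("LR on an all-zero design converges to the bias-only optimum", {
  n <- 200
  y <- rep(c(1, 0), c(60, 140))
  X <- matrix(0L, n, 10)
  cfg <- model_config("lr", seed = 3L, epochs = 300, learning_rate = 5e-3,
                      early_stop_patience = Inf)
  m <- train_lr(X, y, cfg)
  p_hat <- predict(m, X[1, , drop = FALSE])$probability
  # independent oracle: optimize the scalar-bias focal objective directly
  obj <- function(b) mean(focal_loss(hemobleed:::sigmoid(b), y,
                                     cfg$focal_alpha, cfg$focal_gamma))
  b_star <- optimize(obj, c(-8, 8))$minimum
  expect_lt(abs(p_hat - hemobleed:::sigmoid(b_star)), 0.05)
  expect_error(train_lr(X, rep(1, n), cfg), "single class")
})

test_that("LR separates a separable design and trains deterministically", {
  dd <- make_separable(400)
  cfg <- model_config("lr", seed = 5L, epochs = 300, learning_rate = 5e-3,
                      early_stop_patience = Inf)
  m1 <- train_lr(dd$X, dd$y, cfg)
  m2 <- train_lr(dd$X, dd$y, cfg)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$parameters, m2$parameters)
  # held-out rows (validation indices) classified well
  split <- hemobleed:::validation_split(dd$y, 0.2, cfg$seed)
  pr <- predict(m1, dd$X[split$val, ])
  yv <- dd$y[split$val]
  expect_gte(mean(pr$label[yv == 1] == 1), 0.95)
  expect_gte(mean(pr$label[yv == 0] == 0), 0.95)
})

test_that("KNN votes and probabilities follow the neighbour fraction", {
  X <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 0), c(1, 0, 0))
  y <- c(1, 0, 0, 1)
  m1 <- train_knn(X, y, model_config("knn", knn_k = 1L))
  expect_equal(predict(m1, X[1, , drop = FALSE])$probability, 1)
  m3 <- train_knn(X, y, model_config("knn", knn_k = 3L))
  # query (0,1,0): rows 1,2,3 all at distance 1 (row 4 at sqrt 2), so the
  # k=3 neighbourhood votes {1,0,0}
  p <- predict(m3, matrix(c(0, 1, 0), 1))$probability
  expect_equal(p, 1 / 3)
  expect_equal(predict(m3, matrix(c(0, 1, 0), 1))$label, 0L)
  expect_error(train_knn(X, y, model_config("knn", knn_k = 5L)), "exceeds")
})

test_that("KNN equals the brute-force all-pairs oracle", {
  dd <- make_design(100, seed = 42L)
  qq <- make_design(30, seed = 43L)
  k <- 5L
  m <- train_knn(dd$X, dd$y, model_config("knn", knn_k = k))
  got <- predict(m, qq$X)$probability
  oracle <- apply(qq$X, 1, function(q) {
    d2 <- colSums((t(dd$X) - q)^2)
    ord <- order(d2, seq_along(d2))   # lexicographic (distance, index)
    mean(dd$y[ord[seq_len(k)]])
  })
  expect_equal(got, oracle, tolerance = 0)
})

test_that("CNN contracts: zero output layer gives 0.5; order sensitivity", {
  cfg <- model_config("cnn", cnn_filters = 4L, cnn_kernel = 3L)
  zero_model <- hemobleed:::new_trained_model(
    "cnn", cfg,
    list(W = matrix(0.3, 3, 4), bconv = rep(0.1, 4), v = rep(0, 4), bout = 0),
    "catalog_v1", data.frame())
  dd <- make_design(10, d = 20L)
  expect_true(all(predict(zero_model, dd$X)$probability == 0.5))

  dd2 <- make_design(150, d = 30L, seed = 7L)
  cfg2 <- model_config("cnn", seed = 7L, epochs = 60,
                       early_stop_patience = Inf)
  m <- train_cnn(dd2$X, dd2$y, cfg2)
  m_again <- train_cnn(dd2$X, dd2$y, cfg2)
  expect_identical(m$training_history, m_again$training_history)
  perm <- hemobleed:::with_seed(8L, sample.int(30))
  p_orig <- predict(m, dd2$X)$probability
  p_perm <- predict(m, dd2$X[, perm])$probability
  expect_false(isTRUE(all.equal(p_orig, p_perm)))
  expect_error(train_cnn(dd2$X, dd2$y,
                         model_config("cnn", cnn_kernel = 40L)), "kernel")
})

test_that("CNN learns a separable design to high balanced accuracy", {
  dd <- make_design(300, seed = 99L)
  cfg <- model_config("cnn", seed = 2L, epochs = 150,
                      early_stop_patience = Inf)
  m <- train_cnn(dd$X, dd$y, cfg)
  split <- hemobleed:::validation_split(dd$y, 0.2, cfg$seed)
  pr <- predict(m, dd$X[split$val, ])
  yv <- dd$y[split$val]
  bal <- (mean(pr$label[yv == 1] == 1) + mean(pr$label[yv == 0] == 0)) / 2
  expect_gte(bal, 0.90)
})

test_that("prediction threshold rule: ties classify positive", {
  cfg <- model_config("lr", threshold = 0.5)
  m <- hemobleed:::new_trained_model(
    "lr", cfg, list(weights = c(0, 0), bias = 0), "catalog_v1", data.frame())
  pr <- predict(m, matrix(c(1, 0), 1))   # sigmoid(0) = 0.5 exactly
  expect_equal(pr$probability, 0.5)
  expect_equal(pr$label, 1L)
  m2 <- hemobleed:::new_trained_model(
    "lr", cfg, list(weights = c(-0.004, 0), bias = 0), "catalog_v1",
    data.frame())
  expect_equal(predict(m2, matrix(c(1, 0), 1))$label, 0L)  # p = 0.499
  # batch order preserved; width mismatch names the catalog
  dd <- list(X = matrix(rbinom(40, 1, 0.5), 20, 2))
  pr_b <- predict(m, dd$X)
  expect_equal(nrow(pr_b), 20L)
  expect_identical(pr_b$visit_id, as.character(1:20))
  expect_error(predict(m, matrix(0, 1, 5)), "catalog")
  expect_error(predict(m, dd$X, catalog_version = "catalog_v2"),
               "does not match")
})

test_that("model save/load round-trips predictions", {
  dd <- make_design(120, seed = 13L)
  for (kind in c("lr", "knn", "cnn")) {
    cfg <- model_config(kind, seed = 4L, epochs = 15)
    m <- train_model(dd$X, dd$y, cfg)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict(m2, dd$X)$probability,
                 predict(m, dd$X)$probability, tolerance = 1e-12,
                 label = kind)
  }
})
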