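test_that("instantiated tensors match the plan's trainable parameter count", {
  for (cfg in list(build_compressor_plan(compression_config(260, 0.2)),
                   build_classifier_plan(classifier_config(52)),
                   build_classifier_plan(classifier_config(52,
                                                           variant = "plus_lstm")))) {
    net <- withr::with_seed(1, init_network(cfg))
    expect_equal(count_network_params(net), cfg$trainable_params)
  }
})

test_that("a zeroed final dense layer forces the forced outputs", {
  ds <- fixture_dataset(n_per_class = 3)
  cmp <- withr::with_seed(1, init_network(
    build_compressor_plan(compression_config(260, 0.2))))
  nl <- length(cmp$weights)
  cmp$weights[[nl]]$W[] <- 0
  cmp$weights[[nl]]$b[] <- 0
  z <- compress_forward(cmp, ds)
  expect_equal(dim(z), c(12, 52))
  expect_true(all(z == 0))
  cls <- withr::with_seed(1, init_network(build_classifier_plan(
    classifier_config(52))))
  ncl <- length(cls$weights)
  cls$weights[[ncl]]$W[] <- 0
  cls$weights[[ncl]]$b[] <- 0
  p <- classify_forward(cls, z)
  expect_equal(p, matrix(0.25, 12, 4))
})

test_that("classifier outputs are probability rows, deterministic in inference", {
  cls <- withr::with_seed(2, init_network(build_classifier_plan(
    classifier_config(52))))
  z <- matrix(rnorm(10 * 52), 10, 52)
  p <- classify_forward(cls, z)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  # duplicating a row duplicates its output exactly
  p2 <- classify_forward(cls, z[c(1, 1, 3:10), ])
  expect_identical(p2[1, ], p2[2, ])
  expect_error(classify_forward(cls, z[, 1:20]), "expects")
})

test_that("compression is permutation-equivariant over the batch", {
  cmp <- withr::with_seed(3, init_network(
    build_compressor_plan(compression_config(260, 0.2))))
  X <- fixture_dataset(n_per_class = 3)$beats
  perm <- c(4, 1, 12, 7, 2, 3, 5, 6, 8, 9, 10, 11)
  z <- compress_forward(cmp, X)
  zp <- compress_forward(cmp, X[perm, ])
  expect_equal(zp, z[perm, ])
})

test_that("analytic gradients agree with finite differences across layer kinds", {
  # exercises conv, batchnorm, pooling, concatenate, flatten, dense and lstm
  for (variant in c("full", "plus_lstm")) {
    plan <- suppressMessages(build_classifier_plan(
      classifier_config(16, n_classes = 3, variant = variant)))
    net <- withr::with_seed(4, init_network(plan))
    X <- withr::with_seed(5, matrix(rnorm(4 * 16), 4, 16))
    Y <- diag(3)[c(1, 2, 3, 1), ]
    fwd <- cdecg:::.net_forward(net, X, training = FALSE)
    bk <- cdecg:::.net_backward(fwd, (fwd$out - Y) / nrow(Y))
    loss_of <- function(n2) cross_entropy(
      Y, cdecg:::.net_forward(n2, X, training = FALSE)$out)
    for (li in seq_along(net$weights)) {
      w <- net$weights[[li]]
      if (is.null(w)) next
      nm <- intersect(names(w), c("W", "gamma", "Wx"))[1]
      if (is.na(nm)) nm <- names(w)[1]
      target <- if (plan$layers[[li]]$kind == "bilstm") w$fwd[[1]] else w[[nm]]
      ii <- length(target) %/% 2 + 1
      eps <- 1e-6
      bump <- function(delta) {
        n2 <- net
        if (plan$layers[[li]]$kind == "bilstm")
          n2$weights[[li]]$fwd[[1]][ii] <- n2$weights[[li]]$fwd[[1]][ii] + delta
        else n2$weights[[li]][[nm]][ii] <- n2$weights[[li]][[nm]][ii] + delta
        n2
      }
      g_num <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
      g_an <- if (plan$layers[[li]]$kind == "bilstm")
        bk$grads[[li]]$fwd[[1]][ii] else bk$grads[[li]][[nm]][ii]
      expect_equal(g_an, g_num, tolerance = 1e-5)
    }
  }
})

test_that("every CR and every variant instantiates and trains briefly", {
  ds <- fixture_dataset(n_per_class = 16)   # 64 beats
  cfg <- train_config(epochs = 2, seed = 0, batch_size = 16)
  for (cr in c(0.5, 0.3, 0.1, 0.05)) {
    cmp <- build_compressor_plan(compression_config(260, cr))
    cls <- suppressMessages(build_classifier_plan(
      classifier_config(cmp$output_dim)))
    m <- train_model(cmp, cls, ds, cfg)
    expect_equal(nrow(m$history), 2)
    expect_true(all(is.finite(m$history$loss)))
  }
  for (variant in c("no_parallel", "plus_lstm", "plus_bilstm")) {
    cls <- build_classifier_plan(classifier_config(52, variant = variant))
    m <- train_model(build_compressor_plan(compression_config(260, 0.2)),
                     cls, ds, cfg)
    expect_equal(nrow(m$history), 2)
    expect_true(all(is.finite(m$history$loss)))
  }
})
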