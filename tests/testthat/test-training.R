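test_that("cross-entropy matches closed-form and hand-evaluated cases", {
  perfect <- diag(4)
  expect_equal(cross_entropy(perfect, perfect), 0, tolerance = 1e-6)
  uniform <- matrix(0.25, 4, 4)
  expect_equal(cross_entropy(diag(4), uniform), log(4), tolerance = 1e-9)
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(0.8, 0.2), 1)),
               -log(0.8), tolerance = 1e-9)
  # zero predicted probability at the true class is clipped, not infinite
  expect_true(is.finite(cross_entropy(matrix(c(1, 0), 1),
                                      matrix(c(0, 1), 1))))
  expect_error(cross_entropy(diag(4), matrix(0.25, 3, 4)), "shape mismatch")
})

test_that("training loss decreases over the first epochs on a fixed batch", {
  # dropout off so the objective itself is deterministic given the weights
  ds <- fixture_dataset(n_per_class = 16)
  m <- train_model(build_compressor_plan(compression_config(260, 0.2)),
                   build_classifier_plan(classifier_config(52,
                                                           dropout_rate = 0)),
                   ds, train_config(epochs = 5, seed = 0))
  expect_true(all(diff(m$history$loss) < 0))
})

test_that("training is reproducible under a fixed seed", {
  ds <- fixture_dataset(n_per_class = 16)
  cfg <- train_config(epochs = 2, seed = 123)
  m1 <- train_model(build_compressor_plan(compression_config(260, 0.2)),
                    build_classifier_plan(classifier_config(52)), ds, cfg)
  m2 <- train_model(build_compressor_plan(compression_config(260, 0.2)),
                    build_classifier_plan(classifier_config(52)), ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$classifier$weights, m2$classifier$weights)
})

test_that("the learning-rate schedule is non-increasing and floored", {
  ds <- fixture_dataset(n_per_class = 16)
  # aggressive schedule so decay steps actually trigger in a short run
  cfg <- train_config(epochs = 12, seed = 0, lr_patience = 1,
                      lr_factor = 0.5, min_lr = 2e-4)
  m <- train_model(build_compressor_plan(compression_config(260, 0.2)),
                   build_classifier_plan(classifier_config(52)), ds, cfg)
  lr <- m$history$lr
  expect_equal(lr[1], 0.001)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr >= cfg$min_lr))
})

test_that("classifier-only training works on pre-compressed features", {
  ds <- fixture_dataset(n_per_class = 20)
  basis <- pca_fit(ds, 52)
  zds <- beat_dataset(pca_transform(basis, ds), ds$labels,
                      class_names = ds$class_names)
  m <- train_model(NULL, build_classifier_plan(classifier_config(52)),
                   zds, train_config(epochs = 2, seed = 0))
  expect_null(m$compressor)
  p <- predict(m, pca_transform(basis, ds))
  expect_equal(length(p$labels), n_beats(ds))
})

test_that("mismatched plan chains are rejected up front", {
  ds <- fixture_dataset(n_per_class = 4)
  cmp <- build_compressor_plan(compression_config(260, 0.2))
  cls <- build_classifier_plan(classifier_config(26))
  expect_error(train_model(cmp, cls, ds, train_config(epochs = 1)),
               "does not chain")
  cls52 <- build_classifier_plan(classifier_config(52))
  short <- beat_dataset(ds$beats[, 1:100], ds$labels,
                        class_names = ds$class_names)
  expect_error(train_model(cmp, cls52, short, train_config(epochs = 1)),
               "does not match")
})
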