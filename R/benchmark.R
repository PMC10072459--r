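# Benchmark harness: sweep compression ratios x compression methods x
# classifier variants on one dataset, training one model per cell and
# reporting test accuracy and macro F1 per cell.

#' Sweep compression ratios, compression methods and classifier variants
#'
#' For each grid cell the dataset is split 0.8/0.2 (fixed seed), a
#' compressor is prepared (the learned convolutional compressor trained
#' jointly for method `"cnn"`, or an SVD/PCA basis fitted on the training
#' beats for the baselines), the classifier variant is trained, and the
#' held-out accuracy and macro F1 are recorded. A failing cell is reported
#' with an `NA` row, not fatal.
#'
#' @param dataset A [beat_dataset()].
#' @param crs Numeric vector of compression ratios.
#' @param methods Subset of `c("cnn", "svd", "pca")`.
#' @param variants Subset of classifier variants (see
#'   [classifier_config()]).
#' @param config A [train_config()]; its seed also fixes the split.
#' @return Data frame with one row per cell: `cr`, `method`, `variant`,
#'   `k`, `accuracy`, `macro_f1`, `seed`.
#' @export
run_benchmark <- function(dataset, crs = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05),
                          methods = c("cnn", "svd", "pca"),
                          variants = "full", config = train_config()) {
  stopifnot(inherits(dataset, "beat_dataset"))
  methods <- match.arg(methods, c("cnn", "svd", "pca"), several.ok = TRUE)
  n <- dataset$beat_length
  sp <- split_train_test(dataset, split_config(0.8, config$seed))
  grid <- expand.grid(cr = crs, method = methods, variant = variants,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cr <- grid$cr[g]; method <- grid$method[g]; variant <- grid$variant[g]
    k <- compressed_length(n, cr)
    res <- tryCatch({
      cls_plan <- build_classifier_plan(
        classifier_config(k = k, n_classes = length(dataset$class_names),
                          variant = variant))
      if (method == "cnn") {
        cmp_plan <- build_compressor_plan(compression_config(n, cr))
        model <- train_model(cmp_plan, cls_plan, sp$train, config)
        rep <- evaluate_model(model, sp$test)
      } else {
        basis <- if (method == "svd") svd_fit(sp$train, k)
                 else pca_fit(sp$train, k)
        tf <- if (method == "svd") svd_transform else pca_transform
        ztr <- beat_dataset(tf(basis, sp$train), sp$train$labels,
                            class_names = sp$train$class_names)
        model <- train_model(NULL, cls_plan, ztr, config)
        pred <- predict(model, tf(basis, sp$test))
        rep <- metrics_from_confusion(
          confusion_matrix(sp$test$labels, pred$labels,
                           class_names = model$classes))
      }
      c(accuracy = rep$macro$accuracy, macro_f1 = rep$macro$f1)
    }, error = function(e) {
      warning("benchmark cell cr=", cr, " method=", method, " variant=",
              variant, " failed: ", conditionMessage(e), call. = FALSE)
      c(accuracy = NA_real_, macro_f1 = NA_real_)
    })
    data.frame(cr = cr, method = method, variant = variant, k = k,
               accuracy = unname(res["accuracy"]),
               macro_f1 = unname(res["macro_f1"]),
               seed = config$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
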