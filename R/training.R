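# Joint end-to-end training of the compressor + classifier pair (or of a
# classifier alone on pre-compressed features): multi-class cross-entropy
# loss, Adam updates, mini-batches of 64, 50 epochs by default, and a
# reduce-on-plateau learning-rate schedule driven by an internal validation
# split. The compressor has no reconstruction objective: its weights are
# learned purely from the classification loss flowing back through the
# bottleneck.

#' Multi-class cross-entropy loss
#'
#' Mean over samples of `-sum_c y_ic * log(p_ic)`: the standard negative
#' log-likelihood for one-hot targets. Predicted probabilities are clipped
#' at `1e-7` before the logarithm.
#'
#' @param y_true One-hot matrix (n x n_classes).
#' @param y_pred Probability matrix of the same shape (rows sum to 1).
#' @return Non-negative scalar; 0 iff predictions equal the one-hot truths.
#' @examples
#' cross_entropy(diag(2), matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE))
#' @export
cross_entropy <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    stop("shape mismatch: y_true is ", paste(dim(y_true), collapse = "x"),
         ", y_pred is ", paste(dim(y_pred), collapse = "x"))
  p <- pmin(pmax(y_pred, 1e-7), 1)
  -mean(rowSums(y_true * log(p)))
}

#' Training configuration
#'
#' Defaults follow the study protocol: 50 epochs, batch size 64, Adam with
#' initial learning rate 0.001, and a reduce-on-plateau schedule
#' (factor 0.8, patience 5 epochs on validation loss, floor 1e-5) so the
#' rate decays in steps from 0.001 as training plateaus.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_factor Multiplicative decay applied on plateau.
#' @param lr_patience Epochs without validation-loss improvement before a
#'   decay step.
#' @param min_lr Learning-rate floor.
#' @param validation_fraction Fraction of the training set held out to
#'   drive the schedule (default 0.1).
#' @param seed Integer RNG seed covering initialization, shuffling, dropout
#'   and the validation split; a fixed seed makes training fully
#'   reproducible.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 64, initial_lr = 0.001,
                         lr_factor = 0.8, lr_patience = 5, min_lr = 1e-5,
                         validation_fraction = 0.1, seed = 0) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0, lr_factor > 0,
            lr_factor <= 1, lr_patience >= 1, min_lr > 0,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

.one_hot <- function(labels, class_names) {
  m <- matrix(0, length(labels), length(class_names))
  idx <- match(labels, class_names)
  if (anyNA(idx))
    stop("labels outside class set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# Adam optimizer state and update (beta1 0.9, beta2 0.999, eps 1e-7),
# applied recursively over nested weight/gradient lists.
.adam_init <- function(weights) {
  rapply(weights, function(w) list(m = w * 0, v = w * 0),
         how = "replace", classes = c("numeric", "matrix", "array"))
}

.adam_step <- function(w, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  if (is.list(w)) {
    keys <- if (is.null(names(w))) seq_along(w) else names(w)
    for (nm in keys) {
      if (is.null(g[[nm]]) || is.null(st[[nm]])) next
      r <- .adam_step(w[[nm]], g[[nm]], st[[nm]], lr, t, b1, b2, eps)
      w[[nm]] <- r$w; st[[nm]] <- r$st
    }
    return(list(w = w, st = st))
  }
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), st = st)
}

# Run-statistics keys that Adam must not touch.
.strip_bn_stats <- function(weights, plan) {
  for (i in seq_along(weights)) {
    if (!is.null(weights[[i]]) && plan$layers[[i]]$kind == "batchnorm")
      weights[[i]] <- weights[[i]][c("gamma", "beta")]
  }
  weights
}

#' Train a compressor + classifier pair end to end
#'
#' Initializes both networks, carves a seeded validation split out of the
#' training set, and minimizes the classification cross-entropy by Adam
#' over mini-batches, backpropagating through the classifier into the
#' compressor. The learning rate follows a reduce-on-plateau schedule on
#' validation loss. With `compressor_plan = NULL` the classifier is trained
#' alone on pre-compressed features (rows of width `k`), as used for the
#' SVD/PCA baselines.
#'
#' @param compressor_plan A compressor `network_plan`, or `NULL`.
#' @param classifier_plan A classifier `network_plan`.
#' @param train_set A [beat_dataset()]; beat length must match the first
#'   network's input.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress (default `FALSE`).
#' @return A `cdecg_model`: compressor and classifier networks, the class
#'   names, the config and a per-epoch `history` data frame (loss,
#'   accuracy, validation loss/accuracy, learning rate).
#' @export
train_model <- function(compressor_plan, classifier_plan, train_set,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(classifier_plan, "network_plan"),
            inherits(train_set, "beat_dataset"),
            inherits(config, "train_config"))
  expected_in <- if (is.null(compressor_plan)) classifier_plan$input_len
                 else compressor_plan$input_len
  if (train_set$beat_length != expected_in)
    stop("beat length ", train_set$beat_length,
         " does not match network input ", expected_in)
  if (!is.null(compressor_plan) &&
      compressor_plan$output_dim != classifier_plan$input_len)
    stop("compressor output (", compressor_plan$output_dim,
         ") does not chain into classifier input (",
         classifier_plan$input_len, ")")
  classes <- train_set$class_names
  if (length(classes) > classifier_plan$output_dim)
    stop("dataset has ", length(classes), " classes but the classifier has ",
         classifier_plan$output_dim, " outputs")
  Y_all <- .one_hot(train_set$labels,
                    c(classes,
                      rep("", classifier_plan$output_dim - length(classes)))[
                        seq_len(classifier_plan$output_dim)])

  withr::with_seed(config$seed, {
    cmp <- if (!is.null(compressor_plan)) init_network(compressor_plan)
    cls <- init_network(classifier_plan)
    n <- n_beats(train_set)
    n_val <- max(1L, as.integer(round(config$validation_fraction * n)))
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[(n_val + 1L):n]
    Xtr <- train_set$beats[tr_idx, , drop = FALSE]
    Ytr <- Y_all[tr_idx, , drop = FALSE]
    Xval <- train_set$beats[val_idx, , drop = FALSE]
    Yval <- Y_all[val_idx, , drop = FALSE]

    adam_cmp <- if (!is.null(cmp))
      .adam_init(.strip_bn_stats(cmp$weights, cmp$plan))
    adam_cls <- .adam_init(.strip_bn_stats(cls$weights, cls$plan))
    lr <- config$initial_lr
    best_val <- Inf; wait <- 0L; t_step <- 0L
    hist <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(Xtr))
      batch_starts <- seq(1, nrow(Xtr), by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (bs in batch_starts) {
        bi <- ord[bs:min(bs + config$batch_size - 1L, nrow(Xtr))]
        Xb <- Xtr[bi, , drop = FALSE]
        Yb <- Ytr[bi, , drop = FALSE]
        B <- nrow(Xb)

        if (!is.null(cmp)) {
          f_cmp <- .net_forward(cmp, Xb, training = TRUE)
          cmp <- f_cmp$network
          Zb <- f_cmp$out
        } else Zb <- Xb
        f_cls <- .net_forward(cls, Zb, training = TRUE)
        cls <- f_cls$network
        P <- f_cls$out
        loss <- cross_entropy(Yb, P)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, ", batch starting ", bs,
               " (lr = ", lr, ")")
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct +
          sum(max.col(P, ties.method = "first") ==
                max.col(Yb, ties.method = "first"))

        dLogits <- (P - Yb) / B   # softmax + cross-entropy folded together
        b_cls <- .net_backward(f_cls, dLogits)
        t_step <- t_step + 1L
        upd <- .adam_step(cls$weights, b_cls$grads, adam_cls, lr, t_step)
        cls$weights <- upd$w
        adam_cls <- upd$st
        if (!is.null(cmp)) {
          b_cmp <- .net_backward(f_cmp, b_cls$dInput)
          updc <- .adam_step(cmp$weights, b_cmp$grads, adam_cmp, lr, t_step)
          cmp$weights <- updc$w
          adam_cmp <- updc$st
        }
      }

      Zval <- if (!is.null(cmp)) .net_forward(cmp, Xval, FALSE)$out else Xval
      Pval <- .net_forward(cls, Zval, FALSE)$out
      val_loss <- cross_entropy(Yval, Pval)
      val_acc <- mean(max.col(Pval, ties.method = "first") ==
                        max.col(Yval, ties.method = "first"))
      hist[[epoch]] <- data.frame(
        epoch = epoch, loss = ep_loss / nrow(Xtr),
        accuracy = ep_correct / nrow(Xtr),
        val_loss = val_loss, val_accuracy = val_acc, lr = lr)
      if (verbose)
        message(sprintf(
          "epoch %3d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f  lr %.2g",
          epoch, ep_loss / nrow(Xtr), ep_correct / nrow(Xtr), val_loss,
          val_acc, lr))

      if (val_loss < best_val - 1e-7) {
        best_val <- val_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$lr_patience) {
          lr <- max(config$min_lr, lr * config$lr_factor)
          wait <- 0L
        }
      }
    }
    structure(list(compressor = cmp, classifier = cls, classes = classes,
                   config = config, history = do.call(rbind, hist)),
              class = "cdecg_model")
  })
}

#' @export
print.cdecg_model <- function(x, ...) {
  cat("<cdecg_model> ",
      if (!is.null(x$compressor))
        paste0("compressor ", x$compressor$plan$input_len, "->",
               x$compressor$plan$output_dim, " + ") else "",
      "classifier ", x$classifier$plan$input_len, "->",
      x$classifier$plan$output_dim, "; classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  h <- x$history
  cat("  trained ", nrow(h), " epochs; final val_acc ",
      sprintf("%.4f", h$val_accuracy[nrow(h)]), "\n", sep = "")
  invisible(x)
}

#' Predict class probabilities and labels for beats
#'
#' Runs the full inference chain (compressor if present, then classifier)
#' in deterministic inference mode.
#'
#' @param object A `cdecg_model` from [train_model()].
#' @param newdata A [beat_dataset()] or numeric beat matrix.
#' @param ... Unused.
#' @return List with `probabilities` (matrix) and `labels` (character
#'   vector of predicted class names).
#' @export
predict.cdecg_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "beat_dataset")) newdata$beats
       else as.matrix(newdata)
  Z <- if (!is.null(object$compressor)) compress_forward(object$compressor, X)
       else X
  P <- classify_forward(object$classifier, Z)
  labs <- object$classes[pmin(max.col(P, ties.method = "first"),
                              length(object$classes))]
  list(probabilities = P, labels = labs)
}
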