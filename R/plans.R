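# Declarative network plans: an ordered DAG of layer specifications with
# output shapes and parameter counts, covering the learned compressor
# (conv/pool cascade + dense bottleneck) and the parallel-branch classifier
# with its ablation variants. Parameter-count conventions:
#   conv1d:    (kernel * in_channels + 1) * filters
#   dense:     (in_features + 1) * units
#   batchnorm: 4 * channels total (2 * channels trainable scale/shift plus
#              2 * channels moving statistics, reported separately)
#   lstm:      4 * units * (in_channels + units + 1)   (doubled for bilstm)
#   pool/dropout/flatten/concatenate: 0

.new_layer <- function(kind, inputs = integer(0), filters = NA_integer_,
                       kernel = NA_integer_, stride = NA_integer_,
                       pool = NA_integer_, rate = NA_real_,
                       units = NA_integer_, activation = "linear",
                       out_len = NA_integer_, out_ch = NA_integer_,
                       flat = FALSE, params = 0L, trainable = NA_integer_) {
  if (is.na(trainable)) trainable <- params
  list(kind = kind, inputs = as.integer(inputs), filters = filters,
       kernel = kernel, stride = stride, pool = pool, rate = rate,
       units = units, activation = activation, out_len = out_len,
       out_ch = out_ch, flat = flat, params = as.integer(params),
       trainable = as.integer(trainable))
}

.new_plan <- function(layers, kind, input_len, output_dim) {
  structure(list(layers = layers,
                 total_params = sum(vapply(layers, `[[`, integer(1), "params")),
                 trainable_params = sum(vapply(layers, `[[`, integer(1),
                                               "trainable")),
                 kind = kind, input_len = as.integer(input_len),
                 output_dim = as.integer(output_dim)),
            class = "network_plan")
}

# Valid pooling with stride == pool size; the pool is clamped to the
# current length when the sequence is shorter than the pool window, so deep
# cascades stay runnable at strong compression. Emits a message when
# clamping triggers.
.pool_out <- function(len, pool) {
  eff <- min(pool, len)
  if (eff < pool)
    message("pool size ", pool, " clamped to ", eff, " (sequence length ",
            len, ")")
  max(1L, len %/% eff)
}

#' Compressed beat length for a compression ratio
#'
#' The compression ratio is defined as CR = k / n, where n is the original
#' beat length and k the compressed length; thus `k = round(cr * n)`
#' (round-half-away-from-zero, minimum 1). A 260-sample beat at CR = 0.2
#' compresses to 52 samples.
#'
#' @param n Original beat length (samples).
#' @param cr Compression ratio in (0, 1].
#' @return Integer compressed length k.
#' @examples
#' compressed_length(260, 0.2)
#' @export
compressed_length <- function(n, cr) {
  if (!is.numeric(cr) || cr <= 0 || cr > 1)
    stop("compression ratio must be in (0, 1]")
  supported <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  if (!any(abs(cr - supported) < 1e-12) && cr != 1)
    message("compression ratio ", cr,
            " is outside the standard sweep {0.5, 0.4, 0.3, 0.2, 0.1, 0.05}")
  max(1L, as.integer(floor(cr * n + 0.5)))
}

#' Compression configuration
#'
#' @param n Original beat length (samples).
#' @param cr Compression ratio in (0, 1].
#' @return A `compression_config` list with fields `n`, `cr` and the
#'   compressed length `k = round(cr * n)`.
#' @export
compression_config <- function(n = 260, cr = 0.2) {
  n <- as.integer(n)
  structure(list(n = n, cr = cr, k = compressed_length(n, cr)),
            class = "compression_config")
}

#' Build the learned-compressor network plan
#'
#' Three length-preserving 1-D convolutions (16 filters, kernel 3, ReLU)
#' alternating with max pools (sizes 2, 2, 5), then a flatten and a linear
#' dense layer of `k` units that sets the compressed dimension. For
#' n = 260, CR = 0.2 this reproduces the reference shapes
#' 260 -> 130 -> 65 -> 13 with dense parameters (13*16 + 1) * 52 = 10868.
#'
#' @param config A [compression_config()] (or anything with fields `n`, `k`).
#' @return A `network_plan`.
#' @export
build_compressor_plan <- function(config = compression_config()) {
  n <- as.integer(config$n); k <- as.integer(config$k)
  if (n < 20)
    stop("compressor needs n >= 20: the pool cascade (2, 2, 5) degenerates ",
         "at the final pool for shorter inputs")
  if (k < 1 || k > n) stop("compressed length k must satisfy 1 <= k <= n")
  layers <- list()
  layers[[1]] <- .new_layer("input", out_len = n, out_ch = 1L)
  len <- n
  pools <- c(2L, 2L, 5L)
  li <- 1L
  ch <- 1L
  for (i in 1:3) {
    li <- li + 1L
    layers[[li]] <- .new_layer("conv1d", inputs = li - 1L, filters = 16L,
                               kernel = 3L, stride = 1L, activation = "relu",
                               out_len = len, out_ch = 16L,
                               params = (3L * ch + 1L) * 16L)
    ch <- 16L
    li <- li + 1L
    len <- .pool_out(len, pools[i])
    layers[[li]] <- .new_layer("maxpool1d", inputs = li - 1L, pool = pools[i],
                               stride = pools[i], out_len = len, out_ch = 16L)
  }
  li <- li + 1L
  layers[[li]] <- .new_layer("flatten", inputs = li - 1L,
                             out_len = len * 16L, out_ch = 1L, flat = TRUE)
  li <- li + 1L
  layers[[li]] <- .new_layer("dense", inputs = li - 1L, units = k,
                             activation = "linear", out_len = k, out_ch = 1L,
                             flat = TRUE, params = (len * 16L + 1L) * k)
  .new_plan(layers, "compressor", n, k)
}

#' Classifier configuration
#'
#' @param k Input (compressed beat) length.
#' @param n_classes Number of output classes (default 4).
#' @param variant One of `"full"` (parallel-branch front end),
#'   `"no_parallel"` (single path, no concatenate), `"plus_lstm"` and
#'   `"plus_bilstm"` (recurrent layer of `rnn_units` inserted after the
#'   last convolution block).
#' @param dropout_rate Dropout fraction in the trunk (default 0.5).
#' @param rnn_units Hidden units of the LSTM/BiLSTM variants (default 64,
#'   matching the trunk width).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(k = 52, n_classes = 4,
                              variant = c("full", "no_parallel", "plus_lstm",
                                          "plus_bilstm"),
                              dropout_rate = 0.5, rnn_units = 64) {
  variant <- match.arg(variant)
  k <- as.integer(k)
  if (k < 4) stop("classifier needs k >= 4")
  if (n_classes < 2) stop("n_classes must be >= 2")
  structure(list(k = k, n_classes = as.integer(n_classes), variant = variant,
                 dropout_rate = dropout_rate,
                 rnn_units = as.integer(rnn_units)),
            class = "classifier_config")
}

#' Build the classifier network plan
#'
#' The full variant processes the compressed beat in two parallel branches
#' (conv 16/kernel 3 + batch normalization + max pool 2 each), fuses them by
#' concatenation along the time axis, and feeds the result through three
#' convolution blocks (2 x conv16 + pool 2, conv64 + conv64 + pool 3,
#' 2 x conv64 + pool 4, each followed by dropout 0.5), a flatten and a
#' softmax dense layer. For k = 52 this reproduces the reference per-layer
#' parameter counts (branch conv 64, batchnorm 64, 16->64 conv 3136,
#' 64->64 conv 12352, flatten width 128, final dense 516).
#'
#' Pools deeper than the remaining sequence are clamped (see
#' [build_compressor_plan()]), which keeps the plan runnable down to
#' CR = 0.05 on 260-sample beats.
#'
#' @param config A [classifier_config()].
#' @return A `network_plan`.
#' @export
build_classifier_plan <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  k <- config$k; rate <- config$dropout_rate
  layers <- list()
  layers[[1]] <- .new_layer("input", out_len = k, out_ch = 1L)
  li <- 1L
  add <- function(l) { li <<- li + 1L; layers[[li]] <<- l; li }
  conv <- function(input, filters, in_ch, len, act = "relu") {
    force(input)
    add(.new_layer("conv1d", inputs = input, filters = filters, kernel = 3L,
                   stride = 1L, activation = act, out_len = len,
                   out_ch = filters, params = (3L * in_ch + 1L) * filters))
  }
  pool <- function(input, p, len, ch) {
    force(input)
    out <- .pool_out(len, p)
    add(.new_layer("maxpool1d", inputs = input, pool = p, stride = p,
                   out_len = out, out_ch = ch))
    out
  }
  drop_ <- function(input, len, ch) {
    force(input)
    add(.new_layer("dropout", inputs = input, rate = rate, out_len = len,
                   out_ch = ch))
  }

  if (config$variant == "no_parallel") {
    trunk_in <- 1L; len <- k; ch_in <- 1L
  } else {
    # two parallel branches: conv(16) -> batchnorm (ReLU) -> pool(2)
    branch_out <- integer(2)
    blen <- NA_integer_
    for (b in 1:2) {
      c1 <- conv(1L, 16L, 1L, k, act = "linear")
      bn <- add(.new_layer("batchnorm", inputs = c1, activation = "relu",
                           out_len = k, out_ch = 16L, params = 4L * 16L,
                           trainable = 2L * 16L))
      blen <- .pool_out(k, 2L)
      branch_out[b] <- add(.new_layer("maxpool1d", inputs = bn, pool = 2L,
                                      stride = 2L, out_len = blen,
                                      out_ch = 16L))
    }
    len <- 2L * blen   # time-axis fusion: two (k/2 x 16) maps -> k x 16
    trunk_in <- add(.new_layer("concatenate", inputs = branch_out,
                               out_len = len, out_ch = 16L))
    ch_in <- 16L
  }

  # block 1: conv16, conv16, pool 2, dropout
  c1 <- conv(trunk_in, 16L, ch_in, len)
  c2 <- conv(c1, 16L, 16L, len)
  len <- pool(c2, 2L, len, 16L)
  d1 <- drop_(li, len, 16L)
  # block 2: conv64, conv64, pool 3, dropout
  c3 <- conv(d1, 64L, 16L, len)
  c4 <- conv(c3, 64L, 64L, len)
  len <- pool(c4, 3L, len, 64L)
  d2 <- drop_(li, len, 64L)
  # block 3: conv64, conv64, pool 4, dropout
  c5 <- conv(d2, 64L, 64L, len)
  c6 <- conv(c5, 64L, 64L, len)
  len <- pool(c6, 4L, len, 64L)
  d3 <- drop_(li, len, 64L)

  if (config$variant %in% c("plus_lstm", "plus_bilstm")) {
    u <- config$rnn_units
    bidir <- config$variant == "plus_bilstm"
    p <- 4L * u * (64L + u + 1L) * (if (bidir) 2L else 1L)
    feat <- if (bidir) 2L * u else u
    rl <- add(.new_layer(if (bidir) "bilstm" else "lstm", inputs = d3,
                         units = u, out_len = feat, out_ch = 1L, flat = TRUE,
                         params = p))
    dense_in <- feat; last <- rl
  } else {
    fl <- add(.new_layer("flatten", inputs = d3, out_len = len * 64L,
                         out_ch = 1L, flat = TRUE))
    dense_in <- len * 64L; last <- fl
  }
  add(.new_layer("dense", inputs = last, units = config$n_classes,
                 activation = "softmax", out_len = config$n_classes,
                 out_ch = 1L, flat = TRUE,
                 params = (dense_in + 1L) * config$n_classes))
  .new_plan(layers, "classifier", k, config$n_classes)
}

#' Tabulate a network plan
#'
#' Renders a plan as a layer table (layer index, type, filters/units,
#' kernel or pool size and stride, output shape, parameter count,
#' upstream connections) in the style of framework model summaries.
#'
#' @param plan A `network_plan`.
#' @return A data frame with one row per layer.
#' @export
plan_table <- function(plan) {
  stopifnot(inherits(plan, "network_plan"))
  rows <- lapply(seq_along(plan$layers), function(i) {
    l <- plan$layers[[i]]
    size <- if (!is.na(l$kernel)) l$kernel else l$pool
    data.frame(
      layer = i,
      type = l$kind,
      units = if (!is.na(l$filters)) l$filters
              else if (!is.na(l$units)) l$units else NA_integer_,
      kernel_stride = if (!is.na(size)) sprintf("%d, %d", size, l$stride)
                      else "-",
      output = if (l$flat) as.character(l$out_len)
               else sprintf("%dx%d", l$out_len, l$out_ch),
      params = l$params,
      connected_to = if (length(l$inputs)) paste(l$inputs, collapse = ",")
                     else "-",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.network_plan <- function(x, ...) {
  cat("<network_plan> ", x$kind, ": input ", x$input_len, " -> output ",
      x$output_dim, "\n", sep = "")
  print(plan_table(x), row.names = FALSE)
  cat("Total params: ", x$total_params,
      " (trainable: ", x$trainable_params, ")\n", sep = "")
  invisible(x)
}
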