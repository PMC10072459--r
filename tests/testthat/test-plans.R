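test_that("compressed length follows k = round(cr * n)", {
  expect_equal(compressed_length(260, 0.2), 52)
  expect_equal(compressed_length(260, 1.0), 260)
  expect_equal(compressed_length(205, 0.05), 10)  # 10.25 rounds down
  expect_equal(compressed_length(260, 0.3), 78)
  expect_error(compressed_length(260, 0), "in \\(0, 1\\]")
  expect_error(compressed_length(260, 1.5), "in \\(0, 1\\]")
  # monotone non-decreasing in cr
  ks <- sapply(c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), function(cr)
    compressed_length(260, cr))
  expect_true(all(diff(ks) >= 0))
})

test_that("compressor plan reproduces the reference shapes and counts", {
  p <- build_compressor_plan(compression_config(260, 0.2))
  tab <- plan_table(p)
  expect_equal(tab$output[1:8],
               c("260x1", "260x16", "130x16", "130x16", "65x16", "65x16",
                 "13x16", "208"))
  expect_equal(tab$params, c(0, 64, 0, 784, 0, 784, 0, 0, 10868))
  expect_equal(p$output_dim, 52)
  # dense in-features are 13 * 16 = 208 for every CR on n = 260,
  # so dense params are 209 * k
  for (cr in c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)) {
    pl <- build_compressor_plan(compression_config(260, cr))
    dense <- pl$layers[[length(pl$layers)]]
    expect_equal(pl$layers[[8]]$out_len, 208)
    expect_equal(dense$params, 209 * pl$output_dim)
  }
})

test_that("compressor plan shape rules chain on non-standard lengths", {
  # n = 40: pools 2, 2, 5 give 20 -> 10 -> 2; dense in 32
  p <- build_compressor_plan(compression_config(40, 0.5))
  lens <- sapply(p$layers, `[[`, "out_len")
  expect_equal(lens[c(3, 5, 7)], c(20, 10, 2))
  expect_equal(p$layers[[8]]$out_len, 32)
  expect_equal(p$layers[[9]]$params, (32 + 1) * 20)
  expect_error(build_compressor_plan(compression_config(16, 0.5)),
               "n >= 20")
})

test_that("classifier plan at k = 52 matches the reference layer table", {
  p <- build_classifier_plan(classifier_config(52))
  tab <- plan_table(p)
  conv_params <- tab$params[tab$type == "conv1d"]
  expect_equal(conv_params, c(64, 64, 784, 784, 3136, 12352, 12352, 12352))
  expect_equal(tab$params[tab$type == "batchnorm"], c(64, 64))
  expect_equal(tab$params[tab$type == "dense"], 516)
  # branch pools 26, concat back to 52, trunk pools 26 -> 8 -> 2, flatten 128
  expect_equal(tab$output[tab$type == "concatenate"], "52x16")
  pool_out <- tab$output[tab$type == "maxpool1d"]
  expect_equal(pool_out, c("26x16", "26x16", "26x16", "8x64", "2x64"))
  expect_equal(tab$output[tab$type == "flatten"], "128")
})

test_that("classifier variants change the topology as advertised", {
  np <- build_classifier_plan(classifier_config(52, variant = "no_parallel"))
  kinds <- sapply(np$layers, `[[`, "kind")
  expect_false("concatenate" %in% kinds)
  expect_false("batchnorm" %in% kinds)
  expect_equal(sum(kinds == "conv1d"), 6)
  lp <- build_classifier_plan(classifier_config(52, variant = "plus_lstm"))
  kinds_l <- sapply(lp$layers, `[[`, "kind")
  expect_true("lstm" %in% kinds_l)
  expect_equal(lp$layers[[which(kinds_l == "lstm")]]$params,
               4 * 64 * (64 + 64 + 1))
  bp <- build_classifier_plan(classifier_config(52, variant = "plus_bilstm"))
  kinds_b <- sapply(bp$layers, `[[`, "kind")
  expect_true("bilstm" %in% kinds_b)
  expect_equal(bp$layers[[which(kinds_b == "bilstm")]]$params,
               2 * 4 * 64 * (64 + 64 + 1))
})

test_that("plans stay consistent across the CR sweep, clamping deep pools", {
  for (cr in c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05)) {
    k <- compressed_length(260, cr)
    p <- suppressMessages(build_classifier_plan(classifier_config(k)))
    # shapes chain: every layer's input length matches its upstream output
    for (i in seq_along(p$layers)) {
      l <- p$layers[[i]]
      if (l$kind %in% c("conv1d", "batchnorm", "dropout"))
        expect_equal(l$out_len, p$layers[[l$inputs[1]]]$out_len)
    }
    expect_equal(p$layers[[length(p$layers)]]$out_len, 4)
  }
  expect_message(build_classifier_plan(classifier_config(13)), "clamped")
})
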