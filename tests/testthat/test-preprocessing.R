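test_that("min-max normalization hits the unit interval and is idempotent", {
  expect_equal(normalize_beat(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_beat(c(3, 3, 3)), c(0, 0, 0))
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(50, sd = runif(1, 0.1, 10))
      y <- normalize_beat(x)
      expect_true(all(y >= 0 & y <= 1))
      expect_equal(normalize_beat(y), y)
    }
  })
})

test_that("segmentation cuts half-open R-centered windows and skips edges", {
  sig <- seq_len(1000) / 1000
  rec <- ecg_record("w", 360, sig,
                    data.frame(sample = c(50, 500), symbol = c("N", "N")))
  seg <- segment_beats(rec, half_width = 130, normalize = FALSE)
  # the annotation at 50 cannot host a 130-sample left flank
  expect_equal(n_beats(seg), 1)
  expect_equal(attr(seg, "skipped"), 1)
  expect_equal(seg$beat_length, 260)
  expect_equal(seg$beats[1, ], sig[370:629])
  # R lands at position half_width + 1
  expect_equal(seg$beats[1, 131], sig[500])
})

test_that("all segmented beats share one length and labels follow symbols", {
  rec <- fixture_record(n = 3000, ann_samples = c(200, 900, 1600, 2950),
                        symbols = c("N", "V", "A", "F"))
  seg <- segment_beats(rec, half_width = 130)
  expect_equal(n_beats(seg), 3)   # the beat at 2950 crosses the right edge
  expect_equal(attr(seg, "skipped"), 1)
  expect_true(all(apply(seg$beats, 1, length) == 260))
  expect_equal(seg$labels, c("N", "V", "A"))
})

test_that("AAMI mapping groups beat symbols and excludes non-beat marks", {
  expect_equal(as.vector(map_aami("/")), "N")   # paced beat
  expect_equal(as.vector(map_aami("f")), "N")   # fusion of paced and normal
  expect_equal(as.vector(map_aami("A")), "S")   # atrial premature contraction
  expect_equal(as.vector(map_aami("E")), "V")   # ventricular escape beat
  expect_equal(as.vector(map_aami("r")), "V")   # R-on-T PVC
  expect_equal(as.vector(map_aami("F")), "F")
  mapped <- map_aami(c("N", "+", "~", "A", "%"))
  expect_equal(as.vector(mapped), c("N", NA, NA, "S", NA))
  expect_equal(sum(attr(mapped, "non_beat")), 2)   # rhythm + noise marks
  expect_equal(sum(attr(mapped, "unmapped")), 1)   # "%" is not in the table
  # every symbol in the table maps to one of the five super-classes
  expect_true(all(aami_mapping() %in% c("N", "S", "V", "F", "Q")))
})

test_that("balancing draws exact per-class counts, deterministically", {
  ds <- fixture_dataset(n_per_class = 25)
  bal <- balance_dataset(ds, c(N = 10, S = 10, V = 10, F = 8), seed = 0)
  expect_equal(n_beats(bal), 38)
  expect_equal(as.vector(table(factor(bal$labels, levels = c("N", "S", "V", "F")))),
               c(10, 10, 10, 8))
  bal2 <- balance_dataset(ds, c(N = 10, S = 10, V = 10, F = 8), seed = 0)
  expect_identical(bal$beats, bal2$beats)
  # full-count targets return a permutation of each class
  full <- balance_dataset(ds, c(N = 25, S = 25), seed = 1)
  for (cl in c("N", "S")) {
    got <- full$beats[full$labels == cl, , drop = FALSE]
    want <- ds$beats[ds$labels == cl, , drop = FALSE]
    expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ])
  }
  expect_error(balance_dataset(ds, c(N = 26), seed = 0), "short by 1")
})

test_that("train/test split is disjoint, exhaustive and seeded", {
  ds <- fixture_dataset(n_per_class = 25)
  sp <- split_train_test(ds, split_config(0.8, 0))
  expect_equal(n_beats(sp$train), 80)
  expect_equal(n_beats(sp$test), 20)
  sp2 <- split_train_test(ds, split_config(0.8, 0))
  expect_identical(sp$train$beats, sp2$train$beats)
  # round-half-to-even on the training size, as for the 3802-beat set
  expect_equal(round(0.8 * 3802), 3042)
  expect_error(split_config(1.2), "train_fraction")
})
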