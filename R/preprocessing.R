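# Pre-processing: beat-wise amplitude normalization, R-peak-centered
# segmentation, AAMI class mapping, class balancing and train/test splitting.
# No filtering or denoising is applied anywhere in the pipeline: beats keep
# their raw morphology so the networks see unaltered signal features.

#' Normalize one beat to the unit interval
#'
#' Min-max normalization per beat: the minimum maps to 0 and the maximum to
#' 1. A constant beat maps to all zeros. The operation is idempotent. A
#' z-score alternative is available via `method = "zscore"` (mean 0, sd 1;
#' not bounded).
#'
#' @param samples Non-empty numeric vector.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Numeric vector of the same length.
#' @examples
#' normalize_beat(c(0, 5, 10))
#' @export
normalize_beat <- function(samples, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(samples) == 0) stop("empty beat")
  if (method == "minmax") {
    rng <- range(samples)
    if (rng[2] == rng[1]) return(rep(0, length(samples)))
    (samples - rng[1]) / (rng[2] - rng[1])
  } else {
    s <- stats::sd(samples)
    if (s == 0) return(rep(0, length(samples)))
    (samples - mean(samples)) / s
  }
}

.normalize_rows <- function(m, method = "minmax") {
  t(apply(m, 1, normalize_beat, method = method))
}

#' Cut R-peak-centered fixed-length beats from an annotated record
#'
#' For every annotation at sample index `r` (taken as the R-peak location,
#' since database beat annotations mark the QRS), the window
#' `[r - half_width, r + half_width - 1]` is extracted, giving beats of
#' `2 * half_width` samples with the annotated peak at position
#' `half_width + 1`. Windows that would cross a record boundary are skipped
#' and counted. Beats carry their annotation symbol as label.
#'
#' @param record An [ecg_record()].
#' @param half_width Samples taken on each side of the R-peak (default 130,
#'   giving 260-sample beats at 360 Hz).
#' @param normalize Apply [normalize_beat()] to each beat (default `TRUE`).
#' @param refine_peak If `TRUE`, re-center each window on the local signal
#'   maximum within +/- 10 samples of the annotation before cutting
#'   (default `FALSE`: annotation indices are trusted as R locations).
#' @return A [beat_dataset()] whose labels are annotation symbols, with
#'   attribute `skipped` giving the number of boundary-skipped annotations.
#' @export
segment_beats <- function(record, half_width = 130, normalize = TRUE,
                          refine_peak = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  half_width <- as.integer(half_width)
  if (half_width < 1) stop("half_width must be >= 1")
  n <- length(record$signal)
  centers <- record$annotations$sample
  if (refine_peak) {
    centers <- vapply(centers, function(r) {
      lo <- max(1L, r - 10L); hi <- min(n, r + 10L)
      lo + which.max(record$signal[lo:hi]) - 1L
    }, integer(1))
  }
  lo <- centers - half_width
  hi <- centers + half_width - 1L
  keep <- lo >= 1L & hi <= n
  n_skipped <- sum(!keep)
  kept <- which(keep)
  L <- 2L * half_width
  beats <- matrix(0, length(kept), L)
  for (i in seq_along(kept)) {
    beats[i, ] <- record$signal[lo[kept[i]]:hi[kept[i]]]
  }
  if (normalize && length(kept) > 0) beats <- .normalize_rows(beats)
  out <- beat_dataset(beats, labels = record$annotations$symbol[kept],
                      beat_length = L)
  attr(out, "skipped") <- n_skipped
  out
}

# MIT-BIH beat symbol -> AAMI super-class. Grouping follows the convention
# that places paced beats and paced/normal fusions under N (together with
# bundle branch blocks and escape beats), atrial/nodal premature beats under
# S, ventricular ectopy (incl. R-on-T and ventricular escape) under V,
# ventricular/normal fusion under F and unclassifiable beats under Q.
.aami_table <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N", "n" = "N",
  "/" = "N", "f" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V", "r" = "V",
  "F" = "F",
  "Q" = "Q", "?" = "Q")

# Annotation symbols that mark rhythm changes, artifacts or waveform
# boundaries rather than beats; excluded from classification, not "unmapped".
.non_beat_symbols <- c("+", "~", "|", "\"", "=", "*", "s", "T", "D", "p",
                       "t", "u", "!", "[", "]", "@", "x", "(", ")", "^", "B")

#' The MIT-BIH to AAMI class mapping table
#'
#' @return Named character vector: names are MIT-BIH annotation symbols,
#'   values are AAMI classes (`N`, `S`, `V`, `F`, `Q`).
#' @export
aami_mapping <- function() .aami_table

#' Map annotation symbols to AAMI classes
#'
#' Beat symbols are mapped to the five AAMI super-classes N/S/V/F/Q.
#' Non-beat annotations (rhythm marks, artifacts, waveform boundaries) map
#' to `NA` and are tallied under attribute `non_beat`; beat-like symbols
#' absent from the table map to `NA` and are tallied under attribute
#' `unmapped` - never silently dropped.
#'
#' @param symbols Character vector of annotation symbols.
#' @return Character vector of AAMI classes (with `NA` for excluded
#'   symbols), with attributes `non_beat` and `unmapped` (named count
#'   tables).
#' @examples
#' map_aami(c("N", "/", "A", "E", "F"))
#' @export
map_aami <- function(symbols) {
  symbols <- as.character(symbols)
  out <- unname(.aami_table[symbols])
  nb <- symbols[is.na(out) & symbols %in% .non_beat_symbols]
  un <- symbols[is.na(out) & !symbols %in% .non_beat_symbols]
  attr(out, "non_beat") <- table(nb)
  attr(out, "unmapped") <- table(un)
  out
}

#' Relabel a symbol-labelled dataset with AAMI classes
#'
#' Applies [map_aami()] to the labels of a segmented dataset and drops beats
#' whose symbol is non-beat or unmapped, carrying the tallies along.
#'
#' @param dataset A [beat_dataset()] labelled with annotation symbols.
#' @return A `beat_dataset` labelled N/S/V/F/Q with attributes `non_beat`
#'   and `unmapped`.
#' @export
label_beats_aami <- function(dataset) {
  stopifnot(inherits(dataset, "beat_dataset"))
  mapped <- map_aami(dataset$labels)
  keep <- which(!is.na(mapped))
  out <- beat_dataset(dataset$beats[keep, , drop = FALSE], mapped[keep],
                      class_names = intersect(c("N", "S", "V", "F", "Q"),
                                              unique(mapped[keep])),
                      beat_length = dataset$beat_length)
  attr(out, "non_beat") <- attr(mapped, "non_beat")
  attr(out, "unmapped") <- attr(mapped, "unmapped")
  out
}

#' Balance a dataset to fixed per-class counts
#'
#' Selects exactly `targets[c]` beats of every class `c` by seeded uniform
#' sampling without replacement; classes absent from `targets` are dropped.
#' The output is ordered class-by-class in the order of `names(targets)`.
#' With the study's targets (N/S/V = 1000 each, F = 802, Q dropped) this
#' yields the 3802-beat working set.
#'
#' @param dataset A [beat_dataset()].
#' @param targets Named integer vector, class -> requested count.
#' @param seed Integer RNG seed (default 0).
#' @return A balanced `beat_dataset` with `class_names = names(targets)`.
#' @export
balance_dataset <- function(dataset, targets, seed = 0) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("targets must be a named vector (class -> count)")
  targets <- round(targets)
  idx <- withr::with_seed(seed, {
    unlist(lapply(names(targets), function(cl) {
      pool <- which(dataset$labels == cl)
      want <- targets[[cl]]
      if (length(pool) < want)
        stop("class ", cl, ": requested ", want, " beats but only ",
             length(pool), " available (short by ", want - length(pool), ")")
      pool[sample.int(length(pool), want)]
    }))
  })
  beat_dataset(dataset$beats[idx, , drop = FALSE], dataset$labels[idx],
               class_names = names(targets), beat_length = dataset$beat_length)
}

#' Train/test split configuration
#'
#' @param train_fraction Proportion of beats assigned to the training set,
#'   in (0, 1); default 0.8.
#' @param seed Integer RNG seed; default 0.
#' @return A `split_config` list.
#' @export
split_config <- function(train_fraction = 0.8, seed = 0) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_config")
}

#' Random train/test split
#'
#' Disjoint, exhaustive split of a dataset into training and test parts.
#' The training size is `round(train_fraction * n)` using R's
#' round-half-to-even rule (3802 beats at 0.8 give 3042 training beats).
#' Reproducible for a fixed seed.
#'
#' @param dataset A [beat_dataset()].
#' @param config A [split_config()].
#' @return List with elements `train` and `test`, both `beat_dataset`s.
#' @export
split_train_test <- function(dataset, config = split_config()) {
  stopifnot(inherits(dataset, "beat_dataset"), inherits(config, "split_config"))
  n <- n_beats(dataset)
  if (n == 0) stop("cannot split an empty dataset")
  n_train <- as.integer(round(config$train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- withr::with_seed(config$seed, sample.int(n))
  list(train = beats_subset(dataset, sort(perm[seq_len(n_train)])),
       test = beats_subset(dataset, sort(perm[(n_train + 1L):n])))
}
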