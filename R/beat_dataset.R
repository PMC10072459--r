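#' Labelled fixed-length heartbeat dataset
#'
#' The pipeline's unit of work: a matrix of fixed-length heartbeat segments
#' with one class label per beat. Rows are beats, columns are samples.
#'
#' @param beats Numeric matrix, one beat per row.
#' @param labels Character (or coercible) vector of per-beat class labels,
#'   length `nrow(beats)`.
#' @param class_names Ordered character vector of admissible labels. Defaults
#'   to the sorted unique labels.
#' @param beat_length Number of samples per beat; defaults to `ncol(beats)`.
#' @return An object of class `beat_dataset` with fields `beats`, `labels`,
#'   `beat_length` and `class_names`.
#' @examples
#' ds <- beat_dataset(matrix(rnorm(20), 4, 5), labels = c("N", "N", "V", "V"))
#' ds$beat_length
#' @export
beat_dataset <- function(beats, labels, class_names = NULL, beat_length = NULL) {
  beats <- as.matrix(beats)
  storage.mode(beats) <- "double"
  labels <- as.character(labels)
  if (is.null(beat_length)) beat_length <- ncol(beats)
  if (ncol(beats) != beat_length)
    stop("beats have ", ncol(beats), " samples per row, expected beat_length = ",
         beat_length)
  if (nrow(beats) != length(labels))
    stop("number of labels (", length(labels), ") does not match number of beats (",
         nrow(beats), ")")
  if (is.null(class_names)) class_names <- sort(unique(labels))
  class_names <- as.character(class_names)
  bad <- setdiff(unique(labels), class_names)
  if (length(bad) > 0)
    stop("labels not in class_names: ", paste(bad, collapse = ", "))
  structure(
    list(beats = beats, labels = labels, beat_length = as.integer(beat_length),
         class_names = class_names),
    class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat("<beat_dataset> ", nrow(x$beats), " beats x ", x$beat_length,
      " samples\n", sep = "")
  if (nrow(x$beats) > 0) {
    tab <- table(factor(x$labels, levels = x$class_names))
    cat("  classes: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Subset a beat dataset by row index
#'
#' @param dataset A [beat_dataset()].
#' @param idx Integer vector of beat (row) indices.
#' @return A `beat_dataset` with the selected beats, preserving `class_names`.
#' @export
beats_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "beat_dataset"))
  beat_dataset(dataset$beats[idx, , drop = FALSE], dataset$labels[idx],
               class_names = dataset$class_names,
               beat_length = dataset$beat_length)
}

#' Number of beats in a dataset
#' @param dataset A [beat_dataset()].
#' @return Integer count of beats.
#' @export
n_beats <- function(dataset) nrow(dataset$beats)
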