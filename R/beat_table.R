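# Delimited-text beat tables: one beat per row, samples first, label last.
# This is the file shape used by public per-beat ECG distributions such as
# the Tianchi heartbeat-classification tables (205 samples + a 0..3 label).

#' Read a delimited beat table
#'
#' Each data row must hold exactly `beat_length` numeric samples followed by
#' one label field. A single header row is detected (first field non-numeric)
#' and skipped. Labels are taken verbatim as strings.
#'
#' @param path Path to a comma-separated beat table.
#' @param beat_length Expected number of samples per beat.
#' @return A [beat_dataset()].
#' @export
read_beat_table <- function(path, beat_length) {
  if (!file.exists(path)) stop("beat table not found: ", path)
  beat_length <- as.integer(beat_length)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_data <- 1L
  if (length(lines) > 0) {
    f1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]][1]
    if (is.na(suppressWarnings(as.numeric(f1)))) first_data <- 2L
  }
  data_lines <- if (length(lines) >= first_data)
    lines[first_data:length(lines)] else character(0)
  n <- length(data_lines)
  if (n == 0) {
    return(beat_dataset(matrix(numeric(0), 0, beat_length),
                        labels = character(0), class_names = character(0),
                        beat_length = beat_length))
  }
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens != beat_length + 1L)
  if (length(bad) > 0)
    stop("row ", bad[1] + first_data - 1L, " has ", lens[bad[1]],
         " fields, expected ", beat_length + 1L)
  flat <- unlist(fields, use.names = FALSE)
  m <- matrix(flat, nrow = n, byrow = TRUE)
  vals <- suppressWarnings(as.numeric(m[, seq_len(beat_length), drop = FALSE]))
  if (anyNA(vals)) {
    bad_cell <- which(is.na(vals))[1]
    stop("non-numeric sample in row ",
         ((bad_cell - 1L) %% n) + first_data, " of ", path)
  }
  beat_dataset(matrix(vals, nrow = n), labels = m[, beat_length + 1L],
               beat_length = beat_length)
}

#' Write a beat dataset as a delimited beat table
#'
#' Writes a header row (`s1..sN,label`) and one row per beat; samples are
#' printed with 17 significant digits so that
#' `read_beat_table(write_beat_table(x))` reproduces `x` exactly.
#'
#' @param dataset A [beat_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  header <- paste(c(paste0("s", seq_len(dataset$beat_length)), "label"),
                  collapse = ",")
  if (nrow(dataset$beats) > 0) {
    num <- apply(dataset$beats, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    rows <- paste(num, dataset$labels, sep = ",")
  } else rows <- character(0)
  ok <- tryCatch({ writeLines(c(header, rows), path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write beat table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
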