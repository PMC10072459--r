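# Minimal WFDB (PhysioNet waveform database) reader/writer: header (.hea),
# signal (.dat, formats 16 and 212) and beat annotations (.atr, MIT format).
# No R package on CRAN/Bioconductor reads WFDB, so the format support here is
# self-contained. Only the subset exercised by annotated single/dual-channel
# ambulatory records (e.g. the MIT-BIH Arrhythmia Database) is implemented.

# Standard WFDB annotation code -> symbol table (codes 1..41).
.wfdb_codes <- c(
  "1" = "N",  "2" = "L",  "3" = "R",  "4" = "a",  "5" = "V",
  "6" = "F",  "7" = "J",  "8" = "A",  "9" = "S",  "10" = "E",
  "11" = "j", "12" = "/", "13" = "Q", "14" = "~", "16" = "|",
  "18" = "s", "19" = "T", "20" = "*", "21" = "D", "22" = "\"",
  "23" = "=", "24" = "p", "25" = "B", "26" = "^", "27" = "t",
  "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x",
  "38" = "f", "39" = "(", "40" = ")", "41" = "r")

.wfdb_symbol_to_code <- function(symbols) {
  codes <- match(symbols, .wfdb_codes)
  if (anyNA(codes))
    stop("annotation symbol(s) with no WFDB code: ",
         paste(unique(symbols[is.na(codes)]), collapse = " "))
  as.integer(names(.wfdb_codes))[codes]
}

#' Annotated single-channel ECG recording
#'
#' @param record_id Record name (string).
#' @param sampling_rate Samples per second (> 0).
#' @param signal Numeric vector of amplitudes (mV) for one channel.
#' @param annotations Data frame with columns `sample` (1-based sample index,
#'   strictly increasing, within the signal) and `symbol` (single-character
#'   annotation code).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, sampling_rate, signal, annotations) {
  sampling_rate <- as.numeric(sampling_rate)
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  signal <- as.numeric(signal)
  annotations <- as.data.frame(annotations)
  if (!all(c("sample", "symbol") %in% names(annotations)))
    stop("annotations need columns 'sample' and 'symbol'")
  annotations$sample <- as.integer(annotations$sample)
  annotations$symbol <- as.character(annotations$symbol)
  if (nrow(annotations) > 0) {
    if (any(diff(annotations$sample) <= 0))
      stop("annotation sample indices must be strictly increasing")
    if (annotations$sample[1] < 1 ||
        annotations$sample[nrow(annotations)] > length(signal))
      stop("annotation sample index outside the signal")
  }
  structure(list(record_id = as.character(record_id),
                 sampling_rate = sampling_rate,
                 signal = signal, annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record> ", x$record_id, ": ", length(x$signal), " samples @ ",
      x$sampling_rate, " Hz, ", nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

.parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty WFDB header: ", hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("malformed WFDB header line in ", hea_path)
  nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1) stop("bad signal count in ", hea_path)
  sig <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(tok) < 2) stop("malformed signal line ", i, " in ", hea_path)
    fmt <- as.integer(sub("[x:+].*$", "", tok[2]))
    gain_tok <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_tok))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_tok))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    else if (length(tok) >= 5) as.numeric(tok[5]) else 0
    if (!is.finite(baseline)) baseline <- 0
    list(file = tok[1], format = fmt, gain = gain, baseline = baseline)
  })
  list(record = sub("/.*$", "", top[1]), nsig = nsig, fs = fs,
       nsamp = nsamp, signals = sig)
}

.read_dat_samples <- function(dat_path, fmt, nsig) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 16) {
    n <- length(raw) %/% 2
    vals <- readBin(raw, "integer", n = n, size = 2, endian = "little",
                    signed = TRUE)
  } else if (fmt == 212) {
    n3 <- (length(raw) %/% 3) * 3
    b <- as.integer(raw[seq_len(n3)])
    b0 <- b[seq(1, n3, by = 3)]; b1 <- b[seq(2, n3, by = 3)]
    b2 <- b[seq(3, n3, by = 3)]
    s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8)
    s2 <- b2 + bitwShiftL(bitwAnd(b1, 0xF0L), 4)
    vals <- as.vector(rbind(s1, s2))
    vals <- ifelse(vals > 2047L, vals - 4096L, vals)
  } else {
    stop("unsupported WFDB signal format ", fmt, " in ", dat_path)
  }
  m <- (length(vals) %/% nsig) * nsig
  matrix(vals[seq_len(m)], ncol = nsig, byrow = TRUE)
}

.read_atr <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.info(atr_path)$size)
  n2 <- (length(raw) %/% 2) * 2
  b <- as.integer(raw[seq_len(n2)])
  words <- b[seq(1, n2, by = 2)] + bitwShiftL(b[seq(2, n2, by = 2)], 8)
  samples <- integer(0); codes <- integer(0)
  t <- 0; skip <- 0; i <- 1
  while (i <= length(words)) {
    w <- words[i]
    a <- bitwShiftR(w, 10)
    interval <- bitwAnd(w, 0x3FFL)
    if (a == 0L && interval == 0L) break
    if (a == 59L) {          # SKIP: next two words hold a 4-byte interval
      if (i + 2 > length(words)) stop("truncated SKIP in ", atr_path)
      skip <- skip + bitwShiftL(words[i + 1], 16) + words[i + 2]
      i <- i + 3
      next
    }
    if (a %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN: field set, no beat
      i <- i + 1
      next
    }
    if (a == 63L) {          # AUX: interval = byte count, padded to even
      i <- i + 1 + (interval + interval %% 2) %/% 2
      next
    }
    t <- t + skip + interval
    skip <- 0
    samples <- c(samples, t)
    codes <- c(codes, a)
    i <- i + 1
  }
  sym <- .wfdb_codes[as.character(codes)]
  sym[is.na(sym)] <- "?"
  data.frame(sample = samples, symbol = unname(sym),
             stringsAsFactors = FALSE)
}

#' Read a WFDB record and its beat annotations
#'
#' Reads a WFDB header (`.hea`), the signal file it names (formats 16 and
#' 212), and the companion annotation file (`.atr`), returning one channel in
#' physical units (mV) together with the full annotation stream. Annotation
#' sample indices are returned 1-based.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param channel 1-based channel index (default 1; lead MLII in most
#'   MIT-BIH records).
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path, channel = 1) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path))
    stop("WFDB header not found: ", hea_path)
  hdr <- .parse_wfdb_header(hea_path)
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 1 || channel > hdr$nsig)
    stop("channel ", channel, " out of bounds for ", hdr$nsig, "-channel record")
  dat_path <- file.path(dirname(hea_path), hdr$signals[[1]]$file)
  if (!file.exists(dat_path))
    stop("WFDB signal file not found: ", dat_path)
  fmt <- hdr$signals[[1]]$format
  adc <- .read_dat_samples(dat_path, fmt, hdr$nsig)
  si <- hdr$signals[[channel]]
  phys <- (adc[, channel] - si$baseline) / si$gain
  atr_path <- file.path(dirname(hea_path), paste0(hdr$record, ".atr"))
  if (!file.exists(atr_path))
    stop("WFDB annotation file not found: ", atr_path)
  ann <- .read_atr(atr_path)
  ann$sample <- ann$sample + 1L   # WFDB times are 0-based
  ecg_record(hdr$record, hdr$fs, phys, ann)
}

#' Write an `ecg_record` as a WFDB record (fixture writer)
#'
#' Writes a `.hea`/`.dat`/`.atr` triple readable by [read_wfdb_record()].
#' The signal is stored in format 16 (16-bit little-endian) with gain 200
#' ADC units/mV; annotations use the MIT annotation format.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  gain <- 200
  adc <- as.integer(round(record$signal * gain))
  if (any(abs(adc) > 32767)) stop("signal amplitude overflows format 16")
  writeLines(c(sprintf("%s 1 %g %d", record$record_id, record$sampling_rate,
                       length(adc)),
               sprintf("%s.dat 16 %d 16 0 0 0 0 ch1", record$record_id, gain)),
             paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(adc, con, size = 2, endian = "little")
  close(con)
  # annotations, MIT format (16-bit little-endian words)
  words <- integer(0)
  t_prev <- 0
  for (r in seq_len(nrow(record$annotations))) {
    t <- record$annotations$sample[r] - 1L   # stored 0-based
    code <- .wfdb_symbol_to_code(record$annotations$symbol[r])
    interval <- t - t_prev
    if (interval > 1023L) {
      words <- c(words, bitwShiftL(59L, 10),
                 bitwShiftR(interval, 16), bitwAnd(interval, 0xFFFFL))
      interval <- 0L
    }
    words <- c(words, bitwShiftL(code, 10) + interval)
    t_prev <- t
  }
  words <- c(words, 0L)
  con <- file(paste0(base, ".atr"), "wb")
  writeBin(as.raw(as.vector(rbind(bitwAnd(words, 0xFFL),
                                  bitwShiftR(words, 8)))), con)
  close(con)
  invisible(base)
}
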