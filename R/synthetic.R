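# Synthetic heartbeat generator: labelled, class-separable fixed-length
# beats built from sums of Gaussian bumps that caricature P/QRS/T
# morphology. Four default classes mirror the gross morphology separating
# the AAMI super-classes: a normal narrow-QRS beat, a premature
# supraventricular-like beat (extra early bump), a wide tall
# ventricular-like beat with inverted T, and an intermediate fused beat.
# This makes every downstream stage testable at desk scale; it does not
# claim physiological fidelity.

.default_templates <- function() {
  list(
    N = data.frame(center = c(-55, 0, 55), width = c(6, 3, 14),
                   amp = c(0.18, 1.00, 0.35)),
    S = data.frame(center = c(-30, 0, 50), width = c(4, 3, 12),
                   amp = c(0.30, 1.00, 0.25)),
    V = data.frame(center = c(0, 50), width = c(11, 16),
                   amp = c(1.25, -0.45)),
    F = data.frame(center = c(-50, 0, 52), width = c(6, 7, 13),
                   amp = c(0.10, 0.85, 0.25)))
}

#' Specification for the synthetic beat generator
#'
#' @param n_classes Number of classes (default 4; must match
#'   `length(class_templates)`).
#' @param beat_length Samples per beat (default 260, as for 360 Hz beats cut
#'   130 samples either side of the R-peak).
#' @param class_templates Named list of data frames with columns `center`
#'   (sample offset from the window center), `width` (Gaussian sd, samples)
#'   and `amp` (amplitude, arbitrary units); one entry per class. The
#'   defaults differ across classes in QRS width, T amplitude and the
#'   presence of an early ectopic bump.
#' @param jitter_sd Sd of the per-beat shift of all bump centers (samples;
#'   default 2 - beats stay R-centered up to annotation-like jitter).
#' @param amplitude_sd Relative sd of per-bump amplitude scaling
#'   (default 0.08).
#' @param noise_sd Sd of additive white Gaussian noise (default 0.03,
#'   "low-noise" relative to the unit QRS amplitude).
#' @param seed Integer RNG seed used by [generate_dataset()] (default 0).
#' @return A `synthetic_beat_spec` list.
#' @export
synthetic_beat_spec <- function(n_classes = 4, beat_length = 260,
                                class_templates = .default_templates(),
                                jitter_sd = 2, amplitude_sd = 0.08,
                                noise_sd = 0.03, seed = 0) {
  if (length(class_templates) != n_classes)
    stop("need one template per class")
  max_w <- max(vapply(class_templates, function(t) max(t$width), numeric(1)))
  if (beat_length < 2 * max_w)
    stop("beat_length must be at least twice the widest template bump")
  structure(list(n_classes = as.integer(n_classes),
                 beat_length = as.integer(beat_length),
                 class_templates = class_templates,
                 jitter_sd = jitter_sd, amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_beat_spec")
}

#' Evaluate a noiseless class template
#'
#' @param spec A [synthetic_beat_spec()].
#' @param class_id Class index (1-based) or class name.
#' @return Numeric vector of length `spec$beat_length`: the deterministic
#'   sum of the class's Gaussian bumps, R-bump at the window center.
#' @export
class_template <- function(spec, class_id) {
  stopifnot(inherits(spec, "synthetic_beat_spec"))
  ok <- if (is.character(class_id)) class_id %in% names(spec$class_templates)
        else !is.na(class_id) && class_id >= 1 && class_id <= spec$n_classes
  if (!ok) stop("invalid class_id: ", class_id)
  tpl <- if (is.character(class_id)) spec$class_templates[[class_id]]
         else spec$class_templates[[as.integer(class_id)]]
  center <- floor(spec$beat_length / 2) + 1
  x <- seq_len(spec$beat_length)
  y <- numeric(spec$beat_length)
  for (b in seq_len(nrow(tpl))) {
    y <- y + tpl$amp[b] * exp(-0.5 * ((x - center - tpl$center[b]) /
                                        tpl$width[b])^2)
  }
  y
}

#' Generate one synthetic beat
#'
#' The beat is the class template with all bump centers shifted by a common
#' `N(0, jitter_sd)` draw, each amplitude scaled by
#' `1 + N(0, amplitude_sd)`, plus `N(0, noise_sd)` white noise. Uses the
#' current RNG state; seed externally (or via [generate_dataset()]) for
#' reproducibility.
#'
#' @param spec A [synthetic_beat_spec()].
#' @param class_id Class index (1-based) or class name.
#' @return Numeric vector of length `spec$beat_length` (unnormalized).
#' @export
generate_beat <- function(spec, class_id) {
  stopifnot(inherits(spec, "synthetic_beat_spec"))
  ok <- if (is.character(class_id)) class_id %in% names(spec$class_templates)
        else !is.na(class_id) && class_id >= 1 && class_id <= spec$n_classes
  if (!ok) stop("invalid class_id: ", class_id)
  tpl <- if (is.character(class_id)) spec$class_templates[[class_id]]
         else spec$class_templates[[as.integer(class_id)]]
  center <- floor(spec$beat_length / 2) + 1
  shift <- if (spec$jitter_sd > 0) stats::rnorm(1, 0, spec$jitter_sd) else 0
  x <- seq_len(spec$beat_length)
  y <- numeric(spec$beat_length)
  for (b in seq_len(nrow(tpl))) {
    a <- tpl$amp[b] *
      (1 + if (spec$amplitude_sd > 0) stats::rnorm(1, 0, spec$amplitude_sd)
           else 0)
    y <- y + a * exp(-0.5 * ((x - center - shift - tpl$center[b]) /
                               tpl$width[b])^2)
  }
  if (spec$noise_sd > 0) y <- y + stats::rnorm(spec$beat_length, 0, spec$noise_sd)
  y
}

#' Generate a balanced labelled synthetic dataset
#'
#' Draws `n_per_class` beats from every class template, min-max normalizes
#' each beat (see [normalize_beat()]) and attaches class labels. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_beat_spec()].
#' @param n_per_class Beats per class (>= 1).
#' @return A [beat_dataset()] of `n_classes * n_per_class` beats.
#' @examples
#' ds <- generate_dataset(synthetic_beat_spec(seed = 1), n_per_class = 5)
#' table(ds$labels)
#' @export
generate_dataset <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "synthetic_beat_spec"))
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  cls <- names(spec$class_templates)
  if (is.null(cls)) cls <- as.character(seq_len(spec$n_classes))
  withr::with_seed(spec$seed, {
    n_total <- spec$n_classes * n_per_class
    beats <- matrix(0, n_total, spec$beat_length)
    labels <- character(n_total)
    row <- 1L
    for (ci in seq_len(spec$n_classes)) {
      for (j in seq_len(n_per_class)) {
        beats[row, ] <- normalize_beat(generate_beat(spec, ci))
        labels[row] <- cls[ci]
        row <- row + 1L
      }
    }
    beat_dataset(beats, labels, class_names = cls,
                 beat_length = spec$beat_length)
  })
}
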