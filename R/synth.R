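#' Configuration for the synthetic multi-record signal generator
#'
#' The generator emulates the shape of a multi-record, two-class,
#' single-lead physiological dataset: per record, a quasi-periodic asymmetric
#' triangular waveform (a sharp rise to a unique peak at each period start, a
#' slow decay to a trough at mid-period, then recovery — a crude QRS-like
#' morphology) plus white noise. The two classes differ in their dominant
#' period, and because the trough sits at half the period, the peak-to-trough
#' spacing inside a 16-sample window — exactly the geometry the descriptor
#' encodes — differs by class. Each record draws one period jitter and one
#' phase offset, so records of the same class are similar but not identical:
#' the structure leave-one-record-out evaluation needs.
#'
#' @param n_records_per_class Records per class (default 10).
#' @param segments_per_record Whole segments each record will yield
#'   (default 4); the record length is `segments_per_record * fs *
#'   duration_s` samples.
#' @param fs Sampling rate in Hz (default 512).
#' @param duration_s Segment duration in seconds (default 15).
#' @param class_period_samples Dominant pulse period of each class, in
#'   samples (default `c(20, 26)`).
#' @param jitter_sd SD of the per-record period jitter, in samples
#'   (default 1).
#' @param noise_sd SD of the additive white noise, in units of the unit
#'   pulse amplitude (default 0.05).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_records_per_class = 10L, segments_per_record = 4L,
                         fs = 512L, duration_s = 15,
                         class_period_samples = c(20L, 26L), jitter_sd = 1,
                         noise_sd = 0.05, seed = 1L) {
  stopifnot(n_records_per_class >= 1, segments_per_record >= 1,
            all(class_period_samples >= 2), jitter_sd >= 0, noise_sd >= 0)
  structure(list(n_records_per_class = as.integer(n_records_per_class),
                 segments_per_record = as.integer(segments_per_record),
                 fs = as.integer(fs), duration_s = duration_s,
                 class_period_samples = as.integer(class_period_samples),
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One period of the asymmetric triangular waveform: a unique peak of +1 at
# phase 0 (reached by a sharp jump from the recovery level), a slow linear
# decay to a unique trough of -0.4 at mid-period, then a linear recovery.
# Because the trough sits at floor(period / 2), the peak-to-trough spacing
# inside a 16-sample window is itself period-dependent, so the two classes
# occupy different descriptor code bins, not merely different bin counts.
pulse_period <- function(period) {
  h <- period %/% 2L
  down <- seq(1, -0.4, length.out = h + 1L)[seq_len(h)]
  up <- seq(-0.4, 0.7, length.out = period - h + 1L)[seq_len(period - h)]
  c(down, up)
}

#' Generate a synthetic two-class multi-record dataset
#'
#' See [synth_config()] for the signal model. Record ids are
#' `"<class>_r<index>"`; class labels are `"classA"` (first period) and
#' `"classB"` (second period).
#'
#' @param cfg A [synth_config()].
#' @return List of [signal_record()] objects (classA records first).
#' @examples
#' recs <- generate_dataset(synth_config(n_records_per_class = 2,
#'                                       segments_per_record = 2))
#' length(recs)  # 4
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  len <- as.integer(cfg$segments_per_record * round(cfg$fs * cfg$duration_s))
  labels <- c("classA", "classB")
  records <- list()
  with_seed(cfg$seed, {
    for (cls in 1:2) {
      base_period <- cfg$class_period_samples[cls]
      for (r in seq_len(cfg$n_records_per_class)) {
        period <- max(4L,
                      as.integer(round(base_period +
                                         stats::rnorm(1, 0, cfg$jitter_sd))))
        phase <- sample.int(period, 1L) - 1L
        wave <- rep_len(pulse_period(period), len + phase)
        x <- wave[(phase + 1L):(phase + len)] +
          stats::rnorm(len, 0, cfg$noise_sd)
        records[[length(records) + 1L]] <-
          signal_record(x, fs = cfg$fs,
                        record_id = sprintf("%s_r%02d", labels[cls], r),
                        label = labels[cls])
      }
    }
  })
  records
}

#' Planted-feature fixture for selector recovery experiments
#'
#' A balanced two-class sample matrix in which the first `n_informative`
#' columns carry a class mean shift of `effect` (in units of the unit noise
#' SD) and the remaining columns are pure noise. Used to test whether the
#' weighting and selection stages recover the informative set.
#'
#' @param n Number of samples (labels balanced to within one).
#' @param n_features Total number of columns.
#' @param n_informative Number of shifted columns (placed first).
#' @param effect Class mean shift of the informative columns.
#' @param seed Integer seed.
#' @return List with `X` (n x n_features matrix), `y` (factor with levels
#'   `"a"`, `"b"`), and `informative` (column indices of the planted
#'   features).
#' @export
generate_planted_feature_matrix <- function(n = 200L, n_features = 20L,
                                            n_informative = 3L, effect = 3,
                                            seed = 1L) {
  stopifnot(n_informative <= n_features, n >= 2)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- with_seed(seed, {
    M <- matrix(stats::rnorm(n * n_features), n, n_features)
    if (n_informative > 0) {
      shift <- effect * (y == "b")
      M[, seq_len(n_informative)] <- M[, seq_len(n_informative)] + shift
    }
    M
  })
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  list(X = X, y = y, informative = seq_len(n_informative))
}
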