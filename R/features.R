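#' Construct a labeled signal record
#'
#' A `signal_record` bundles one continuous physiological recording with its
#' sampling rate, an identifier and a class label. Records are the unit of
#' grouping for leave-one-record-out cross-validation: segments cut from the
#' same record never span the train/test boundary there.
#'
#' @param samples Numeric vector of signal samples (arbitrary units). Must be
#'   finite.
#' @param fs Sampling rate in Hz (positive). Default 512.
#' @param record_id Identifier for the recording (coerced to character).
#' @param label Class label (any atomic scalar; typically one of two classes).
#' @return An object of class `signal_record`.
#' @examples
#' rec <- signal_record(sin(seq_len(7680) / 10), fs = 512, record_id = "r1",
#'                      label = "control")
#' @export
signal_record <- function(samples, fs = 512, record_id, label) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("signal_record: samples must be finite (record ", record_id, ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("signal_record: fs must be a positive scalar")
  }
  structure(
    list(samples = samples, fs = fs,
         record_id = as.character(record_id), label = label),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record %s> %d samples @ %g Hz, label = %s\n",
              x$record_id, length(x$samples), x$fs, as.character(x$label)))
  invisible(x)
}

#' Cut a record into fixed-length non-overlapping segments
#'
#' Splits the record into consecutive windows of `duration_s` seconds
#' (`fs * duration_s` samples each, 7680 for the 15 s / 512 Hz defaults).
#' A trailing remainder shorter than one window is dropped; no padding is
#' applied.
#'
#' @param rec A [signal_record()].
#' @param duration_s Window length in seconds (default 15).
#' @return A list of segments; each is a list with elements `values`,
#'   `record_id`, `label`.
#' @examples
#' rec <- signal_record(rnorm(15360), fs = 512, record_id = "a", label = 1)
#' length(segment_signal(rec))  # 2 segments of 7680 samples
#' @export
segment_signal <- function(rec, duration_s = 15) {
  stopifnot(inherits(rec, "signal_record"), duration_s > 0)
  seg_len <- as.integer(round(rec$fs * duration_s))
  n <- length(rec$samples)
  if (n < seg_len) {
    stop("segment_signal: record '", rec$record_id, "' has ", n,
         " samples, shorter than one window of ", seg_len)
  }
  n_seg <- n %/% seg_len
  lapply(seq_len(n_seg), function(i) {
    list(values = rec$samples[((i - 1L) * seg_len + 1L):(i * seg_len)],
         record_id = rec$record_id, label = rec$label)
  })
}

#' Extract fully overlapping fixed-width blocks from a segment
#'
#' Returns the `Len - W + 1` stride-1 windows of width `W`; window `i` holds
#' samples `i .. i + W - 1`.
#'
#' @param values Numeric vector (a segment's samples).
#' @param W Block width (default 16).
#' @return A `(Len - W + 1) x W` numeric matrix, one block per row.
#' @export
extract_blocks <- function(values, W = 16L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < W) stop("extract_blocks: segment length ", n, " is below W = ", W)
  # embed() yields reversed column order; flip so row i = values[i..i+W-1]
  m <- stats::embed(values, W)[, W:1, drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Locate the minimum and maximum within each block
#'
#' 1-based positions of the extrema; ties resolve to the first occurrence.
#'
#' @param blocks A numeric matrix, one block per row (see [extract_blocks()]).
#' @return List with integer vectors `mini` and `maxi` (values in `1..W`).
#' @export
block_minmax_indices <- function(blocks) {
  if (is.null(dim(blocks))) blocks <- matrix(blocks, nrow = 1L)
  if (!all(is.finite(blocks))) {
    stop("block_minmax_indices: blocks contain non-finite values")
  }
  # max.col(ties.method = "first") gives the first-occurrence arg extremum
  list(mini = max.col(-blocks, ties.method = "first"),
       maxi = max.col(blocks, ties.method = "first"))
}

#' Encode extremum positions as a two-digit base-`base` code
#'
#' `code = base * (maxi - 1) + (mini - 1)`, a bijection from the
#' (maxi, mini) grid onto `0 .. base^2 - 1` (0..255 for base 16).
#'
#' @param mini,maxi Integer vectors of 1-based extremum positions in
#'   `1..base`.
#' @param base Code base, equal to the block width (default 16).
#' @return Integer vector of codes.
#' @export
encode_map <- function(mini, maxi, base = 16L) {
  mini <- as.integer(mini); maxi <- as.integer(maxi)
  if (any(mini < 1L | mini > base) || any(maxi < 1L | maxi > base)) {
    stop("encode_map: extremum positions must lie in 1..", base)
  }
  base * (maxi - 1L) + (mini - 1L)
}

#' MinMaxPat descriptor of one segment
#'
#' The core local descriptor: slide a `W`-sample window across the segment at
#' stride 1, record the 1-based positions of the window minimum and maximum,
#' encode each pair as `W * (maxi - 1) + (mini - 1)`, and histogram the codes.
#' The result is a `W^2`-bin count vector (256 bins for the default `W = 16`)
#' whose entries sum to `Len - W + 1`. Counts are raw integers; set
#' `normalize = TRUE` to divide by the block count.
#'
#' The descriptor is invariant to adding a constant or rescaling by a positive
#' factor (arg-extrema do not move), which makes it robust to baseline offset
#' and gain differences between recordings.
#'
#' @param values Numeric vector, the segment samples (length at least `W`).
#' @param W Block width and code base (default 16).
#' @param normalize If `TRUE`, return per-block frequencies instead of counts.
#' @return Numeric vector of length `W^2` with bin names `c000, c001, ...`.
#' @examples
#' fv <- minmaxpat(sin(seq_len(7680) / 5))
#' length(fv)  # 256
#' sum(fv)     # 7665 blocks
#' @export
minmaxpat <- function(values, W = 16L, normalize = FALSE) {
  W <- as.integer(W)
  blocks <- extract_blocks(values, W)
  ext <- block_minmax_indices(blocks)
  codes <- encode_map(ext$mini, ext$maxi, base = W)
  counts <- tabulate(codes + 1L, nbins = W * W)
  if (normalize) counts <- counts / nrow(blocks)
  names(counts) <- sprintf("c%03d", seq_len(W * W) - 1L)
  counts
}

#' Build the segment-level feature matrix for a set of records
#'
#' Segments every record, applies [minmaxpat()] to each segment, and stacks
#' the descriptors into one matrix with aligned label and record-id vectors.
#' Row order is record order, then segment order within the record, so
#' grouping by record id is preserved for leave-one-record-out evaluation.
#'
#' @param records List of [signal_record()] objects.
#' @param duration_s Segment length in seconds (default 15).
#' @param W Block width / code base (default 16).
#' @param normalize Passed to [minmaxpat()].
#' @return An object of class `feature_matrix`: list with `X` (segments x
#'   `W^2` matrix), `y` (factor of labels) and `record_ids` (character).
#' @export
build_feature_matrix <- function(records, duration_s = 15, W = 16L,
                                 normalize = FALSE) {
  if (length(records) == 0L) stop("build_feature_matrix: no records supplied")
  segs <- unlist(lapply(records, segment_signal, duration_s = duration_s),
                 recursive = FALSE)
  X <- t(vapply(segs, function(s) minmaxpat(s$values, W = W,
                                            normalize = normalize),
                numeric(W * W)))
  feature_matrix(
    X,
    labels = vapply(segs, function(s) as.character(s$label), character(1)),
    record_ids = vapply(segs, function(s) s$record_id, character(1))
  )
}

#' Assemble a feature matrix object from components
#'
#' @param X Numeric matrix, one row per segment.
#' @param labels Vector of class labels aligned to rows.
#' @param record_ids Vector of record identifiers aligned to rows.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(X, labels, record_ids) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels) || nrow(X) != length(record_ids)) {
    stop("feature_matrix: rows (", nrow(X), "), labels (", length(labels),
         ") and record_ids (", length(record_ids), ") must align")
  }
  structure(list(X = X, y = factor(labels),
                 record_ids = as.character(record_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features, %d records, classes: %s\n",
              nrow(x$X), ncol(x$X), length(unique(x$record_ids)),
              paste(levels(x$y), collapse = ", ")))
  invisible(x)
}
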