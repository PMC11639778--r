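#' Write a feature matrix as CSV with a label sidecar
#'
#' The matrix is written with columns `c000..c255` (for the default
#' descriptor); a sidecar file `<path minus .csv>_labels.csv` holds the
#' aligned `record_id` and `label` columns.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("c%03d", seq_len(ncol(X)) - 1L)
  }
  write.csv(as.data.frame(X), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, "_labels.csv")
  write.csv(data.frame(record_id = fm$record_ids,
                       label = as.character(fm$y)),
            sidecar, row.names = FALSE)
  invisible(sidecar)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Feature CSV path; the label sidecar is located automatically
#'   (or given explicitly).
#' @param sidecar Optional explicit sidecar path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) {
    sidecar <- paste0(sub("\\.csv$", "", path), "_labels.csv")
  }
  X <- as.matrix(read.csv(path, check.names = FALSE))
  meta <- read.csv(sidecar, colClasses = "character")
  feature_matrix(X, labels = meta$label, record_ids = meta$record_id)
}

#' Write records as per-record CSV files plus a manifest
#'
#' Each record becomes `<record_id>.csv` (a single `value` column); the
#' manifest CSV maps `file` to `record_id`, `label` and `fs`.
#'
#' @param records List of [signal_record()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    fn <- paste0(r$record_id, ".csv")
    write.csv(data.frame(value = r$samples), file.path(dir, fn),
              row.names = FALSE)
    data.frame(file = fn, record_id = r$record_id,
               label = as.character(r$label), fs = r$fs)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read records from a manifest CSV
#'
#' The manifest must have columns `file`, `record_id`, `label`, and
#' optionally `fs` (default 512). Each referenced file is a delimited text
#' file containing one numeric signal (one value per row, header optional).
#'
#' @param manifest Path to the manifest CSV; record files are resolved
#'   relative to its directory.
#' @param fs_default Sampling rate used when the manifest has no `fs`
#'   column.
#' @return List of [signal_record()]s.
#' @export
read_records <- function(manifest, fs_default = 512) {
  m <- read.csv(manifest)
  need <- c("file", "record_id", "label")
  if (!all(need %in% names(m))) {
    stop("read_records: manifest must have columns ",
         paste(need, collapse = ", "))
  }
  base <- dirname(manifest)
  lapply(seq_len(nrow(m)), function(i) {
    f <- file.path(base, m$file[i])
    if (!file.exists(f)) stop("read_records: missing file '", f, "'")
    first <- readLines(f, n = 1L)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, "[,;\t ]+")[[1]][1])))
    vals <- unlist(read.csv(f, header = has_header), use.names = FALSE)
    fs <- if ("fs" %in% names(m)) m$fs[i] else fs_default
    signal_record(vals, fs = fs, record_id = m$record_id[i],
                  label = m$label[i])
  })
}
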