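#' Construct a labeled ECG recording
#'
#' The unit of every dataset handled by the package: a single-lead ECG trace
#' with its sampling rate and diagnostic class.
#'
#' @param record_id Character scalar identifying the recording.
#' @param samples Numeric vector of voltage samples (arbitrary units,
#'   typically mV).
#' @param fs Sampling rate in Hz; must be positive. The public three-class
#'   cohort this package emulates is sampled at 128 Hz.
#' @param label Diagnostic class, one of `"ARR"`, `"CHF"`, `"NSR"`.
#'
#' @return An object of class `ecg_record`: a list with fields `record_id`,
#'   `samples`, `fs` and `label`.
#' @examples
#' rec <- ecg_record("demo", sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 128)),
#'                   fs = 128, label = "NSR")
#' rec
#' @export
ecg_record <- function(record_id, samples, fs, label) {
  assert_that(is.character(record_id) && length(record_id) == 1,
              "record_id must be a single string")
  samples <- as.numeric(samples)
  assert_that(length(samples) >= 1, "record must contain at least one sample")
  assert_that(all(is.finite(samples)), "record contains non-finite samples")
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be > 0")
  label <- as.character(label)
  assert_that(label %in% ECG_CLASSES,
              "unknown label '", label, "' for record ", record_id)
  structure(list(record_id = record_id, samples = samples,
                 fs = as.numeric(fs), label = label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> %d samples @ %g Hz, label %s\n",
              x$record_id, length(x$samples), x$fs, x$label))
  invisible(x)
}

#' Load a dataset manifest
#'
#' Reads a CSV manifest with header `record_id,path,label`, one recording per
#' row, validates every label against [ecg_classes()] and computes per-class
#' counts. Rows are returned in lexicographic `record_id` order so that
#' downstream splits are reproducible across platforms.
#'
#' @param root_path Directory holding the per-record signal files.
#' @param manifest_file Path to the manifest CSV. Defaults to
#'   `manifest.csv` inside `root_path`.
#'
#' @return A tibble of class `ecg_manifest` with columns `record_id`, `path`,
#'   `label` and an attribute `class_counts` (named integer vector over all
#'   three classes). Retrieve the counts with [class_counts()].
#' @seealso [write_dataset()] which emits this layout for synthetic data.
#' @export
load_manifest <- function(root_path, manifest_file = file.path(root_path, "manifest.csv")) {
  assert_that(file.exists(manifest_file), "manifest file not found: ", manifest_file)
  df <- read.csv(manifest_file, stringsAsFactors = FALSE)
  required <- c("record_id", "path", "label")
  assert_that(all(required %in% names(df)),
              "manifest must have columns record_id,path,label")
  assert_that(nrow(df) > 0, "empty manifest: ", manifest_file)
  bad <- which(!df$label %in% ECG_CLASSES)
  if (length(bad) > 0) {
    stop_ecg("unknown label '", df$label[bad[1]], "' in manifest row ",
             bad[1], " (record_id ", df$record_id[bad[1]], ")")
  }
  df <- df[order(df$record_id), required, drop = FALSE]
  out <- tibble::as_tibble(df)
  counts <- table(factor(df$label, levels = ECG_CLASSES))
  attr(out, "class_counts") <- stats::setNames(as.integer(counts), ECG_CLASSES)
  attr(out, "root_path") <- root_path
  class(out) <- c("ecg_manifest", class(out))
  out
}

#' Per-class record counts of a manifest
#'
#' @param manifest An `ecg_manifest` (from [load_manifest()]) or any data
#'   frame with a `label` column.
#' @return Named integer vector over `ARR`, `CHF`, `NSR`.
#' @export
class_counts <- function(manifest) {
  cc <- attr(manifest, "class_counts")
  if (!is.null(cc)) return(cc)
  counts <- table(factor(manifest$label, levels = ECG_CLASSES))
  stats::setNames(as.integer(counts), ECG_CLASSES)
}

#' Read one ECG record from a signal file
#'
#' Native record format: a plain-text file with one numeric sample per line
#' (a header line is tolerated). Binary/WFDB formats are out of scope; the
#' synthetic generator writes this same format so synthetic and on-disk data
#' are interchangeable.
#'
#' @param path File holding the numeric vector.
#' @param record_id,label,fs Metadata for the record (see [ecg_record()]).
#' @return An [ecg_record()].
#' @export
read_ecg_record <- function(path, record_id, label, fs = 128) {
  assert_that(file.exists(path), "signal file not found: ", path)
  first <- readLines(path, n = 1)
  skip <- if (suppressWarnings(is.na(as.numeric(first)))) 1L else 0L
  x <- scan(path, what = numeric(), skip = skip, quiet = TRUE)
  ecg_record(record_id, x, fs = fs, label = label)
}

#' Load every record listed in a manifest
#'
#' @param manifest An `ecg_manifest` from [load_manifest()].
#' @param root_path Directory the manifest's relative paths resolve against;
#'   defaults to the directory the manifest was loaded from.
#' @param fs Sampling rate to attach to each record (Hz).
#' @return List of [ecg_record()] objects, in manifest order.
#' @export
load_records <- function(manifest, root_path = attr(manifest, "root_path"), fs = 128) {
  purrr::pmap(list(manifest$path, manifest$record_id, manifest$label),
              function(p, id, lab) {
                full <- if (file.exists(p)) p else file.path(root_path, p)
                read_ecg_record(full, id, lab, fs = fs)
              })
}

#' Cut a fixed-length segment from a record
#'
#' Extracts `samples[offset : offset + length)` using 0-based half-open
#' indexing. Records shorter than `offset + length` are rejected rather than
#' padded: the cohorts this mirrors are hours long, and padding semantics for
#' a truncated ECG are undefined.
#'
#' @param record An [ecg_record()].
#' @param length Segment length in samples (default 1000, i.e. the first
#'   ~7.8 s at 128 Hz).
#' @param offset 0-based starting sample (default 0).
#' @return An object of class `ecg_segment`: list with `record_id`, `values`,
#'   `label`, `normalized = FALSE`.
#' @examples
#' rec <- ecg_record("r", seq_len(2000) - 1, fs = 128, label = "ARR")
#' seg <- extract_segment(rec, length = 1000, offset = 500)
#' range(seg$values)  # 500 .. 1499
#' @export
extract_segment <- function(record, length = 1000, offset = 0) {
  assert_that(inherits(record, "ecg_record"), "record must be an ecg_record")
  assert_that(length >= 1 && length == round(length), "length must be a positive integer")
  assert_that(offset >= 0 && offset == round(offset), "offset must be >= 0")
  n <- base::length(record$samples)
  assert_that(n >= offset + length,
              "record too short: ", record$record_id, " has ", n,
              " samples, need ", offset + length)
  values <- record$samples[(offset + 1):(offset + length)]
  structure(list(record_id = record$record_id, values = values,
                 label = record$label, normalized = FALSE),
            class = "ecg_segment")
}

#' Z-normalize a segment to zero mean and unit variance
#'
#' Uses the population (divide-by-N) standard deviation, so "unit variance"
#' holds literally; this is also the usual deep-learning preprocessing
#' convention. Constant segments are rejected rather than silently divided.
#' The operation is idempotent: renormalizing a normalized segment leaves it
#' unchanged (up to floating point).
#'
#' @param segment An `ecg_segment` from [extract_segment()].
#' @return The segment with `values` standardized and `normalized = TRUE`.
#' @export
znormalize <- function(segment) {
  assert_that(inherits(segment, "ecg_segment"), "segment must be an ecg_segment")
  v <- segment$values
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  assert_that(s > 1e-12, "zero-variance segment: ", segment$record_id)
  segment$values <- (v - m) / s
  segment$normalized <- TRUE
  segment
}

#' Write a list of records to a directory in the native format
#'
#' One plain-text signal file per record (`<record_id>.csv`, header `value`)
#' plus `manifest.csv` with header `record_id,path,label` — the exact layout
#' [load_manifest()] and [load_records()] consume, so synthetic datasets can
#' round-trip through disk.
#'
#' @param records List of [ecg_record()]s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the manifest file.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(records, function(r) {
    fname <- paste0(r$record_id, ".csv")
    writeLines(c("value", format(r$samples, digits = 10, trim = TRUE, scientific = FALSE)),
               file.path(dir, fname))
    tibble::tibble(record_id = r$record_id, path = fname, label = r$label)
  })
  manifest <- dplyr::bind_rows(rows)
  manifest <- manifest[order(manifest$record_id), ]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
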