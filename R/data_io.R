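# Reading, writing and conditioning of parcellated sessions.

#' Construct a parcellated session time series
#'
#' One scanning session: the frames-by-parcel matrix of BOLD values for one
#' subject at one timepoint, possibly concatenating several runs (separate
#' acquisitions). Run boundaries are tracked because no dwell time or state
#' transition is ever allowed to span two runs.
#'
#' @param data numeric matrix, frames x parcels.
#' @param subject_id subject identifier.
#' @param group group label, e.g. "TRD" or "HC".
#' @param timepoint session label, e.g. "baseline" or "post".
#' @param run_boundaries integer vector of first-frame indices of each run
#'   (1-based, first element 1). Default: a single run.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param fd_mm per-frame framewise displacement in mm; the first frame of a
#'   run has no preceding frame and is stored as 0 by convention.
#' @param zscored logical flag: has per-parcel standardization been applied?
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(data, subject_id, group, timepoint,
                   run_boundaries = 1L, tr_seconds = 0.8,
                   fd_mm = NULL, zscored = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) stop("session matrix must be numeric with no missing values")
  if (nrow(data) < 2) stop("a session needs at least 2 frames")
  run_boundaries <- as.integer(run_boundaries)
  if (run_boundaries[1] != 1L || is.unsorted(run_boundaries, strictly = TRUE))
    stop("run_boundaries must be strictly increasing and start at 1")
  if (any(run_boundaries > nrow(data))) stop("run boundary beyond last frame")
  if (is.null(fd_mm)) fd_mm <- numeric(nrow(data))
  if (length(fd_mm) != nrow(data)) stop("fd_mm length must equal frame count")
  structure(list(
    subject_id = as.character(subject_id), group = as.character(group),
    timepoint = as.character(timepoint), data = data,
    run_boundaries = run_boundaries, tr_seconds = tr_seconds,
    fd_mm = as.numeric(fd_mm), zscored = isTRUE(zscored)
  ), class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s [%s/%s]: %d frames x %d parcels, %d run(s), TR = %gs, %s\n",
              x$subject_id, x$group, x$timepoint, nrow(x$data), ncol(x$data),
              length(x$run_boundaries), x$tr_seconds,
              if (x$zscored) "z-scored" else "raw"))
  invisible(x)
}

# frames of each run as a list of row-index vectors
run_index_list <- function(n_frames, run_boundaries) {
  starts <- run_boundaries
  ends <- c(run_boundaries[-1] - 1L, n_frames)
  Map(seq.int, starts, ends)
}

#' Write one run's frames-by-parcel matrix as TSV
#'
#' Plain UTF-8 TSV: header row of parcel ids, one row per frame, '.' decimal.
#'
#' @param mat frames x parcels numeric matrix.
#' @param path output path.
#' @param parcel_ids integer parcel ids for the header (default 1..ncol).
#' @export
write_session_matrix <- function(mat, path, parcel_ids = seq_len(ncol(mat))) {
  stopifnot(is.matrix(mat), length(parcel_ids) == ncol(mat))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(parcel_ids, collapse = "\t"), con)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read one run's frames-by-parcel matrix from TSV
#'
#' @param path TSV file written by [write_session_matrix()] (header row of
#'   parcel ids, one row per frame).
#' @param parcel_table optional parcel table; if given, the file's column
#'   count and parcel ids are checked against it.
#' @return numeric matrix frames x parcels.
#' @export
read_session_matrix <- function(path, parcel_table = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop(sprintf("%s: need a header and at least one frame", path))
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  p <- length(ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != p)) {
    bad <- which(nfield != p)[1]
    stop(sprintf("%s: ragged row %d (%d fields, expected %d)", path, bad, nfield[bad], p))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1]
    stop(sprintf("%s: non-numeric cell at frame %d, column %d",
                 path, (flat - 1) %/% p + 1, (flat - 1) %% p + 1))
  }
  mat <- matrix(vals, ncol = p, byrow = TRUE)
  if (!is.null(parcel_table)) {
    validate_parcel_table(parcel_table)
    if (p != nrow(parcel_table))
      stop(sprintf("%s: %d parcel columns but parcel table has %d rows",
                   path, p, nrow(parcel_table)))
    if (!identical(as.integer(ids), as.integer(parcel_table$parcel_id)))
      stop(sprintf("%s: header parcel ids do not match parcel table order", path))
  }
  mat
}

manifest_columns <- c("subject_id", "group", "timepoint", "run_index", "path",
                      "age", "sex", "mean_fd", "hdrs",
                      "rrs_brooding", "rrs_reflection", "rrs_reappraisal")

#' Write / read a cohort manifest
#'
#' The manifest has one row per (subject, timepoint, run): group membership,
#' path to the run's matrix file, covariates (age, sex), mean framewise
#' displacement, and mood scores (HDRS; RRS brooding/reflection/reappraisal).
#' Mood scores may be NA for rows where a scale was not administered.
#'
#' @param manifest data.frame with the manifest columns.
#' @param path TSV path.
#' @export
write_manifest <- function(manifest, path) {
  need_fields(manifest, manifest_columns, "manifest")
  utils::write.table(manifest[, manifest_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @param check_paths if TRUE, error when a referenced matrix file is absent.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         colClasses = c(subject_id = "character", group = "character",
                                        timepoint = "character", path = "character",
                                        sex = "character"))  # "F" must not parse as FALSE
  need_fields(m, manifest_columns, "manifest")
  key <- paste(m$subject_id, m$timepoint, m$run_index)
  if (anyDuplicated(key)) stop("manifest has duplicate (subject, timepoint, run) rows")
  if (check_paths) {
    missing <- !file.exists(m$path)
    if (any(missing))
      stop(sprintf("manifest references missing file(s): %s",
                   paste(utils::head(m$path[missing], 3), collapse = ", ")))
  }
  m
}

#' Z-score a session's parcel time series
#'
#' Standardizes each parcel's time course to mean 0, sd 1 (denominator n-1)
#' so frames express relative activation/deactivation. Default is per run:
#' each run is standardized separately before frames are pooled, which
#' removes run-level offsets; set `per = "session"` to standardize across
#' the concatenated session instead.
#'
#' @param ts an [roi_ts()].
#' @param per "run" (default) or "session".
#' @param constant_policy what to do with a zero-variance parcel: "error"
#'   (default) or "zero" (emit zeros for that parcel, with a warning).
#' @return the z-scored `roi_ts` (flagged `zscored`).
#' @export
zscore_session <- function(ts, per = c("run", "session"), constant_policy = c("error", "zero")) {
  stopifnot(inherits(ts, "roi_ts"))
  per <- match.arg(per)
  constant_policy <- match.arg(constant_policy)
  if (ts$zscored) stop("session is already z-scored")
  blocks <- if (per == "run") run_index_list(nrow(ts$data), ts$run_boundaries)
            else list(seq_len(nrow(ts$data)))
  out <- ts$data
  for (idx in blocks) {
    block <- ts$data[idx, , drop = FALSE]
    mu <- colMeans(block)
    sd <- apply(block, 2, stats::sd)
    zero <- sd < 1e-12
    if (any(zero)) {
      if (constant_policy == "error")
        stop(sprintf("zero-variance parcel(s) in z-scoring: %s",
                     paste(utils::head(which(zero), 5), collapse = ", ")))
      warning(sprintf("%d constant parcel(s) set to zero during z-scoring", sum(zero)))
      sd[zero] <- 1
      mu[zero] <- block[1, zero]
    }
    out[idx, ] <- sweep(sweep(block, 2, mu, "-"), 2, sd, "/")
  }
  ts$data <- out
  ts$zscored <- TRUE
  ts
}

#' Motion quality control on mean framewise displacement
#'
#' Retains sessions whose mean FD is strictly below the threshold (the
#' inclusion rule is "moved less than `threshold_mm` on average"; a session
#' at exactly the threshold is excluded). Exclusion is escalated to the
#' subject: if any of a subject's sessions fails, all of that subject's rows
#' are excluded, since longitudinal contrasts need both sessions.
#'
#' @param manifest cohort manifest data.frame (needs `mean_fd`).
#' @param threshold_mm threshold in mm, default 0.5.
#' @return list with `retained` and `excluded` manifest subsets.
#' @export
qc_mean_fd <- function(manifest, threshold_mm = 0.5) {
  need_fields(manifest, c("subject_id", "mean_fd"), "manifest")
  if (anyNA(manifest$mean_fd)) stop("mean_fd missing for some sessions")
  fail_row <- manifest$mean_fd >= threshold_mm
  bad_subjects <- unique(manifest$subject_id[fail_row])
  excl <- manifest$subject_id %in% bad_subjects
  list(retained = manifest[!excl, , drop = FALSE],
       excluded = manifest[excl, , drop = FALSE])
}
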