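#' Voxel-level recording of one region
#'
#' A volumes x voxels matrix of BOLD time courses for a single region of
#' one hemisphere, with a per-voxel tissue label.  Row `t` is the state
#' vector of the region at volume `t` — the instances entering the
#' nearest-neighbour rank statistics.
#'
#' @param region_id One of `"precentral"`, `"sulcus"`, `"postcentral"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param data Numeric matrix, `n_volumes` rows x `n_voxels` columns,
#'   all values finite.
#' @param tissue Character vector of length `n_voxels` with values
#'   `"cortex"` or `"white_matter"`. Defaults to all-cortex.
#' @return An object of class `region_recording`.
#' @export
region_recording <- function(region_id, hemisphere, data, tissue = NULL) {
  region_id <- match.arg(region_id, REGIONS)
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 1) stop_field("%s/%s: recording needs at least one voxel",
                                 hemisphere, region_id)
  if (!all(is.finite(data)))
    stop_field("%s/%s: non-finite values in data", hemisphere, region_id)
  if (is.null(tissue)) tissue <- rep("cortex", ncol(data))
  if (length(tissue) != ncol(data))
    stop_field("%s/%s: tissue has length %d but data has %d voxels",
               hemisphere, region_id, length(tissue), ncol(data))
  if (!all(tissue %in% TISSUES))
    stop_field("%s/%s: tissue labels must be in {%s}", hemisphere, region_id,
               paste(TISSUES, collapse = ", "))
  structure(list(region_id = region_id, hemisphere = hemisphere,
                 data = data, tissue = as.character(tissue)),
            class = "region_recording")
}

#' @export
print.region_recording <- function(x, ...) {
  cat(sprintf("Region recording %s/%s: %d volumes x %d voxels (%d cortex, %d white matter)\n",
              x$hemisphere, x$region_id, nrow(x$data), ncol(x$data),
              sum(x$tissue == "cortex"), sum(x$tissue == "white_matter")))
  invisible(x)
}

#' All recordings of one subject
#'
#' Bundles the six region recordings (2 hemispheres x 3 regions) of one
#' subject with the task protocol they share.
#'
#' @param subject_id Character identifier.
#' @param protocol A [task_protocol()].
#' @param regions A list of six [region_recording()]s (any order); all
#'   must have `protocol$n_volumes` rows and cover each
#'   hemisphere/region pair exactly once.
#' @param provenance Optional list with generator metadata.
#' @return An object of class `subject_recording`. Regions are stored
#'   under names `"<hemisphere>_<region>"`.
#' @export
subject_recording <- function(subject_id, protocol, regions, provenance = NULL) {
  stopifnot(inherits(protocol, "task_protocol"))
  if (length(regions) != 6L) stop_field("subject %s: expected 6 region recordings, got %d",
                                        subject_id, length(regions))
  keys <- character(6)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!inherits(r, "region_recording"))
      stop_field("subject %s: regions[[%d]] is not a region_recording", subject_id, i)
    if (nrow(r$data) != protocol$n_volumes)
      stop_field("subject %s: %s/%s has %d volumes but protocol says %d",
                 subject_id, r$hemisphere, r$region_id, nrow(r$data), protocol$n_volumes)
    keys[i] <- paste(r$hemisphere, r$region_id, sep = "_")
  }
  if (anyDuplicated(keys) || length(setdiff(region_keys(), keys)))
    stop_field("subject %s: regions must cover each hemisphere/region pair exactly once",
               subject_id)
  names(regions) <- keys
  structure(list(subject_id = as.character(subject_id), protocol = protocol,
                 regions = regions[region_keys()], provenance = provenance),
            class = "subject_recording")
}

region_keys <- function() {
  as.vector(outer(HEMISPHERES, REGIONS, paste, sep = "_"))
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("Subject recording '%s': %d volumes, 6 regions\n",
              x$subject_id, x$protocol$n_volumes))
  invisible(x)
}

#' Fetch one region of a subject
#' @param subject A [subject_recording()].
#' @param hemisphere,region_id Which recording.
#' @return The [region_recording()].
#' @export
get_region <- function(subject, hemisphere, region_id) {
  subject$regions[[paste(match.arg(hemisphere, HEMISPHERES),
                         match.arg(region_id, REGIONS), sep = "_")]]
}

#' Drop white-matter voxels
#'
#' Returns the recording restricted to voxels labelled `cortex`,
#' preserving voxel order.  Used for the cortex-only definition of the
#' sulcus, which excludes white-matter voxels that carry signal from
#' fibres connecting the two gyri.
#'
#' @param recording A [region_recording()].
#' @return A [region_recording()] with only cortex voxels.
#' @export
restrict_to_cortex <- function(recording) {
  stopifnot(inherits(recording, "region_recording"))
  keep <- recording$tissue == "cortex"
  if (!any(keep))
    stop_field("%s/%s: no cortex voxels to keep", recording$hemisphere,
               recording$region_id)
  region_recording(recording$region_id, recording$hemisphere,
                   recording$data[, keep, drop = FALSE], recording$tissue[keep])
}

#' Region-mean time series
#'
#' Collapses a volumes x voxels matrix to the per-volume arithmetic mean
#' over voxels — the univariate series consumed by the mutual-information
#' and Granger baselines.
#'
#' @param x A numeric matrix or [region_recording()].
#' @return Numeric vector of length `n_volumes`; the `epoch` attribute
#'   of `x`, if any, is preserved.
#' @export
region_mean <- function(x) {
  if (inherits(x, "region_recording")) x <- x$data
  x <- as.matrix(x)
  if (ncol(x) < 1) stop_field("region_mean needs at least one voxel column")
  out <- rowMeans(x)
  attr(out, "epoch") <- attr(x, "epoch")
  out
}

#' Extract the volumes selected by a segment set
#'
#' Row-concatenates the windows of `segments` in temporal order.  The
#' result carries an `epoch` attribute (integer window id per row) so
#' that lagged statistics can avoid pairing samples across window
#' boundaries: each window is an independent epoch.
#'
#' @param x A numeric matrix (volumes x voxels) or [region_recording()].
#' @param segments A [segment_set()]; all windows must lie inside the
#'   recording.
#' @return A numeric matrix with `sum(ends - starts)` rows and an
#'   `epoch` attribute.
#' @export
extract_segments <- function(x, segments) {
  if (inherits(x, "region_recording")) x <- x$data
  x <- as.matrix(x)
  stopifnot(inherits(segments, "segment_set"))
  if (length(segments$ends) && max(segments$ends) > nrow(x))
    stop_field("segment window [%d, %d) exceeds the %d recorded volumes",
               segments$starts[which.max(segments$ends)], max(segments$ends), nrow(x))
  idx <- integer(0); epoch <- integer(0)
  for (w in seq_along(segments$starts)) {
    rows <- seq.int(segments$starts[w] + 1L, segments$ends[w])
    idx <- c(idx, rows)
    epoch <- c(epoch, rep.int(w, length(rows)))
  }
  out <- x[idx, , drop = FALSE]
  attr(out, "epoch") <- epoch
  out
}

#' Standardize voxel time courses
#'
#' Z-scores every column (voxel) of a matrix over its rows, the segment
#' actually analysed.  BOLD offsets and per-voxel gains are arbitrary,
#' so distances are computed on standardized series by default.
#' Constant voxels become all-zero rather than NaN.
#'
#' @param x Numeric matrix, rows = volumes.
#' @return Matrix of the same shape; `epoch` attribute preserved.
#' @export
standardize_voxels <- function(x) {
  x <- as.matrix(x)
  epoch <- attr(x, "epoch")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(out, "epoch") <- epoch
  out
}
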