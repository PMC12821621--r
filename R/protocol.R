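#' @keywords internal
"_PACKAGE"

# Controlled vocabularies shared across the package.
REGIONS <- c("precentral", "sulcus", "postcentral")
HEMISPHERES <- c("left", "right")
CONDITIONS <- c("right_hand", "left_hand")
TISSUES <- c("cortex", "white_matter")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Block-design task protocol
#'
#' Describes an alternating finger-tapping block design: the repetition
#' time (TR), the number of acquired volumes, and an ordered set of
#' non-overlapping task blocks, each tagged with the tapping hand.
#' Volume indices are 0-based and block timing must be commensurate with
#' the TR so that every block maps onto an exact half-open volume window.
#'
#' @param tr_s Repetition time in seconds (one volume every `tr_s`).
#' @param n_volumes Total number of volumes in the run.
#' @param blocks A data.frame with columns `onset_s`, `duration_s` and
#'   `condition` (one of `"right_hand"`, `"left_hand"`), sorted by onset.
#'   May have zero rows.
#' @return An object of class `task_protocol`.
#' @examples
#' p <- tapping_protocol()           # 4 x 30 s right + 4 x 30 s left, TR 3 s
#' p$n_volumes                       # 80
#' @export
task_protocol <- function(tr_s, n_volumes, blocks) {
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop_field("tr_s must be a single positive number")
  if (!is.numeric(n_volumes) || length(n_volumes) != 1L || n_volumes < 1 ||
      n_volumes != round(n_volumes))
    stop_field("n_volumes must be a positive integer")
  n_volumes <- as.integer(n_volumes)
  if (is.null(blocks)) blocks <- data.frame(onset_s = numeric(), duration_s = numeric(),
                                            condition = character())
  blocks <- as.data.frame(blocks)
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(blocks)))
    stop_field("blocks must have columns %s", paste(need, collapse = ", "))
  if (nrow(blocks) > 0) {
    if (!all(blocks$condition %in% CONDITIONS))
      stop_field("block condition must be one of: %s", paste(CONDITIONS, collapse = ", "))
    tol <- 1e-9
    frac <- function(x) abs(x / tr_s - round(x / tr_s))
    if (any(frac(blocks$onset_s) > tol) || any(frac(blocks$duration_s) > tol))
      stop_field("block onsets and durations must be integer multiples of tr_s = %g", tr_s)
    if (any(blocks$duration_s <= 0))
      stop_field("block durations must be positive")
    if (is.unsorted(blocks$onset_s, strictly = TRUE))
      stop_field("blocks must be sorted by onset with no duplicates")
    ends <- blocks$onset_s + blocks$duration_s
    if (nrow(blocks) > 1 && any(blocks$onset_s[-1] < ends[-nrow(blocks)] - tol))
      stop_field("blocks overlap")
    if (max(ends) > n_volumes * tr_s + tol)
      stop_field("blocks extend past the end of the run (%g s > %g s)",
                 max(ends), n_volumes * tr_s)
  }
  structure(list(tr_s = tr_s, n_volumes = n_volumes, blocks = blocks),
            class = "task_protocol")
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf("Task protocol: TR %g s, %d volumes (%g s), %d blocks\n",
              x$tr_s, x$n_volumes, x$tr_s * x$n_volumes, nrow(x$blocks)))
  invisible(x)
}

#' Standard alternating-hand tapping protocol
#'
#' Convenience constructor for the alternating right-/left-hand tapping
#' run used throughout: `blocks_per_condition` pairs of `block_s`-second
#' blocks, right hand first, back to back with no rest periods.
#' The defaults (TR 3 s, 30 s blocks, four per hand) give a 4-minute run
#' of 80 volumes.
#'
#' @param tr_s Repetition time in seconds.
#' @param block_s Duration of one tapping block in seconds.
#' @param blocks_per_condition Number of blocks per hand.
#' @return A [task_protocol()].
#' @export
tapping_protocol <- function(tr_s = 3, block_s = 30, blocks_per_condition = 4) {
  n_blocks <- 2L * blocks_per_condition
  onsets <- block_s * (seq_len(n_blocks) - 1L)
  conds <- rep(c("right_hand", "left_hand"), blocks_per_condition)
  n_volumes <- as.integer(round(n_blocks * block_s / tr_s))
  task_protocol(tr_s, n_volumes,
                data.frame(onset_s = onsets, duration_s = block_s, condition = conds))
}

#' Named set of half-open volume windows
#'
#' A `segment_set` selects the volumes entering an analysis: an ordered
#' sequence of non-overlapping half-open intervals `[start, end)` in
#' 0-based volume indices.  Windows are treated as independent epochs by
#' all lagged statistics: lagged sample pairs never straddle a window
#' boundary.
#'
#' @param label Free-form label, e.g. `"full"`, `"contralateral"`.
#' @param starts,ends Integer vectors of equal length; `0 <= start < end`.
#' @param n_volumes Optional run length to validate against.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(label, starts, ends, n_volumes = NULL) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends))
    stop_field("starts and ends must have equal length")
  if (any(starts < 0) || any(ends <= starts))
    stop_field("windows must satisfy 0 <= start < end")
  if (length(starts) > 1) {
    if (is.unsorted(starts, strictly = TRUE)) stop_field("windows must be sorted")
    if (any(starts[-1] < ends[-length(ends)])) stop_field("windows overlap")
  }
  if (!is.null(n_volumes) && length(ends) && max(ends) > n_volumes)
    stop_field("window end %d exceeds n_volumes = %d", max(ends), as.integer(n_volumes))
  structure(list(label = as.character(label), starts = starts, ends = ends),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set '%s': %d window(s), %d volumes\n",
              x$label, length(x$starts), sum(x$ends - x$starts)))
  invisible(x)
}

n_selected <- function(segments) sum(segments$ends - segments$starts)

#' Whole-run segment set
#'
#' @param protocol A [task_protocol()].
#' @return A single-window [segment_set()] labelled `"full"` covering
#'   every volume.
#' @export
segment_full <- function(protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  segment_set("full", 0L, protocol$n_volumes, protocol$n_volumes)
}

#' Select task blocks by laterality
#'
#' Maps task blocks to the volume windows during which a given
#' hemisphere is (contralateral mode) or is not (ipsilateral mode)
#' driving the tapping hand.  Right-hand tapping engages the left
#' hemisphere, so for the left hemisphere the contralateral blocks are
#' the right-hand ones, and vice versa.
#'
#' @param protocol A [task_protocol()].
#' @param hemisphere `"left"` or `"right"`.
#' @param mode `"contralateral"` or `"ipsilateral"`.
#' @param shift_volumes Integer number of volumes by which every window
#'   is delayed, e.g. to absorb haemodynamic lag. Default 0 (no shift);
#'   shifted windows are clipped to the run.
#' @return A [segment_set()] with one window per matching block.
#' @export
segment_by_condition <- function(protocol, hemisphere, mode, shift_volumes = 0L) {
  stopifnot(inherits(protocol, "task_protocol"))
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  mode <- match.arg(mode, c("contralateral", "ipsilateral"))
  # contralateral pairing: left hemisphere <-> right hand
  hand <- if (xor(hemisphere == "left", mode == "ipsilateral")) "right_hand" else "left_hand"
  b <- protocol$blocks[protocol$blocks$condition == hand, , drop = FALSE]
  starts <- as.integer(round(b$onset_s / protocol$tr_s)) + as.integer(shift_volumes)
  ends <- as.integer(round((b$onset_s + b$duration_s) / protocol$tr_s)) +
    as.integer(shift_volumes)
  keep <- starts < protocol$n_volumes & ends > 0
  starts <- pmax(starts[keep], 0L); ends <- pmin(ends[keep], protocol$n_volumes)
  segment_set(mode, starts, ends, protocol$n_volumes)
}

#' Split a run into halves
#'
#' @param protocol A [task_protocol()] with at least 2 volumes.
#' @return A list of two [segment_set()]s, `first_half` = `[0, floor(T/2))`
#'   and `second_half` = `[floor(T/2), T)`; together they cover every
#'   volume exactly once.
#' @export
split_halves <- function(protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  T <- protocol$n_volumes
  if (T < 2) stop_field("cannot split a run of %d volume(s) into halves", T)
  mid <- T %/% 2L
  list(first_half = segment_set("first_half", 0L, mid, T),
       second_half = segment_set("second_half", mid, T, T))
}

#' Keep only the leading or trailing part of each window
#'
#' Replaces every window of a segment set by its first (or last)
#' `span_s` seconds, e.g. the first 15 s of each 30 s tapping block.
#'
#' @param segments A [segment_set()].
#' @param part `"first"` or `"last"`.
#' @param span_s Length to keep, in seconds; must be a multiple of
#'   `tr_s` and no longer than any window.
#' @param tr_s Repetition time in seconds.
#' @return A [segment_set()] with equally many, shorter windows.
#' @export
window_within_blocks <- function(segments, part, span_s, tr_s) {
  stopifnot(inherits(segments, "segment_set"))
  part <- match.arg(part, c("first", "last"))
  k <- span_s / tr_s
  if (abs(k - round(k)) > 1e-9)
    stop_field("span_s = %g is not a multiple of tr_s = %g", span_s, tr_s)
  k <- as.integer(round(k))
  if (k < 1) stop_field("span_s must cover at least one volume")
  widths <- segments$ends - segments$starts
  bad <- which(widths < k)
  if (length(bad))
    stop_field("span of %d volumes exceeds window %d ([%d, %d))",
               k, bad[1], segments$starts[bad[1]], segments$ends[bad[1]])
  if (part == "first") {
    segment_set(paste0(segments$label, "_", part, span_s, "s"),
                segments$starts, segments$starts + k)
  } else {
    segment_set(paste0(segments$label, "_", part, span_s, "s"),
                segments$ends - k, segments$ends)
  }
}

#' Restrict a segment set to one half of the run
#'
#' Intersects the windows of `segments` with `[0, floor(T/2))` or
#' `[floor(T/2), T)`, dropping windows that fall entirely in the other
#' half.  Used for the "first half vs second half of the contralateral
#' activity" comparison.
#'
#' @param segments A [segment_set()].
#' @param half `"first"` or `"second"`.
#' @param n_volumes Run length `T`.
#' @return A [segment_set()].
#' @export
intersect_half <- function(segments, half, n_volumes) {
  stopifnot(inherits(segments, "segment_set"))
  half <- match.arg(half, c("first", "second"))
  mid <- as.integer(n_volumes) %/% 2L
  lo <- if (half == "first") 0L else mid
  hi <- if (half == "first") mid else as.integer(n_volumes)
  starts <- pmax(segments$starts, lo); ends <- pmin(segments$ends, hi)
  keep <- starts < ends
  segment_set(paste0(segments$label, "_", half, "_half"), starts[keep], ends[keep])
}
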