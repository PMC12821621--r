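#' Write a subject recording to a directory
#'
#' On-disk layout: `protocol.json` (tr_s, n_volumes, blocks as
#' `[onset_s, duration_s, condition]` triples), six tab-separated files
#' `<hemisphere>_<region>.tsv` (header row = voxel ids, one row per
#' volume), companion `<hemisphere>_<region>.tissue.tsv` files
#' (voxel id, label), and `provenance.json` when generator metadata is
#' attached.
#'
#' @param subject A [subject_recording()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  stopifnot(inherits(subject, "subject_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- subject$protocol
  blocks <- lapply(seq_len(nrow(p$blocks)), function(i)
    list(p$blocks$onset_s[i], p$blocks$duration_s[i], p$blocks$condition[i]))
  jsonlite::write_json(
    list(subject_id = subject$subject_id, tr_s = p$tr_s,
         n_volumes = p$n_volumes, blocks = blocks),
    file.path(path, "protocol.json"), auto_unbox = TRUE, digits = NA)
  for (key in names(subject$regions)) {
    r <- subject$regions[[key]]
    d <- as.data.frame(r$data)
    names(d) <- paste0("v", seq_len(ncol(d)))
    utils::write.table(d, file.path(path, paste0(key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(voxel = names(d), tissue = r$tissue),
      file.path(path, paste0(key, ".tissue.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(subject$provenance))
    jsonlite::write_json(subject$provenance, file.path(path, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subject recording from a directory
#'
#' Inverse of [write_subject()]; validates every invariant (protocol
#' well-formedness, matching volume counts, finite values, tissue
#' length) and names the offending file on failure.
#'
#' @param path Directory written by [write_subject()].
#' @return A [subject_recording()].
#' @export
read_subject <- function(path) {
  pj <- file.path(path, "protocol.json")
  if (!file.exists(pj)) stop_field("%s: protocol.json not found", path)
  meta <- jsonlite::read_json(pj, simplifyVector = FALSE)
  blocks <- data.frame(
    onset_s = vapply(meta$blocks, function(b) as.numeric(b[[1]]), 0),
    duration_s = vapply(meta$blocks, function(b) as.numeric(b[[2]]), 0),
    condition = vapply(meta$blocks, function(b) as.character(b[[3]]), ""))
  protocol <- tryCatch(task_protocol(meta$tr_s, meta$n_volumes, blocks),
                       error = function(e) stop_field("%s: %s", pj, conditionMessage(e)))
  regions <- lapply(region_keys(), function(key) {
    f <- file.path(path, paste0(key, ".tsv"))
    tf <- file.path(path, paste0(key, ".tissue.tsv"))
    if (!file.exists(f)) stop_field("%s: missing region file %s.tsv", path, key)
    d <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    tissue <- if (file.exists(tf)) {
      t <- utils::read.table(tf, header = TRUE, sep = "\t")
      if (nrow(t) != ncol(d))
        stop_field("%s: tissue file lists %d voxels but %s.tsv has %d",
                   tf, nrow(t), key, ncol(d))
      t$tissue
    } else NULL
    hemi <- sub("_.*$", "", key); region <- sub("^[^_]*_", "", key)
    if (nrow(d) != protocol$n_volumes)
      stop_field("%s: %s.tsv has %d volumes but protocol says %d",
                 path, key, nrow(d), protocol$n_volumes)
    tryCatch(region_recording(region, hemi, as.matrix(d), tissue),
             error = function(e) stop_field("%s: %s", f, conditionMessage(e)))
  })
  prov <- NULL
  pv <- file.path(path, "provenance.json")
  if (file.exists(pv)) prov <- jsonlite::read_json(pv, simplifyVector = TRUE)
  subject_recording(meta$subject_id %||% basename(path), protocol, regions, prov)
}

#' Write a cohort of subjects
#'
#' Writes each subject under `<path>/<subject_id>/` in the
#' [write_subject()] layout.
#'
#' @param cohort List of [subject_recording()]s.
#' @param path Cohort directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) write_subject(s, file.path(path, s$subject_id))
  invisible(path)
}

#' Read a cohort directory
#'
#' @param path Directory whose subdirectories each hold one subject in
#'   the [write_subject()] layout.
#' @return A list of [subject_recording()]s, sorted by subject id.
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "protocol.json"))]
  if (!length(dirs)) stop_field("%s: no subject directories with protocol.json", path)
  lapply(sort(dirs), read_subject)
}
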