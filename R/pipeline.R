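#' Analysis configuration
#'
#' Bundles every switch of the end-to-end analysis: which metrics to
#' run, which part of the run to analyse, whether to exclude
#' white-matter voxels, half-splits and within-block windows, lag,
#' permutations, standardization, the shuffled-source negative control
#' and the seed.
#'
#' @param metrics Subset of `c("iig", "mi", "gc")`.
#' @param condition `"full"`, `"contralateral"` or `"ipsilateral"` (per
#'   analysed hemisphere).
#' @param exclude_white_matter Keep only cortex voxels (default FALSE).
#' @param halves `"none"`, `"whole_series"` (first vs second half of
#'   the run) or `"contralateral_only"` (halves of the selected blocks).
#' @param window `"none"`, `"first15"` or `"last15"` — keep only the
#'   first/last 15 s of each selected block window.
#' @param lag_volumes Prediction lag (>= 1).
#' @param n_permutations Permutations for IIG and MI nulls.
#' @param standardize Z-score voxel series over the analysed segment.
#' @param shuffle_control Shuffle the source region's volumes (within
#'   epochs) before testing — a negative control that destroys all
#'   directed coupling.
#' @param seed Master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(metrics = "iig",
                            condition = c("full", "contralateral", "ipsilateral"),
                            exclude_white_matter = FALSE,
                            halves = c("none", "whole_series", "contralateral_only"),
                            window = c("none", "first15", "last15"),
                            lag_volumes = 1L, n_permutations = 100L,
                            standardize = TRUE, shuffle_control = FALSE,
                            seed = 1L) {
  metrics <- match.arg(metrics, c("iig", "mi", "gc"), several.ok = TRUE)
  condition <- match.arg(condition)
  halves <- match.arg(halves)
  window <- match.arg(window)
  if (lag_volumes < 1) stop_field("lag_volumes must be >= 1")
  if (n_permutations < 2 && any(c("iig", "mi") %in% metrics))
    stop_field("n_permutations must be >= 2 for permutation-based metrics")
  structure(list(metrics = metrics, condition = condition,
                 exclude_white_matter = exclude_white_matter, halves = halves,
                 window = window, lag_volumes = as.integer(lag_volumes),
                 n_permutations = as.integer(n_permutations),
                 standardize = standardize, shuffle_control = shuffle_control,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Segment sets to analyse for one (subject, hemisphere) unit under a
# config: a named list with one entry per half-analysis (or a single
# entry when halves == "none").
unit_segments <- function(protocol, hemisphere, config) {
  base <- switch(config$condition,
    full = segment_full(protocol),
    contralateral = segment_by_condition(protocol, hemisphere, "contralateral"),
    ipsilateral = segment_by_condition(protocol, hemisphere, "ipsilateral"))
  if (config$window != "none") {
    part <- if (config$window == "first15") "first" else "last"
    base <- window_within_blocks(base, part, 15, protocol$tr_s)
  }
  switch(config$halves,
    none = list(all = base),
    whole_series = {
      h <- split_halves(protocol)
      list(half1 = h$first_half, half2 = h$second_half)
    },
    contralateral_only = list(
      half1 = intersect_half(base, "first", protocol$n_volumes),
      half2 = intersect_half(base, "second", protocol$n_volumes)))
}

shuffle_source <- function(x, seed) {
  epoch <- attr(x, "epoch") %||% rep.int(1L, nrow(x))
  set.seed(seed)
  p <- permute_within_groups(epoch)
  out <- x[p, , drop = FALSE]
  attr(out, "epoch") <- epoch
  out
}

region_pairs <- function() {
  do.call(rbind, lapply(REGIONS, function(f)
    data.frame(from = f, to = setdiff(REGIONS, f))))
}

#' Run the full directed-connectivity analysis on a cohort
#'
#' For every (subject, hemisphere) analysis unit and every ordered
#' region pair, builds the analysed volume windows from the config,
#' runs the selected metrics (IIG on voxel matrices; MI and Granger on
#' region-mean series) and aggregates across units — Stouffer's Z for
#' IIG, Fisher's method reported as log10 aggregated p for MI and GC.
#' All randomness derives deterministically from `config$seed`.
#'
#' @param cohort A list of [subject_recording()]s or a cohort directory
#'   path (read with [read_cohort()]).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory: tables are written as
#'   `table_<metric>_<condition>[_cortexonly][_half{1,2}].tsv` with
#'   JSON sidecars and a `manifest.json` of the config.
#' @return A named list of [build_table()] results, one per
#'   metric x half-analysis.
#' @export
run_analysis <- function(cohort, config = analysis_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(config, "analysis_config"))
  pairs <- region_pairs()
  halves_keys <- names(unit_segments(cohort[[1]]$protocol, "left", config))
  results <- list()  # results[[metric]][[half]] = list of causality_result
  for (m in config$metrics) for (h in halves_keys) results[[m]][[h]] <- list()

  unit_i <- 0L
  for (s in cohort) {
    for (hemi in HEMISPHERES) {
      unit_i <- unit_i + 1L
      segs <- unit_segments(s$protocol, hemi, config)
      recs <- lapply(REGIONS, function(r) {
        rec <- get_region(s, hemi, r)
        if (config$exclude_white_matter) rec <- restrict_to_cortex(rec)
        rec
      })
      names(recs) <- REGIONS
      for (h in names(segs)) {
        seg <- segs[[h]]
        extracted <- lapply(recs, function(r) extract_segments(r, seg))
        for (q in seq_len(nrow(pairs))) {
          from <- pairs$from[q]; to <- pairs$to[q]
          test_seed <- config$seed + unit_i * 6011L + q * 97L +
            match(h, names(segs)) * 13L
          x <- extracted[[from]]
          if (config$shuffle_control) x <- shuffle_source(x, test_seed + 7L)
          y <- extracted[[to]]
          for (m in config$metrics) {
            res <- switch(m,
              iig = iig_causality(x, y, segments = NULL,
                                  lag_volumes = config$lag_volumes,
                                  n_permutations = config$n_permutations,
                                  seed = test_seed,
                                  standardize = config$standardize,
                                  condition = seg$label),
              mi = {
                mp <- mi_permutation_p(region_mean(x), region_mean(y),
                                       lag = config$lag_volumes,
                                       n_permutations = config$n_permutations,
                                       seed = test_seed)
                causality_result(from, to, "mi", seg$label,
                                 statistic = mp$observed$value, p = mp$p_value,
                                 n_permutations = config$n_permutations,
                                 lag_volumes = config$lag_volumes, seed = test_seed)
              },
              gc = {
                g <- granger_f_test(region_mean(x), region_mean(y),
                                    order = config$lag_volumes)
                causality_result(from, to, "gc", seg$label,
                                 statistic = g$f_statistic, p = g$p_value,
                                 lag_volumes = config$lag_volumes, seed = test_seed)
              })
            res$from_region <- from; res$to_region <- to
            results[[m]][[h]][[length(results[[m]][[h]]) + 1L]] <- res
          }
        }
      }
    }
  }

  tables <- list()
  for (m in config$metrics) {
    method <- if (m == "iig") "stouffer" else "fisher"
    for (h in halves_keys) {
      name <- paste0("table_", m, "_", config$condition,
                     if (config$exclude_white_matter) "_cortexonly" else "",
                     if (h == "all") "" else paste0("_", h))
      tables[[name]] <- build_table(results[[m]][[h]], method)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (name in names(tables))
      write_table_tsv(tables[[name]], file.path(out_dir, paste0(name, ".tsv")))
    jsonlite::write_json(c(unclass(config), list(n_subjects = length(cohort))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tables
}

#' Cell-wise difference between two directed tables
#'
#' Tabulates how each directed connection changed between two analysis
#' conditions or halves (second minus first), with no inferential claim
#' attached.
#'
#' @param table_a,table_b Two [build_table()] results sharing metric
#'   and method.
#' @return A list with the two input tables and `difference`, a 3x3
#'   matrix `table_b - table_a`.
#' @export
compare_conditions <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "directed_table"), inherits(table_b, "directed_table"))
  if (table_a$metric != table_b$metric || table_a$method != table_b$method)
    stop_field("tables mix metrics (%s vs %s)", table_a$metric, table_b$metric)
  structure(list(from = table_a, to = table_b,
                 difference = table_b$values - table_a$values),
            class = "table_comparison")
}

#' @export
print.table_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison [%s]: '%s' -> '%s'\n", toupper(x$from$metric),
              x$from$condition, x$to$condition))
  print(round(x$difference, 2))
  invisible(x)
}
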