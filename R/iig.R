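# Lagged (present, future) instance pairs that never straddle an epoch
# boundary.  `epoch` is the per-row window id produced by
# extract_segments(); NULL means one contiguous epoch.
lagged_instances <- function(n_rows, lag, epoch = NULL) {
  if (is.null(epoch)) epoch <- rep.int(1L, n_rows)
  if (length(epoch) != n_rows) stop_field("epoch attribute length mismatch")
  past <- which(seq_len(n_rows) + lag <= n_rows)
  past <- past[epoch[past] == epoch[past + lag]]
  list(past = past, future = past + lag, group = epoch[past])
}

# Shared machinery for the observed statistic and its permutation null:
# everything that does not depend on the permutation is computed once.
iig_prepare <- function(x_states, y_states, lag_volumes, k, weight) {
  x_states <- as.matrix(x_states); y_states <- as.matrix(y_states)
  if (nrow(x_states) != nrow(y_states))
    stop_field("source and target share %d vs %d volumes", nrow(x_states), nrow(y_states))
  lag_volumes <- as.integer(lag_volumes)
  if (lag_volumes < 1) stop_field("lag_volumes must be >= 1")
  inst <- lagged_instances(nrow(y_states), lag_volumes,
                           attr(y_states, "epoch") %||% attr(x_states, "epoch"))
  if (length(inst$past) < 3)
    stop_field("only %d usable (past, future) instance pairs; need >= 3 (%d rows, lag %d)",
               length(inst$past), nrow(y_states), lag_volumes)
  dYp <- pairwise_distance(y_states[inst$past, , drop = FALSE])
  dYf <- pairwise_distance(y_states[inst$future, , drop = FALSE])
  dXp <- pairwise_distance(x_states[inst$past, , drop = FALSE])
  list(inst = inst, dYp2 = dYp^2, dXp2 = weight^2 * dXp^2, dYf = dYf,
       delta_self = information_imbalance(dYp, dYf, k)$delta, k = k,
       n_instances = length(inst$past))
}

iig_gain <- function(prep, perm = NULL) {
  dXp2 <- if (is.null(perm)) prep$dXp2 else prep$dXp2[perm, perm]
  dC <- sqrt(dXp2 + prep$dYp2)
  prep$delta_self - information_imbalance(dC, prep$dYf, prep$k)$delta
}

permute_within_groups <- function(group) {
  p <- seq_along(group)
  for (g in unique(group)) {
    i <- which(group == g)
    if (length(i) > 1) p[i] <- i[sample.int(length(i))]
  }
  p
}

#' Information Imbalance Gain statistic
#'
#' Tests whether the present state of a source region X helps predict
#' the future state of a target region Y.  Instances are the
#' (present, future) volume pairs `t -> t + lag` built within epochs
#' only.  The statistic is the gain
#' \deqn{G = \Delta(d_{Y_{past}} \to d_{Y_{fut}}) -
#'           \Delta(d_{(X_{past}, Y_{past})} \to d_{Y_{fut}})}
#' where the combined distance is the Euclidean distance on the
#' concatenated voxel states, `sqrt(dX^2 + dY^2)`.  `G > 0` indicates
#' that adding X's present shrinks the imbalance, i.e. X carries
#' predictive information about Y's future beyond Y's own past.
#'
#' @param x_states,y_states Numeric matrices (volumes x voxels) over the
#'   same volumes, optionally carrying the `epoch` attribute from
#'   [extract_segments()].
#' @param lag_volumes Prediction lag in volumes (default 1).
#' @param k Nearest neighbours averaged in the imbalance (default 1).
#' @param weight Relative weight of X in the combined distance
#'   (default 1, the plain concatenation formula).
#' @return The gain `G`, a single number.
#' @export
iig_statistic <- function(x_states, y_states, lag_volumes = 1L, k = 1L, weight = 1) {
  prep <- iig_prepare(x_states, y_states, lag_volumes, k, weight)
  iig_gain(prep)
}

#' Permutation null distribution of the IIG statistic
#'
#' Recomputes the gain with the source's instance rows permuted by
#' seeded random permutations of the time indices (whole voxel patterns
#' move together; permutation restricted within epochs), which removes
#' any temporal coupling from X to Y while preserving both marginals.
#'
#' @inheritParams iig_statistic
#' @param n_permutations Number of permutations (default 100).
#' @param seed Integer seed for reproducibility.
#' @return A list of class `null_distribution` with `samples`, `mean`,
#'   `sd`, `n_permutations`, `seed`.
#' @export
iig_permutation_null <- function(x_states, y_states, lag_volumes = 1L,
                                 n_permutations = 100L, seed = 1L,
                                 k = 1L, weight = 1) {
  if (n_permutations < 2) stop_field("n_permutations must be >= 2")
  prep <- iig_prepare(x_states, y_states, lag_volumes, k, weight)
  set.seed(seed)
  samples <- vapply(seq_len(n_permutations), function(b)
    iig_gain(prep, permute_within_groups(prep$inst$group)), 0)
  null_distribution(samples, seed)
}

null_distribution <- function(samples, seed = NA_integer_) {
  structure(list(samples = samples, mean = mean(samples), sd = stats::sd(samples),
                 n_permutations = length(samples), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null: %d samples, mean %.4g, sd %.4g\n",
              x$n_permutations, x$mean, x$sd))
  invisible(x)
}

#' Z-score of an observed statistic against a permutation null
#'
#' @param observed Observed statistic.
#' @param null A `null_distribution` with positive standard deviation.
#' @return `(observed - null$mean) / null$sd`.
#' @export
z_score <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(null$sd) || null$sd <= 0)
    stop_field("degenerate permutation null (sd = %g)", null$sd)
  (observed - null$mean) / null$sd
}

#' Full IIG causality test between two regions
#'
#' Extracts the analysed volumes, optionally standardizes each voxel
#' over them, computes the observed Information Imbalance Gain, its
#' permutation null, and the Z-score.
#'
#' @param from,to [region_recording()]s or volumes x voxels matrices
#'   (source and target).
#' @param segments A [segment_set()] choosing the analysed volumes;
#'   `NULL` means all volumes as one epoch.
#' @param lag_volumes Prediction lag in volumes.
#' @param n_permutations Permutations for the null (default 100).
#' @param seed Integer seed.
#' @param standardize Z-score each voxel over the analysed segment
#'   before computing distances (default TRUE).
#' @param k,weight Passed to [iig_statistic()].
#' @param condition Label stored in the result (defaults to the segment
#'   label).
#' @return A `causality_result` with `statistic` (the gain),
#'   `z_score`, `null`, and metadata.
#' @export
iig_causality <- function(from, to, segments = NULL, lag_volumes = 1L,
                          n_permutations = 100L, seed = 1L,
                          standardize = TRUE, k = 1L, weight = 1,
                          condition = NULL) {
  from_id <- if (inherits(from, "region_recording")) from$region_id else "from"
  to_id <- if (inherits(to, "region_recording")) to$region_id else "to"
  x <- if (inherits(from, "region_recording")) from$data else as.matrix(from)
  y <- if (inherits(to, "region_recording")) to$data else as.matrix(to)
  if (!is.null(segments)) {
    x <- extract_segments(x, segments)
    y <- extract_segments(y, segments)
    condition <- condition %||% segments$label
  }
  condition <- condition %||% "full"
  if (standardize) {
    x <- standardize_voxels(x)
    y <- standardize_voxels(y)
  }
  prep <- iig_prepare(x, y, lag_volumes, k, weight)
  observed <- iig_gain(prep)
  set.seed(seed)
  samples <- vapply(seq_len(n_permutations), function(b)
    iig_gain(prep, permute_within_groups(prep$inst$group)), 0)
  null <- null_distribution(samples, seed)
  causality_result(from_id, to_id, metric = "iig", condition = condition,
                   statistic = observed, z = z_score(observed, null),
                   n_permutations = n_permutations, lag_volumes = lag_volumes,
                   seed = seed, n_instances = prep$n_instances, null = null)
}

#' One directed causality test result
#'
#' @param from_region,to_region Region identifiers.
#' @param metric `"iig"`, `"mi"` or `"gc"`.
#' @param condition Analysis-condition label.
#' @param statistic Observed test statistic.
#' @param z Z-score (IIG) or `NA`.
#' @param p P-value (MI/GC) or `NA`.
#' @param n_permutations,lag_volumes,seed,n_instances Metadata.
#' @param null Optional `null_distribution`.
#' @return An object of class `causality_result`.
#' @export
causality_result <- function(from_region, to_region, metric, condition,
                             statistic, z = NA_real_, p = NA_real_,
                             n_permutations = 0L, lag_volumes = 1L,
                             seed = NA_integer_, n_instances = NA_integer_,
                             null = NULL) {
  metric <- match.arg(metric, c("iig", "mi", "gc"))
  if (is.na(z) == is.na(p))
    stop_field("exactly one of z / p must be present (metric %s)", metric)
  if (!is.na(p) && (p < 0 || p > 1)) stop_field("p-value %g outside [0, 1]", p)
  structure(list(from_region = from_region, to_region = to_region,
                 metric = metric, condition = condition, statistic = statistic,
                 z_score = z, p_value = p, n_permutations = n_permutations,
                 lag_volumes = lag_volumes, seed = seed,
                 n_instances = n_instances, null = null),
            class = "causality_result")
}

#' @export
print.causality_result <- function(x, ...) {
  val <- if (!is.na(x$z_score)) sprintf("Z = %.3f", x$z_score)
         else sprintf("p = %.4g", x$p_value)
  cat(sprintf("%s: %s -> %s [%s]: statistic %.4g, %s\n",
              toupper(x$metric), x$from_region, x$to_region, x$condition,
              x$statistic, val))
  invisible(x)
}
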