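# Lagged (x_past, y_present) sample pairs for the univariate baselines,
# respecting epoch boundaries like the voxel-level statistics do.
lagged_pairs <- function(x, y, lag) {
  if (length(x) != length(y))
    stop_field("series lengths differ (%d vs %d)", length(x), length(y))
  inst <- lagged_instances(length(y), lag, attr(y, "epoch") %||% attr(x, "epoch"))
  list(x = as.numeric(x)[inst$past], y = as.numeric(y)[inst$future],
       group = inst$group)
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(NULL)
  (v - mean(v)) / s
}

# Box-kernel (uniform, half-width h) density estimates evaluated at the
# sample points; marginals in 1-D, joint with the product kernel in
# 2-D.  Densities are leave-one-out (the evaluation point is excluded
# from its own kernel sums), removing the self-sampling bias of the
# naive plug-in.  Points whose leave-one-out joint count is zero carry
# no usable density and are dropped from the average.
box_kernel_mi <- function(xs, ys, h) {
  n <- length(xs)
  in_x <- abs(outer(xs, xs, "-")) <= h
  in_y <- abs(outer(ys, ys, "-")) <= h
  cx <- rowSums(in_x) - 1
  cy <- rowSums(in_y) - 1
  cxy <- rowSums(in_x & in_y) - 1
  ok <- cxy > 0
  if (!any(ok)) return(0)  # no reusable joint mass anywhere
  fx <- cx[ok] / ((n - 1) * 2 * h)
  fy <- cy[ok] / ((n - 1) * 2 * h)
  fxy <- cxy[ok] / ((n - 1) * 4 * h^2)
  mean(log(fxy / (fx * fy)))
}

#' Time-lagged mutual information, box-kernel plug-in estimate
#'
#' Estimates `I(y(t); x(t - lag))` in nats: how much knowing the
#' source's past reduces uncertainty about the target's present.  Both
#' series are z-scored, the joint and marginal densities are estimated
#' with a uniform ("box") kernel of half-width `bandwidth`, and the
#' mutual-information sum is evaluated at the sample points.  The
#' plug-in value can be slightly negative for independent data; it is
#' clipped at 0 and the raw value retained.
#'
#' @param x,y Univariate numeric series of equal length (source,
#'   target), optionally carrying an `epoch` attribute; lagged pairs
#'   never straddle epochs.
#' @param lag Lag in volumes (default 1).
#' @param bandwidth Kernel half-width on the z-scored scale
#'   (default 0.2).
#' @return A list of class `mi_estimate` with `value` (nats, >= 0),
#'   `raw`, `lag_volumes`, `bandwidth`, `n_samples`, `degenerate`.
#' @export
lagged_mi <- function(x, y, lag = 1L, bandwidth = 0.2) {
  if (bandwidth <= 0) stop_field("bandwidth must be positive")
  pr <- lagged_pairs(x, y, lag)
  if (length(pr$x) < 3) stop_field("too few lagged samples (%d)", length(pr$x))
  xs <- zscore(pr$x); ys <- zscore(pr$y)
  if (is.null(xs) || is.null(ys)) {
    return(structure(list(value = 0, raw = 0, lag_volumes = as.integer(lag),
                          bandwidth = bandwidth, n_samples = length(pr$x),
                          degenerate = TRUE), class = "mi_estimate"))
  }
  raw <- box_kernel_mi(xs, ys, bandwidth)
  structure(list(value = max(raw, 0), raw = raw, lag_volumes = as.integer(lag),
                 bandwidth = bandwidth, n_samples = length(pr$x),
                 degenerate = FALSE), class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("Lagged MI: %.4f nats (lag %d, h = %g, n = %d)%s\n", x$value,
              x$lag_volumes, x$bandwidth, x$n_samples,
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' Permutation p-value for lagged mutual information
#'
#' The source series is randomly permuted (within epochs) to destroy
#' all temporal information, the MI re-estimated for each permutation,
#' and a one-sided add-one p-value returned:
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @inheritParams lagged_mi
#' @param n_permutations At least 19 (so p can resolve alpha = 0.05).
#' @param seed Integer seed.
#' @return A list with `p_value`, `observed` (an `mi_estimate`) and
#'   `null` (a `null_distribution` of raw MI values).
#' @export
mi_permutation_p <- function(x, y, lag = 1L, bandwidth = 0.2,
                             n_permutations = 100L, seed = 1L) {
  if (n_permutations < 19)
    stop_field("n_permutations = %d is too coarse; need >= 19", n_permutations)
  observed <- lagged_mi(x, y, lag, bandwidth)
  pr <- lagged_pairs(x, y, lag)
  xs <- zscore(pr$x); ys <- zscore(pr$y)
  if (observed$degenerate || is.null(xs) || is.null(ys)) {
    return(list(p_value = 1, observed = observed, null = NULL))
  }
  set.seed(seed)
  samples <- vapply(seq_len(n_permutations), function(b)
    box_kernel_mi(xs[permute_within_groups(pr$group)], ys, observed$bandwidth), 0)
  p <- (1 + sum(samples >= observed$raw)) / (1 + n_permutations)
  list(p_value = p, observed = observed, null = null_distribution(samples, seed))
}

# Lagged design matrix y(t) ~ own lags (+ x lags), built within epochs.
gc_design <- function(x, y, order) {
  n <- length(y)
  epoch <- attr(y, "epoch") %||% attr(x, "epoch") %||% rep.int(1L, n)
  t_ok <- which(seq_len(n) > order)
  t_ok <- t_ok[vapply(t_ok, function(t) all(epoch[(t - order):t] == epoch[t]), TRUE)]
  if (length(t_ok) < 2 * order + 3)
    stop_field("series too short for order-%d model (%d usable samples)",
               order, length(t_ok))
  ylags <- sapply(seq_len(order), function(l) y[t_ok - l])
  xlags <- sapply(seq_len(order), function(l) x[t_ok - l])
  list(target = y[t_ok], ylags = cbind(ylags), xlags = cbind(xlags),
       n_used = length(t_ok))
}

rss_of <- function(target, design, label) {
  fit <- stats::lm.fit(design, target)
  if (fit$rank < ncol(design))
    stop_field("rank-deficient design (%s): a regressor is constant or collinear",
               label)
  sum(fit$residuals^2)
}

#' Bivariate Granger causality F-test
#'
#' Fits two autoregressive models of the target series by ordinary
#' least squares — restricted (own lags only) and unrestricted (own
#' plus source lags) — and tests whether including the source's past
#' reduces the residual sum of squares:
#' \deqn{F = \frac{(RSS_r - RSS_u)/p}{RSS_u/(n - 2p - 1)}}
#' with `p = order` lags and an intercept in both models.
#'
#' @param x,y Univariate numeric series (source, target), optionally
#'   with an `epoch` attribute.
#' @param order Autoregressive model order (default 1).
#' @return A list of class `gc_result` with `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `model_order`, `n_used`.
#' @export
granger_f_test <- function(x, y, order = 1L) {
  order <- as.integer(order)
  if (order < 1) stop_field("order must be >= 1")
  if (length(x) != length(y))
    stop_field("series lengths differ (%d vs %d)", length(x), length(y))
  d <- gc_design(as.numeric(x), as.numeric(y), order)
  intercept <- rep(1, d$n_used)
  rss_r <- rss_of(d$target, cbind(intercept, d$ylags), "restricted: target lags")
  rss_u <- rss_of(d$target, cbind(intercept, d$ylags, d$xlags),
                  "unrestricted: source lags")
  df_num <- order
  df_den <- d$n_used - 2L * order - 1L
  if (df_den < 1) stop_field("not enough samples for the F-test (df_den = %d)", df_den)
  f <- ((rss_r - rss_u) / df_num) / (rss_u / df_den)
  f <- max(f, 0)
  structure(list(f_statistic = f, df_num = df_num, df_den = df_den,
                 p_value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
                 model_order = order, n_used = d$n_used),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Granger causality: F(%d, %d) = %.4f, p = %.4g (order %d)\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value, x$model_order))
  invisible(x)
}
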