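#' Stouffer's combined Z-score
#'
#' Combines k per-analysis Z-scores into one:
#' \deqn{\tilde{Z} = \sum_i Z_i / \sqrt{k}.}
#' Under the null of independent standard-normal inputs the combined
#' value is again standard normal.
#'
#' @param z_values Numeric vector of finite Z-scores, length >= 1.
#' @return The combined Z-score.
#' @export
stouffer <- function(z_values) {
  if (length(z_values) < 1) stop_field("stouffer needs at least one Z-score")
  if (!all(is.finite(z_values))) stop_field("non-finite Z-score in input")
  sum(z_values) / sqrt(length(z_values))
}

#' Fisher's combined p-value
#'
#' Combines k p-values as `X^2 = -2 * sum(log(p_i))`, chi-squared with
#' `2k` degrees of freedom under independence; the aggregated p-value
#' is the upper-tail probability.
#'
#' @param p_values Numeric vector with values in (0, 1], length >= 1.
#' @return A list with `statistic`, `dof` and `p_value`.
#' @export
fisher <- function(p_values) {
  if (length(p_values) < 1) stop_field("fisher needs at least one p-value")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop_field("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  dof <- 2L * length(p_values)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE))
}

#' Base-10 log of a p-value
#'
#' Reporting convention for aggregated p-values: a value below -2
#' (resp. -3) marks significance at alpha = 0.01 (resp. 0.001).  Values
#' below -16 are floored, with a flag.
#'
#' @param p A p-value in (0, 1].
#' @return `log10(p)`, floored at -16; the `floored` attribute records
#'   whether the floor was applied.
#' @export
log10_p <- function(p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop_field("p must lie in (0, 1]")
  v <- log10(p)
  out <- max(v, -16)
  attr(out, "floored") <- v < -16
  out
}

#' Assemble a directed region-by-region table
#'
#' Aggregates per-(subject, hemisphere) causality results into one 3x3
#' directed matrix over \{precentral, sulcus, postcentral\}: Stouffer's
#' combined Z for Z-scored results, Fisher's method (reported as log10
#' aggregated p) for p-valued results.  Every ordered pair must be
#' covered by the same number of units and a single metric.
#'
#' @param results A list of [causality_result()]s, k per ordered pair.
#' @param method `"stouffer"` or `"fisher"`.
#' @return An object of class `directed_table`: a 3x3 `values` matrix
#'   (NA diagonal) plus `metric`, `condition`, `k`, `method`.
#' @export
build_table <- function(results, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  if (!length(results)) stop_field("no results to aggregate")
  metrics <- unique(vapply(results, function(r) r$metric, ""))
  if (length(metrics) != 1)
    stop_field("mixed metrics in one table: %s", paste(metrics, collapse = ", "))
  if (method == "stouffer" && any(vapply(results, function(r) is.na(r$z_score), TRUE)))
    stop_field("stouffer aggregation needs Z-scored results (metric %s)", metrics)
  if (method == "fisher" && any(vapply(results, function(r) is.na(r$p_value), TRUE)))
    stop_field("fisher aggregation needs p-valued results (metric %s)", metrics)
  condition <- unique(vapply(results, function(r) r$condition, ""))[1]
  vals <- matrix(NA_real_, 3, 3, dimnames = list(from = REGIONS, to = REGIONS))
  ks <- integer(0)
  for (from in REGIONS) for (to in setdiff(REGIONS, from)) {
    sel <- Filter(function(r) r$from_region == from && r$to_region == to, results)
    if (!length(sel)) stop_field("no results for pair %s -> %s", from, to)
    ks <- c(ks, length(sel))
    vals[from, to] <- if (method == "stouffer") {
      stouffer(vapply(sel, function(r) r$z_score, 0))
    } else {
      as.numeric(log10_p(fisher(vapply(sel, function(r) r$p_value, 0))$p_value))
    }
  }
  if (length(unique(ks)) != 1)
    stop_field("unbalanced units across pairs (k ranges %d..%d)", min(ks), max(ks))
  structure(list(values = vals, metric = metrics, condition = condition,
                 k = ks[1], method = method),
            class = "directed_table")
}

#' @export
print.directed_table <- function(x, ...) {
  cat(sprintf("Directed table [%s, %s, %s over k = %d units]\n",
              toupper(x$metric), x$condition,
              if (x$method == "stouffer") "aggregated Z" else "log10 aggregated p",
              x$k))
  print(round(x$values, 2))
  invisible(x)
}

#' Write a directed table as TSV plus JSON sidecar
#'
#' @param table A [build_table()] result.
#' @param path Output TSV path; a `.json` sidecar with metric,
#'   condition, method and k is written alongside.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  stopifnot(inherits(table, "directed_table"))
  d <- as.data.frame(table$values)
  d <- cbind(from = rownames(table$values), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metric = table$metric, condition = table$condition,
         method = table$method, k = table$k),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
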