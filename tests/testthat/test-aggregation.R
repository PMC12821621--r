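test_that("Stouffer combination matches its definition", {
  expect_equal(stouffer(1.7), 1.7)
  expect_equal(stouffer(c(0, 0, 0)), 0)
  expect_equal(stouffer(c(1, 2, 3)), 6 / sqrt(3))
  z <- c(-0.4, 1.1, 2.3)
  expect_equal(stouffer(3 * z), 3 * stouffer(z))  # linearity
  expect_error(stouffer(numeric(0)), "at least one")
  expect_error(stouffer(c(1, NA)), "finite")
})

test_that("Fisher combination matches the chi-squared survival oracle", {
  f1 <- fisher(0.037)
  expect_equal(f1$p_value, 0.037, tolerance = 1e-12)  # k = 1 identity
  f2 <- fisher(c(1, 1, 1))
  expect_equal(f2$statistic, 0)
  expect_equal(f2$p_value, 1)
  f3 <- fisher(c(0.05, 0.05))
  expect_equal(f3$statistic, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(f3$statistic, 11.98293, tolerance = 1e-5)
  expect_equal(f3$dof, 4L)
  # survival oracle via numerical integration of the chi-squared density
  surv <- integrate(function(u) dchisq(u, 4), f3$statistic, Inf)$value
  expect_equal(f3$p_value, surv, tolerance = 1e-6)
  expect_error(fisher(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher(1.2), "\\(0, 1\\]")
})

test_that("Fisher's aggregate p is monotone in each input", {
  base <- c(0.2, 0.5, 0.8)
  p0 <- fisher(base)$p_value
  for (i in 1:3) {
    up <- base; up[i] <- up[i] + 0.1
    expect_gte(fisher(up)$p_value, p0)
  }
})

test_that("log10 reporting follows the significance conventions", {
  expect_equal(as.numeric(log10_p(1)), 0)
  expect_equal(as.numeric(log10_p(0.01)), -2)
  expect_equal(as.numeric(log10_p(0.001)), -3)
  floored <- log10_p(1e-20)
  expect_equal(as.numeric(floored), -16)
  expect_true(attr(floored, "floored"))
  expect_error(log10_p(0), "\\(0, 1\\]")
})

test_that("directed tables aggregate per ordered pair", {
  mk <- function(from, to, z, unit) {
    causality_result(from, to, "iig", "full", statistic = z / 10, z = z,
                     seed = unit)
  }
  pairs <- expand.grid(from = c("precentral", "sulcus", "postcentral"),
                       to = c("precentral", "sulcus", "postcentral"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  results <- list()
  set.seed(1)
  zmat <- matrix(rnorm(6 * 18), 6, 18)
  for (u in 1:18) for (q in 1:6)
    results[[length(results) + 1]] <- mk(pairs$from[q], pairs$to[q], zmat[q, u], u)
  tab <- build_table(results, "stouffer")
  expect_equal(tab$k, 18L)
  expect_true(all(is.na(diag(tab$values))))
  expect_equal(tab$values["precentral", "sulcus"],
               stouffer(zmat[pairs$from == "precentral" & pairs$to == "sulcus", ]))
  # permutation invariance of unit order
  tab2 <- build_table(results[sample(length(results))], "stouffer")
  expect_equal(tab2$values, tab$values)
  # single unit: cells equal the unit's own z
  single <- build_table(results[1:6], "stouffer")
  expect_equal(single$values["precentral", "sulcus"],
               zmat[pairs$from == "precentral" & pairs$to == "sulcus", 1])
  # mixed metrics rejected
  bad <- results
  bad[[1]] <- causality_result("precentral", "sulcus", "mi", "full",
                               statistic = 0.2, p = 0.5)
  expect_error(build_table(bad, "stouffer"), "mixed metrics")
  # fisher on z-only results rejected
  expect_error(build_table(results, "fisher"), "p-valued")
})

test_that("stouffer output is standard-normal calibrated under the global null", {
  set.seed(99)
  agg <- replicate(200, stouffer(rnorm(18)))
  expect_lt(abs(mean(agg)), 0.25)
  expect_lt(abs(sd(agg) - 1), 0.2)
})

test_that("tables round-trip to TSV with a JSON sidecar", {
  results <- list()
  for (u in 1:2) for (from in c("precentral", "sulcus", "postcentral"))
    for (to in setdiff(c("precentral", "sulcus", "postcentral"), from))
      results[[length(results) + 1]] <-
        causality_result(from, to, "iig", "full", statistic = 0, z = u / 2)
  tab <- build_table(results, "stouffer")
  dir <- withr::local_tempdir()
  write_table_tsv(tab, file.path(dir, "t.tsv"))
  back <- utils::read.table(file.path(dir, "t.tsv"), header = TRUE, sep = "\t")
  expect_equal(back$sulcus[1], tab$values["precentral", "sulcus"])
  side <- jsonlite::read_json(file.path(dir, "t.json"))
  expect_equal(side$k, 2L)
  expect_equal(side$method, "stouffer")
})
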