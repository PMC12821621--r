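test_that("task protocol validates block timing", {
  p <- tapping_protocol()
  expect_equal(p$n_volumes, 80L)
  expect_equal(nrow(p$blocks), 8L)
  # overlap
  expect_error(task_protocol(3, 80, data.frame(
    onset_s = c(0, 15), duration_s = 30, condition = "right_hand")), "overlap")
  # not commensurate with TR
  expect_error(task_protocol(3, 80, data.frame(
    onset_s = 1, duration_s = 30, condition = "right_hand")), "multiples")
  # past end of run
  expect_error(task_protocol(3, 10, data.frame(
    onset_s = 0, duration_s = 60, condition = "left_hand")), "past the end")
  expect_error(task_protocol(0, 10, NULL), "positive")
})

test_that("condition segmentation maps hands to hemispheres", {
  p <- tapping_protocol()
  con <- segment_by_condition(p, "left", "contralateral")
  expect_equal(length(con$starts), 4L)
  expect_true(all(con$ends - con$starts == 10L))
  expect_equal(con$starts, c(0L, 20L, 40L, 60L))  # right-hand blocks
  # left/contra selects the same blocks as right/ipsi
  expect_equal(segment_by_condition(p, "right", "ipsilateral")[c("starts", "ends")],
               con[c("starts", "ends")])
  # contralateral and ipsilateral partition the task blocks
  ips <- segment_by_condition(p, "left", "ipsilateral")
  all_w <- sort(c(con$starts, ips$starts))
  expect_equal(all_w, as.integer(round(p$blocks$onset_s / p$tr_s)))
  expect_equal(sum(con$ends - con$starts) + sum(ips$ends - ips$starts), 80L)
  # 15-s blocks at TR 3 give 5-volume windows
  p2 <- task_protocol(3, 10, data.frame(onset_s = c(0, 15), duration_s = 15,
                                        condition = c("right_hand", "left_hand")))
  con2 <- segment_by_condition(p2, "left", "contralateral")
  expect_equal(con2$ends - con2$starts, 5L)
  # empty block sequence
  p3 <- task_protocol(3, 10, NULL)
  expect_length(segment_by_condition(p3, "left", "contralateral")$starts, 0L)
  expect_error(segment_by_condition(p, "dorsal", "contralateral"))
})

test_that("half-splits cover the run exactly once", {
  h <- split_halves(tapping_protocol())
  expect_equal(h$first_half$ends, 40L)
  expect_equal(h$second_half$starts, 40L)
  h7 <- split_halves(task_protocol(1, 7, NULL))
  expect_equal(c(h7$first_half$starts, h7$first_half$ends), c(0L, 3L))
  expect_equal(c(h7$second_half$starts, h7$second_half$ends), c(3L, 7L))
  h2 <- split_halves(task_protocol(1, 2, NULL))
  expect_equal(h2$first_half$ends, 1L)
  expect_error(split_halves(task_protocol(1, 1, NULL)), "halves")
})

test_that("within-block windows keep the requested span", {
  p <- tapping_protocol()
  con <- segment_by_condition(p, "left", "contralateral")
  w <- window_within_blocks(con, "first", 15, 3)
  expect_equal(w$ends - w$starts, rep(5L, 4))
  expect_equal(w$starts, con$starts)
  # span equal to block duration is the identity on windows
  same <- window_within_blocks(con, "first", 30, 3)
  expect_equal(same$starts, con$starts)
  expect_equal(same$ends, con$ends)
  one <- segment_set("x", 0L, 10L)
  last <- window_within_blocks(one, "last", 6, 3)
  expect_equal(c(last$starts, last$ends), c(8L, 10L))
  expect_error(window_within_blocks(one, "first", 45, 3), "exceeds window 1")
})

test_that("extraction concatenates windows and tracks epochs", {
  m <- matrix(seq_len(80 * 3), 80, 3)
  full <- segment_set("full", 0L, 80L)
  out <- extract_segments(m, full)
  expect_equal(unclass(out)[, ], m)
  two <- segment_set("two", c(0L, 40L), c(5L, 45L))
  out2 <- extract_segments(m, two)
  expect_equal(dim(out2), c(10L, 3L))
  expect_equal(attr(out2, "epoch"), rep(1:2, each = 5))
  expect_equal(out2[6, ], m[41, ])
  empty <- segment_set("none", integer(), integer())
  expect_equal(nrow(extract_segments(m, empty)), 0L)
  expect_error(extract_segments(m, segment_set("big", 0L, 81L)), "exceeds")
})

test_that("cortex restriction subsets voxels in order", {
  tissue <- c(rep("cortex", 22), rep("white_matter", 8))
  r <- region_recording("sulcus", "left", matrix(rnorm(80 * 30), 80, 30), tissue)
  rc <- restrict_to_cortex(r)
  expect_equal(ncol(rc$data), 22L)
  expect_equal(rc$data, r$data[, 1:22])
  all_c <- region_recording("sulcus", "left", r$data)
  expect_equal(restrict_to_cortex(all_c)$data, all_c$data)
  wm <- region_recording("sulcus", "left", matrix(0, 5, 2) + 1,
                         rep("white_matter", 2))
  expect_error(restrict_to_cortex(wm), "no cortex")
})

test_that("region mean matches the elementwise oracle", {
  set.seed(4)
  m <- matrix(rnorm(20), 5, 4)
  oracle <- sapply(1:5, function(i) sum(m[i, ]) / 4)
  expect_equal(as.numeric(region_mean(m)), oracle)
  expect_equal(as.numeric(region_mean(m[, 2, drop = FALSE])), m[, 2])
  expect_equal(as.numeric(region_mean(cbind(rep(1, 5), rep(3, 5)))), rep(2, 5))
})

test_that("subject IO round-trips and validates", {
  cfg <- generator_config(voxels_per_region = 5, wm_voxels_sulcus = 2, seed = 9)
  s <- simulate_subject(coupling_graph(), cfg)
  dir <- withr::local_tempdir()
  write_subject(s, file.path(dir, "sub01"))
  s2 <- read_subject(file.path(dir, "sub01"))
  expect_equal(s2$protocol$blocks, s$protocol$blocks)
  for (key in names(s$regions)) {
    expect_equal(unname(s2$regions[[key]]$data), unname(s$regions[[key]]$data))
    expect_equal(s2$regions[[key]]$tissue, s$regions[[key]]$tissue)
  }
  # malformed protocol is rejected with the file named
  bad <- file.path(dir, "sub01", "protocol.json")
  js <- jsonlite::read_json(bad)
  js$blocks[[2]][[1]] <- 10  # overlaps block 1
  jsonlite::write_json(js, bad, auto_unbox = TRUE)
  expect_error(read_subject(file.path(dir, "sub01")), "protocol.json")
  # tissue shorter than voxel count
  write_subject(s, file.path(dir, "sub02"))
  tf <- file.path(dir, "sub02", "left_sulcus.tissue.tsv")
  t <- utils::read.table(tf, header = TRUE, sep = "\t")
  utils::write.table(t[1:3, ], tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_subject(file.path(dir, "sub02")), "tissue")
})

test_that("voxel standardization is per-voxel over the segment", {
  set.seed(8)
  m <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  z <- standardize_voxels(m)
  expect_equal(colMeans(z), rep(0, 3))
  expect_equal(apply(z, 2, sd), rep(1, 3))
  const <- standardize_voxels(cbind(m[, 1], rep(2, 20)))
  expect_true(all(const[, 2] == 0))
})
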