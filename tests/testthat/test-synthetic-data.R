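test_that("canonical HRF is causal, peaks at ~5 s, undershoots once", {
  t <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(t)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gte(peak, 4); expect_lte(peak, 7)
  signs <- sign(h[h != 0])
  expect_equal(sum(diff(signs) != 0), 1L)  # one sign change: lobe then undershoot
  expect_error(canonical_hrf(c(0, 1, 3)), "uniform")
  expect_error(canonical_hrf(c(1, 2, 3)), "start at 0")
})

test_that("noise-free uncoupled voxels equal the direct convolution oracle", {
  cfg <- generator_config(sigma_neural = 0, sigma_obs = 0, beta_contra = 1,
                          beta_ipsi = 0.4, voxels_per_region = 3,
                          wm_voxels_sulcus = 1, seed = 42)
  s <- simulate_subject(coupling_graph(), cfg)
  r <- get_region(s, "left", "precentral")
  dt <- cfg$dt_s; burn <- cfg$burn_in_s / dt; S <- burn + 80 * 3 / dt
  tt <- (seq_len(S) - 1 - burn) * dt
  beta <- ifelse(tt < 0, 0, ifelse((tt %% 60) < 30, 1, 0.4))
  k <- canonical_hrf(seq(0, 32, by = dt)); k <- k / sum(k)
  conv <- sapply(seq_len(S), function(t) {
    j <- seq_len(min(length(k), t)); sum(k[j] * beta[t - j + 1])
  })
  oracle <- conv[burn + (0:79) * (3 / dt) + 1]
  est_load <- r$data[10, ] / oracle[10]
  expect_lt(max(abs(sweep(r$data, 2, est_load, "/") - oracle)), 1e-9)
  expect_true(all(est_load >= 0.5 & est_load <= 1.5))
})

test_that("contralateral blocks evoke stronger BOLD than ipsilateral", {
  cfg <- generator_config(sigma_neural = 0, sigma_obs = 0, voxels_per_region = 2,
                          wm_voxels_sulcus = 1, seed = 3)
  s <- simulate_subject(coupling_graph(), cfg)
  for (hemi in c("left", "right")) for (region in c("precentral", "postcentral")) {
    r <- get_region(s, hemi, region)
    con <- extract_segments(r, segment_by_condition(s$protocol, hemi, "contralateral"))
    ips <- extract_segments(r, segment_by_condition(s$protocol, hemi, "ipsilateral"))
    expect_gt(mean(con), mean(ips))
  }
})

test_that("latent coupling shifts the cross-correlation peak by the lag", {
  g <- coupling_graph(data.frame(source = "precentral", target = "sulcus",
                                 gain = 0.8, lag_s = 3))
  cfg <- generator_config(beta_contra = 0, beta_ipsi = 0, sigma_obs = 0, seed = 7)
  s <- simulate_subject(g, cfg)
  x <- region_mean(get_region(s, "left", "precentral"))
  y <- region_mean(get_region(s, "left", "sulcus"))
  cc <- ccf(x, y, lag.max = 4, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -1)  # source leads target by 1 volume
})

test_that("simulation is deterministic and validates", {
  cfg <- generator_config(voxels_per_region = 6, wm_voxels_sulcus = 2, seed = 19)
  g <- scenario_graph("direct")
  s1 <- simulate_subject(g, cfg)
  s2 <- simulate_subject(g, cfg)
  expect_identical(s1$regions, s2$regions)
  expect_s3_class(s1, "subject_recording")  # constructor enforces invariants
  # all-zero configuration gives constant recordings
  cfg0 <- generator_config(sigma_neural = 0, sigma_obs = 0, beta_contra = 0,
                           beta_ipsi = 0, voxels_per_region = 2,
                           wm_voxels_sulcus = 1, seed = 1)
  s0 <- simulate_subject(coupling_graph(), cfg0)
  expect_true(all(s0$regions$left_sulcus$data == 0))
})

test_that("unstable coupling graphs are rejected", {
  g <- coupling_graph(data.frame(source = c("precentral", "sulcus"),
                                 target = c("sulcus", "precentral"),
                                 gain = 1.6, lag_s = 0.5))
  cfg <- generator_config(seed = 2, voxels_per_region = 2, wm_voxels_sulcus = 1)
  expect_error(simulate_subject(g, cfg), "unstable")
})

test_that("scenario presets have the documented edge structure", {
  med <- scenario_graph("mediated")
  expect_equal(nrow(med$edges), 4L)
  expect_setequal(med$edges$source, c("precentral", "postcentral", "sulcus"))
  expect_true(all(med$edges$lag_s[med$edges$source == "sulcus"] < 3))
  dir <- scenario_graph("direct")
  expect_equal(nrow(dir$edges), 3L)
  expect_true(all(dir$edges$lag_s == 3))
  expect_equal(nrow(scenario_graph("null")$edges), 0L)
  expect_error(scenario_graph("ring"))
})

test_that("cohorts are reproducible with derived per-subject seeds", {
  cfg <- generator_config(voxels_per_region = 4, wm_voxels_sulcus = 1, seed = 100)
  coh <- make_cohort("null", 9, cfg)
  expect_length(coh, 9L)
  expect_equal(length(coh) * 2, 18L)  # (subject, hemisphere) analysis units
  expect_equal(nrow(coh[[1]]$provenance$edges), 0L)
  expect_equal(coh[[3]]$provenance$config$seed, 103L)
  coh2 <- make_cohort("null", 9, cfg)
  expect_identical(coh[[5]]$regions, coh2[[5]]$regions)
  # subjects differ from one another
  expect_false(identical(coh[[1]]$regions$left_sulcus$data,
                         coh[[2]]$regions$left_sulcus$data))
})

test_that("white-matter sulcal voxels mix the two gyral signals", {
  cfg <- generator_config(sigma_neural = 0, sigma_obs = 0, voxels_per_region = 4,
                          wm_voxels_sulcus = 2, wm_mixture = 0.5,
                          loading_range = c(1, 1), seed = 5)
  g <- coupling_graph(data.frame(source = "precentral", target = "postcentral",
                                 gain = 0.5, lag_s = 3))
  s <- simulate_subject(g, cfg)
  sul <- get_region(s, "left", "sulcus")
  pre <- get_region(s, "left", "precentral")$data[, 1]
  post <- get_region(s, "left", "postcentral")$data[, 1]
  expect_equal(sul$tissue, c("cortex", "cortex", "white_matter", "white_matter"))
  # with unit loadings the wm voxel is exactly the stated convex mixture
  expect_equal(sul$data[, 4], 0.5 * pre + 0.5 * post, tolerance = 1e-12)
})
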