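# Sorting-based brute-force information imbalance, independent of the
# counting implementation in the package.
bf_imbalance <- function(dA, dB, k = 1L) {
  N <- nrow(dA)
  total <- 0
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    oA <- others[order(dA[i, others], others)]
    oB <- others[order(dB[i, others], others)]
    total <- total + mean(match(oA[seq_len(k)], oB))
  }
  2 / N * total / N
}

# Tie-free random distance matrix over N instances.
random_distances <- function(N, dim = 3) {
  pairwise_distance(matrix(stats::rnorm(N * dim), N, dim))
}

# A small cohort with no coupling and no task drive: truly independent
# regions, used for null calibration checks.
independent_null_cohort <- function(n_subjects, seed, voxels = 30) {
  cfg <- generator_config(seed = seed, beta_contra = 0, beta_ipsi = 0,
                          voxels_per_region = voxels)
  make_cohort("null", n_subjects, cfg)
}

# Per-unit IIG Z-scores for one directed pair over a cohort.
cohort_edge_z <- function(cohort, from, to, seed, segments_fn = segment_full,
                          n_permutations = 100, trim_to_voxels = NULL) {
  zs <- numeric(0)
  i <- 0
  for (s in cohort) for (hemi in c("left", "right")) {
    i <- i + 1
    seg <- segments_fn(s$protocol)
    x <- extract_segments(get_region(s, hemi, from), seg)
    y <- get_region(s, hemi, to)
    if (!is.null(trim_to_voxels))
      y <- region_recording(y$region_id, y$hemisphere,
                            y$data[, seq_len(trim_to_voxels), drop = FALSE])
    y <- extract_segments(y, seg)
    zs[i] <- iig_causality(x, y, n_permutations = n_permutations,
                           seed = seed + i)$z_score
  }
  zs
}
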