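#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical HRF: a gamma response peaking about 5 s
#' after the stimulus minus a later gamma undershoot, here with peak
#' delay 6 s, undershoot delay 16 s, unit dispersions and undershoot
#' ratio 1/6, normalized to unit peak.  The kernel is causal
#' (`h(0) = 0`) and has exactly one sign change (positive lobe, then
#' undershoot).
#'
#' @param time_grid_s Uniform increasing time grid starting at 0, in
#'   seconds.
#' @return Numeric vector of kernel values on the grid, max = 1.
#' @export
canonical_hrf <- function(time_grid_s) {
  t <- as.numeric(time_grid_s)
  if (length(t) < 2 || t[1] != 0) stop_field("time grid must start at 0")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]) || dt[1] <= 0)
    stop_field("time grid must be uniform and increasing")
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Lagged linear coupling graph between regions
#'
#' Directed edges `source -> target` with a dimensionless gain and a
#' transmission lag in seconds.  The same graph is instantiated
#' independently in each hemisphere.
#'
#' @param edges A data.frame with columns `source`, `target` (region
#'   ids), `gain`, `lag_s`; zero rows allowed.
#' @return An object of class `coupling_graph`.
#' @export
coupling_graph <- function(edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        gain = numeric(), lag_s = numeric())
  edges <- as.data.frame(edges)
  need <- c("source", "target", "gain", "lag_s")
  if (!all(need %in% names(edges)))
    stop_field("edges must have columns %s", paste(need, collapse = ", "))
  if (nrow(edges)) {
    if (!all(edges$source %in% REGIONS) || !all(edges$target %in% REGIONS))
      stop_field("edge endpoints must be region ids")
    if (any(edges$source == edges$target)) stop_field("self-edges are not allowed")
    if (!all(is.finite(edges$gain))) stop_field("gains must be finite")
    if (any(edges$lag_s < 0)) stop_field("lags must be >= 0")
  }
  structure(list(edges = edges), class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("Coupling graph: %d edge(s)\n", nrow(x$edges)))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s (gain %g, lag %g s)\n", x$edges$source[i],
                  x$edges$target[i], x$edges$gain[i], x$edges$lag_s[i]))
  invisible(x)
}

#' Scenario presets for the coupling graph
#'
#' Two hypotheses about how the gyri and the sulcus exchange
#' information, plus a null:
#' * `mediated` — both gyri feed the sulcus at a 1-TR lag and the
#'   sulcus relays back to both gyri at a sub-TR lag (one simulation
#'   step), so the relay is faster than the sampling resolution.
#' * `direct` — both gyri feed the sulcus at 1 TR and the postcentral
#'   gyrus drives the precentral gyrus directly at 1 TR.
#' * `null` — no coupling at all.
#'
#' @param scenario `"mediated"`, `"direct"` or `"null"`.
#' @param gain Gain of the gyrus-to-sulcus (and direct gyrus-to-gyrus)
#'   edges (default 0.8).
#' @param relay_gain Gain of the sub-TR relay edges in the mediated
#'   scenario.  The two feed-forward/relay loops share the sulcus, so
#'   the total loop gain is `2 * gain * relay_gain`; the default 0.4
#'   keeps it at 0.64, inside the stability region (a uniform 0.8
#'   everywhere would diverge).
#' @param tr_s Repetition time (the 1-TR lag).
#' @param dt_s Simulation step (the sub-TR lag).
#' @return A [coupling_graph()].
#' @export
scenario_graph <- function(scenario = c("mediated", "direct", "null"),
                           gain = 0.8, relay_gain = 0.4, tr_s = 3, dt_s = 0.5) {
  scenario <- match.arg(scenario)
  edges <- switch(scenario,
    mediated = data.frame(
      source = c("precentral", "postcentral", "sulcus", "sulcus"),
      target = c("sulcus", "sulcus", "precentral", "postcentral"),
      gain = c(gain, gain, relay_gain, relay_gain),
      lag_s = c(tr_s, tr_s, dt_s, dt_s)),
    direct = data.frame(
      source = c("precentral", "postcentral", "postcentral"),
      target = c("sulcus", "sulcus", "precentral"),
      gain = gain, lag_s = tr_s),
    null = NULL)
  coupling_graph(edges)
}

#' Generator configuration
#'
#' All tunables of the block-design BOLD simulator.  Defaults emulate
#' the 1.5 T alternating finger-tapping acquisition: TR 3 s, four 30 s
#' blocks per hand (80 volumes over 4 min), 30 voxels per region of
#' which 8 sulcal voxels are white matter, task response twice as
#' strong contralaterally, neural noise comparable to the task drive
#' after haemodynamic smoothing, and no scanner drift.
#'
#' @param tr_s,block_s,blocks_per_condition Protocol parameters.
#' @param dt_s Latent simulation step in seconds; must divide `tr_s`.
#'   Sub-TR coupling lags are expressed on this grid.
#' @param voxels_per_region Voxels in every region.
#' @param wm_voxels_sulcus How many sulcal voxels are white matter
#'   (mixture voxels); must be < `voxels_per_region`.
#' @param beta_contra,beta_ipsi Task drive amplitude during blocks
#'   contralateral / ipsilateral to a region's hemisphere
#'   (`beta_contra >= beta_ipsi >= 0`).
#' @param sigma_neural Per-step sd of the latent neural noise.
#' @param sigma_obs Per-volume sd of voxel observation noise.
#' @param drift_amplitude,drift_period_s Slow sinusoidal drift added to
#'   every voxel (amplitude 0 disables it).
#' @param loading_range Range of the uniform per-voxel loadings.
#' @param wm_mixture Convex weight of the precentral signal in
#'   white-matter sulcal voxels (the rest is postcentral).
#' @param burn_in_s Simulated seconds discarded before volume 0.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(tr_s = 3, block_s = 30, blocks_per_condition = 4,
                             dt_s = 0.5, voxels_per_region = 30,
                             wm_voxels_sulcus = 8,
                             beta_contra = 1, beta_ipsi = 0.4,
                             sigma_neural = 1, sigma_obs = 0.3,
                             drift_amplitude = 0, drift_period_s = 120,
                             loading_range = c(0.5, 1.5), wm_mixture = 0.5,
                             burn_in_s = 30, seed = 1L) {
  steps <- tr_s / dt_s
  if (abs(steps - round(steps)) > 1e-9)
    stop_field("dt_s = %g must divide tr_s = %g", dt_s, tr_s)
  if (sigma_neural < 0 || sigma_obs < 0) stop_field("noise sds must be >= 0")
  if (!(beta_contra >= beta_ipsi && beta_ipsi >= 0))
    stop_field("need beta_contra >= beta_ipsi >= 0")
  if (wm_voxels_sulcus >= voxels_per_region)
    stop_field("wm_voxels_sulcus must leave at least one cortex voxel")
  if (wm_mixture < 0 || wm_mixture > 1) stop_field("wm_mixture must lie in [0, 1]")
  structure(list(tr_s = tr_s, block_s = block_s,
                 blocks_per_condition = blocks_per_condition, dt_s = dt_s,
                 voxels_per_region = as.integer(voxels_per_region),
                 wm_voxels_sulcus = as.integer(wm_voxels_sulcus),
                 beta_contra = beta_contra, beta_ipsi = beta_ipsi,
                 sigma_neural = sigma_neural, sigma_obs = sigma_obs,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 loading_range = loading_range, wm_mixture = wm_mixture,
                 burn_in_s = burn_in_s, seed = as.integer(seed)),
            class = "generator_config")
}

# Per-step task drive for one hemisphere's regions: beta_contra during
# blocks of the opposite hand, beta_ipsi during same-side blocks.
step_drive <- function(protocol, hemisphere, config, step_times) {
  beta <- numeric(length(step_times))
  contra_hand <- if (hemisphere == "left") "right_hand" else "left_hand"
  b <- protocol$blocks
  for (i in seq_len(nrow(b))) {
    inb <- step_times >= b$onset_s[i] & step_times < b$onset_s[i] + b$duration_s[i]
    beta[inb] <- if (b$condition[i] == contra_hand) config$beta_contra else config$beta_ipsi
  }
  beta
}

#' Simulate one subject's recordings
#'
#' Latent neural dynamics per region at step `dt_s`:
#' `n_r(t) = beta_r(t) + sum over incoming edges of gain * n_src(t - lag) + eta`,
#' with `beta_r` the task drive (stronger during contralateral blocks)
#' and `eta` white noise of sd `sigma_neural`.  The latent signal is
#' convolved with the canonical HRF (kernel normalized to unit sum, so
#' a sustained drive of amplitude beta plateaus at beta), sampled at
#' the TR, and projected to voxels: cortex voxel `v` carries
#' `loading_v * BOLD + drift + observation noise`; white-matter sulcal
#' voxels instead carry a convex mixture of the precentral and
#' postcentral BOLD (the fibre-passing signal) plus noise.  The two
#' hemispheres are simulated independently with mirrored task drives.
#' Identical seeds give identical output.
#'
#' @param graph A [coupling_graph()], instantiated in each hemisphere.
#' @param config A [generator_config()].
#' @param subject_id Identifier stored on the result.
#' @return A [subject_recording()] whose `provenance` records the graph
#'   and configuration.
#' @export
simulate_subject <- function(graph, config, subject_id = "sim") {
  stopifnot(inherits(graph, "coupling_graph"), inherits(config, "generator_config"))
  protocol <- tapping_protocol(config$tr_s, config$block_s, config$blocks_per_condition)
  dt <- config$dt_s
  burn_steps <- as.integer(round(config$burn_in_s / dt))
  run_steps <- as.integer(round(protocol$n_volumes * config$tr_s / dt))
  S <- burn_steps + run_steps
  step_times <- (seq_len(S) - 1 - burn_steps) * dt  # volume 0 starts at time 0
  lag_steps <- as.integer(round(graph$edges$lag_s / dt))
  if (nrow(graph$edges) && any(lag_steps < 1))
    stop_field("coupling lag below the simulation step dt_s = %g", dt)
  src_i <- match(graph$edges$source, REGIONS)
  tgt_i <- match(graph$edges$target, REGIONS)
  kernel <- canonical_hrf(seq(0, 32, by = dt))
  kernel <- kernel / sum(kernel)
  steps_per_tr <- as.integer(round(config$tr_s / dt))
  vol_steps <- burn_steps + (seq_len(protocol$n_volumes) - 1L) * steps_per_tr + 1L

  set.seed(config$seed)
  regions <- list()
  for (hemi in HEMISPHERES) {
    beta <- step_drive(protocol, hemi, config, step_times)
    drive <- cbind(beta, beta, beta)  # same task drive for all three regions
    eta <- matrix(stats::rnorm(S * 3, sd = config$sigma_neural), S, 3)
    n <- matrix(0, S, 3)
    for (t in seq_len(S)) {
      n[t, ] <- drive[t, ] + eta[t, ]
      for (e in seq_along(src_i)) {
        tp <- t - lag_steps[e]
        if (tp >= 1)
          n[t, tgt_i[e]] <- n[t, tgt_i[e]] + graph$edges$gain[e] * n[tp, src_i[e]]
      }
    }
    if (!all(is.finite(n)) || max(abs(n)) > 1e6)
      stop_field("unstable latent recursion for coupling graph with %d edge(s)",
                 nrow(graph$edges))
    bold <- apply(n, 2, function(v) {
      conv <- stats::convolve(v, rev(kernel), type = "open")
      conv[seq_len(S)]
    })
    bold_tr <- bold[vol_steps, , drop = FALSE]  # volumes x regions
    drift <- if (config$drift_amplitude > 0) {
      config$drift_amplitude *
        sin(2 * pi * (seq_len(protocol$n_volumes) - 1) * config$tr_s /
              config$drift_period_s)
    } else numeric(protocol$n_volumes)
    for (ri in seq_along(REGIONS)) {
      region <- REGIONS[ri]
      V <- config$voxels_per_region
      n_wm <- if (region == "sulcus") config$wm_voxels_sulcus else 0L
      tissue <- c(rep("cortex", V - n_wm), rep("white_matter", n_wm))
      loading <- stats::runif(V, config$loading_range[1], config$loading_range[2])
      noise <- matrix(stats::rnorm(protocol$n_volumes * V, sd = config$sigma_obs),
                      protocol$n_volumes, V)
      base <- matrix(bold_tr[, ri], protocol$n_volumes, V)
      if (n_wm > 0) {
        wm_sig <- config$wm_mixture * bold_tr[, match("precentral", REGIONS)] +
          (1 - config$wm_mixture) * bold_tr[, match("postcentral", REGIONS)]
        base[, (V - n_wm + 1):V] <- matrix(wm_sig, protocol$n_volumes, n_wm)
      }
      data <- sweep(base, 2, loading, "*") + drift + noise
      regions[[paste(hemi, region, sep = "_")]] <-
        region_recording(region, hemi, data, tissue)
    }
  }
  prov <- list(generator = "iigfc block-design simulator",
               edges = graph$edges, config = unclass(config))
  subject_recording(subject_id, protocol, regions, prov)
}

#' Simulate a cohort
#'
#' Generates `n_subjects` independent subjects under one coupling
#' scenario.  Per-subject seeds are `config$seed + subject index`, so
#' cohorts are reproducible from a single master seed.
#'
#' @param scenario `"mediated"`, `"direct"` or `"null"` (see
#'   [scenario_graph()]), or a [coupling_graph()] for custom edges.
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [generator_config()]; its `seed` is the master seed.
#' @param gain Edge gain used by the scenario presets.
#' @return A list of [subject_recording()]s named `sub01`, `sub02`, ...
#' @export
make_cohort <- function(scenario = "null", n_subjects = 9L,
                        config = generator_config(), gain = 0.8) {
  if (n_subjects < 1) stop_field("n_subjects must be >= 1")
  graph <- if (inherits(scenario, "coupling_graph")) scenario
           else scenario_graph(scenario, gain = gain,
                               tr_s = config$tr_s, dt_s = config$dt_s)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    simulate_subject(graph, cfg_i, subject_id = sprintf("sub%02d", i))
  })
}
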