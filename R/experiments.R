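# Subject-level experiment drivers: one synthetic "subject" is a seeded
# draw of source geometry plus one simulated recording per task/condition,
# pushed through the full processing chain. These functions are the working
# units behind the analysis scripts and the acceptance checks.

#' Build a subject-specific wrist-task configuration
#'
#' Draws subject anatomy (source-centre jitter) and dead electrodes from the
#' subject seed, then returns a [sim_config()] for a cyclic wrist
#' flexion/extension task with the three default sources.
#'
#' @param seed Subject seed.
#' @param n_cycles Movement cycles (default 20, the wrist protocol).
#' @param gain_scale Multiplier on source amplitudes (finger tasks use 0.5).
#' @param prone_gain Named per-source prone gains (see
#'   [default_wrist_sources()]).
#' @param condition_shift_x Prone-condition ulnar-radial source shift, IED.
#' @param n_bad Number of planted dead electrodes (default 2).
#' @param ... Further arguments to [sim_config()].
#' @return A `sim_config`.
#' @export
wrist_subject_config <- function(seed, n_cycles = 20L, gain_scale = 1,
                                 prone_gain = NULL, condition_shift_x = 0,
                                 n_bad = 2L, ...) {
  grid <- grid_layout()
  sources <- with_seed(seed * 13L + 1L,
                       default_wrist_sources(center_jitter = 0.5,
                                             gain_scale = gain_scale,
                                             prone_gain = prone_gain))
  bad <- with_seed(seed * 13L + 2L, {
    idx <- sample.int(n_channels(grid), n_bad)
    cc <- channel_coords(grid)
    lapply(idx, function(i) c(cc$x[i], cc$y[i]))
  })
  sim_config(grid = grid, sources = sources, n_cycles = n_cycles,
             bad_channels = bad, condition_shift_x = condition_shift_x,
             seed = seed, ...)
}

#' Process one simulated recording through conditioning and cycle analysis
#'
#' Runs the preprocessing chain (band-pass, power-line removal, envelope,
#' bad-channel detection), resamples and synchronizes the joint angle,
#' detects and filters movement cycles, and time-normalizes envelopes.
#'
#' @param rec An [emg_recording()] with attached `kinematics`.
#' @param n_points Phase points per normalized cycle (default 500).
#' @return List with `env`, `trace`, `cycles`, `norm` (from
#'   [time_normalize()]), `mean_env` (channels x phase), `cmc` (per
#'   channel), `active` (logical), `bad_mask`.
#' @export
process_recording <- function(rec, n_points = 500L) {
  stopifnot(inherits(rec, "emg_recording"), !is.null(rec$kinematics))
  env <- preprocess(rec)
  trace <- resample_sync(rec$kinematics$angle, fs_in = rec$kinematics$fs_angle,
                         target_fs = rec$fs)
  n <- min(length(trace$angle), ncol(env$env))
  trace$angle <- trace$angle[seq_len(n)]
  env$env <- env$env[, seq_len(n), drop = FALSE]
  cycles <- detect_cycles(trace)
  if (length(cycles$rom) >= 4L) cycles <- exclude_outlier_cycles(cycles)
  norm <- time_normalize(env, cycles, angle = trace$angle, n_points = n_points)
  list(env = env, trace = trace, cycles = cycles, norm = norm,
       mean_env = mean_envelope(norm$norm_env),
       cmc = channel_cmc(norm$norm_env),
       active = active_channels(env),
       bad_mask = env$bad_mask)
}

#' Median envelope CMC over active channels of one task
#'
#' @param proc Output of [process_recording()].
#' @return Scalar median CMC across active, unmasked channels.
#' @export
median_active_cmc <- function(proc) {
  keep <- proc$active & !proc$bad_mask
  median(proc$cmc[keep], na.rm = TRUE)
}

#' Module extraction for one processed subject
#'
#' Restricts the mean envelope to unmasked channels, fits NNMF at the
#' requested module count and (optionally) selects the module count by the
#' VAF criterion.
#'
#' @param proc Output of [process_recording()] (or a list of them, which are
#'   concatenated task blocks).
#' @param N Module count for the fixed-N fit (default 3).
#' @param n_restarts Random restarts (default 20).
#' @param seed Seed for the restarts.
#' @param select Also run [select_module_count()] (default TRUE).
#' @param n_range Candidate module counts for selection.
#' @return List with `fit` (`module_decomposition`), `selection` (or NULL),
#'   `kept_channels`, `M`.
#' @export
subject_modules <- function(proc, N = 3L, n_restarts = 20L, seed = 1L,
                            select = TRUE, n_range = 1:10) {
  procs <- if (!is.null(proc$mean_env)) list(proc) else proc
  bad <- Reduce(`|`, lapply(procs, `[[`, "bad_mask"))
  kept <- which(!bad)
  blocks <- lapply(procs, function(p) p$mean_env[kept, , drop = FALSE])
  names(blocks) <- names(procs) %||% paste0("task", seq_along(procs))
  M <- concatenate_tasks(blocks)
  fit <- fit_nnmf(M, N = N, n_restarts = n_restarts, seed = seed)
  selection <- if (select) {
    select_module_count(M, n_range = n_range, n_restarts = n_restarts,
                        seed = seed + 1L)
  }
  list(fit = fit, selection = selection, kept_channels = kept, M = M)
}

# Identify which fitted module corresponds to a planted temporal profile.
# The planted profile (ground truth from the generator) is correlated with
# each unit-max temporal module; returns the index of the best match.
identify_module <- function(S, profile) {
  np <- length(profile)
  phase_idx <- round(seq(1, np, length.out = ncol(S)))
  which.max(cor(t(S), profile[phase_idx]))
}

#' Simulate and analyse one wrist subject in two hand positions
#'
#' Simulates the same subject in the `neutral` (reference) and `prone`
#' conditions, processes both recordings, fits NNMF (N modules) per
#' condition, matches modules across conditions by temporal correlation and
#' segments the matched coefficient maps.
#'
#' @param seed Subject seed.
#' @param condition_shift_x Planted prone-condition COG shift, IED units.
#' @param prone_gain Named per-source prone gains (e.g.
#'   `c(extensor = 1.4, flexor = 0.5)`).
#' @param n_cycles Cycles per condition.
#' @param N Module count (default 3).
#' @param n_restarts NNMF restarts (default 20).
#' @return List with per-matched-module entries: `label` (planted source
#'   best matching the neutral module), `r` (temporal match), `shift_x`
#'   (|COG_prone - COG_neutral| along x), `weight_ratio` (prone/neutral
#'   barycenter weight), plus `fits`, `clusters` and `maps` per condition.
#' @export
condition_pair_analysis <- function(seed, condition_shift_x = 0,
                                    prone_gain = c(extensor = 1, flexor = 1),
                                    n_cycles = 20L, N = 3L, n_restarts = 20L) {
  cfg <- wrist_subject_config(seed, n_cycles = n_cycles,
                              prone_gain = prone_gain,
                              condition_shift_x = condition_shift_x)
  recs <- list(neutral = simulate_emg(cfg, "neutral"),
               prone = simulate_emg(cfg, "prone"))
  procs <- lapply(recs, process_recording)
  bad <- procs$neutral$bad_mask | procs$prone$bad_mask
  kept <- which(!bad)
  fits <- lapply(procs, function(p)
    fit_nnmf(p$mean_env[kept, , drop = FALSE], N = N,
             n_restarts = n_restarts, seed = seed))
  matched <- match_modules(fits$neutral$S, fits$prone$S)
  grid <- cfg$grid
  truth_profiles <- recs$neutral$truth$profiles
  labels <- recs$neutral$truth$labels
  modules <- list()
  for (k in seq_len(nrow(matched))) {
    jn <- matched$module_a[k]
    jp <- matched$module_b[k]
    src <- which.max(vapply(truth_profiles, function(pr) {
      idx <- round(seq(1, length(pr), length.out = ncol(fits$neutral$S)))
      cor(fits$neutral$S[jn, ], pr[idx])
    }, numeric(1)))
    map_n <- coefficient_map(fits$neutral$A[, jn], grid, bad)
    map_p <- coefficient_map(fits$prone$A[, jp], grid, bad)
    cl_n <- segment_map(map_n)
    cl_p <- segment_map(map_p)
    if (!length(cl_n) || !length(cl_p)) next
    wr <- tryCatch(weight_ratio(map_p, map_n, cog(cl_p[[1L]]), cog(cl_n[[1L]])),
                   error = function(e) NA_real_)
    modules[[length(modules) + 1L]] <- list(
      label = labels[src], r = matched$r[k],
      module_neutral = jn, module_prone = jp,
      cog_neutral = cog(cl_n[[1L]]), cog_prone = cog(cl_p[[1L]]),
      shift_x = cog_shift(cl_p[[1L]], cl_n[[1L]], axis = "x"),
      weight_ratio = wr,
      cluster_neutral = cl_n[[1L]], cluster_prone = cl_p[[1L]],
      map_neutral = map_n, map_prone = map_p)
  }
  list(modules = modules, fits = fits, procs = procs, cfg = cfg,
       kept_channels = kept, truth = lapply(recs, `[[`, "truth"))
}

#' Default source geometry of the four single-finger extensor sources
#'
#' One source per finger. The middle-finger source is placed at least
#' 2.5 IED away from every other source centre, matching the planted
#' separability the recovery checks probe.
#'
#' @return Named list of `(x, y)` centres.
#' @export
finger_source_centers <- function() {
  list(index = c(3.0, 3.5), middle = c(6.0, 6.0),
       ring = c(9.0, 3.5), little = c(12.0, 5.0))
}

#' Simulate and analyse one subject's single-finger tasks
#'
#' Each finger task carries one planted extensor source (sigma 1 IED) at a
#' finger-specific grid position with small subject-specific jitter; tasks
#' run the full chain (simulate, preprocess, cycles, NNMF with VAF-selected
#' module count, map segmentation) and the dominant activity cluster per
#' finger is returned.
#'
#' @param seed Subject seed.
#' @param n_cycles Cycles per finger task (default 12, the finger protocol).
#' @param gain_scale Source amplitude relative to wrist defaults
#'   (default 0.5).
#' @param n_restarts NNMF restarts per task (default 10; per-task envelope
#'   structure is rank 1).
#' @return List with `clusters` (named per finger), `maps`, `overlaps`
#'   (middle vs others, both normalizations), `cog_distances` (middle vs
#'   others, IED units), `median_cmc` per finger.
#' @export
finger_separability_analysis <- function(seed, n_cycles = 12L,
                                         gain_scale = 0.5, n_restarts = 10L) {
  centers <- finger_source_centers()
  grid <- grid_layout()
  jit <- with_seed(seed * 17L + 3L,
                   matrix(runif(2L * length(centers), -0.3, 0.3), ncol = 2L))
  clusters <- list()
  maps <- list()
  med_cmc <- numeric(0)
  for (i in seq_along(centers)) {
    fn <- names(centers)[i]
    src <- planted_source(centers[[i]] + jit[i, ], sigma = 1,
                          profile = gain_scale * phase_bump(0.62, 0.09),
                          gain = c(neutral = 1), label = fn)
    cfg <- sim_config(grid = grid, sources = list(src), n_cycles = n_cycles,
                      seed = seed * 101L + i)
    proc <- process_recording(simulate_emg(cfg))
    kept <- which(!proc$bad_mask)
    sel <- select_module_count(proc$mean_env[kept, , drop = FALSE],
                               n_range = 1:3, n_restarts = n_restarts,
                               seed = seed + i)
    A <- sel$fits[[as.character(sel$N)]]$A
    # the dominant module's map carries the finger's activity area
    j <- which.max(colSums(A))
    map <- coefficient_map(A[, j], grid, proc$bad_mask)
    cl <- segment_map(map)
    if (!length(cl)) stop("no cluster recovered for finger ", fn, call. = FALSE)
    clusters[[fn]] <- cl[[1L]]
    maps[[fn]] <- map
    med_cmc[fn] <- median_active_cmc(proc)
  }
  others <- setdiff(names(centers), "middle")
  ov <- t(vapply(others, function(fn) overlap(clusters$middle, clusters[[fn]]),
                 numeric(2)))
  dists <- vapply(others, function(fn)
    cog_shift(clusters$middle, clusters[[fn]], axis = "euclidean"), numeric(1))
  list(clusters = clusters, maps = maps, overlaps = ov,
       cog_distances = dists, median_cmc = med_cmc)
}

#' Designed geometry for the electrode-subset reconstruction comparison
#'
#' Simulates a wrist subject whose sources sit well distal of the proximal
#' ring row, so the ring carries only weak source projections while the
#' COG-targeted electrodes sit on the source centres; compares
#' cross-validated r^2 of the two subsets.
#'
#' @param seed Subject seed.
#' @param n_cycles Cycles (default 12).
#' @param env_fs Envelope resampling rate for the MLP inputs, samples/s
#'   (default 32; the 1 Hz envelope bandwidth makes higher rates redundant).
#' @return List with `r2_ring`, `r2_cog` (per-fold vectors), `comparison`
#'   (ANOVA + SNK) and the subsets.
#' @export
subset_comparison_analysis <- function(seed, n_cycles = 12L, env_fs = 32) {
  cfg <- wrist_subject_config(seed, n_cycles = n_cycles, n_bad = 0L)
  # push sources toward the distal rows, away from the y = 1 ring
  for (i in seq_along(cfg$sources)) {
    cfg$sources[[i]]$center[2] <- max(cfg$sources[[i]]$center[2], 5)
  }
  rec <- simulate_emg(cfg)
  proc <- process_recording(rec)
  kept <- which(!proc$bad_mask)
  mods <- subject_modules(proc, N = 3L, n_restarts = 10L, seed = seed,
                          select = FALSE)
  clusters <- list()
  for (j in seq_len(3L)) {
    map <- coefficient_map(mods$fit$A[, j], cfg$grid, proc$bad_mask)
    cl <- segment_map(map)
    if (length(cl)) clusters[[length(clusters) + 1L]] <- cl[[1L]]
  }
  sub_ring <- select_subset(cfg$grid, "ring", bad_mask = proc$bad_mask)
  sub_cog <- select_subset(cfg$grid, "cog", clusters = clusters,
                           bad_mask = proc$bad_mask)
  # envelope + angle, downsampled for the regression
  step <- max(1L, as.integer(round(rec$fs / env_fs)))
  idx <- seq(1L, length(proc$trace$angle), by = step)
  cyc_id <- findInterval(idx, proc$cycles$onsets)
  use <- cyc_id >= 1L & cyc_id <= nrow(proc$cycles$boundaries)
  idx <- idx[use]
  cyc_id <- cyc_id[use]
  y <- proc$trace$angle[idx]
  res <- lapply(list(ring = sub_ring, cog = sub_cog), function(sub) {
    X <- t(proc$env$env[sub$channels, idx, drop = FALSE])
    crossval_r2(X, y, cyc_id, folds = 4L, seed = seed)
  })
  comparison <- compare_subsets(ring = res$ring$r2, cog = res$cog$r2)
  list(r2_ring = res$ring$r2, r2_cog = res$cog$r2, comparison = comparison,
       subset_ring = sub_ring, subset_cog = sub_cog)
}
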