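# Whole-pipeline orchestration: simulate a cohort of synthetic subjects,
# run every analysis stage and collect the summary tables (CMC, VAF and
# module counts, activity clusters and COGs, overlap, prone/neutral shift
# and weight ratios, subset r^2 comparison).

#' Pipeline configuration
#'
#' @param seed Master seed; every random stage derives its seed from it.
#' @param n_subjects Number of simulated subjects.
#' @param n_cycles_wrist,n_cycles_finger Movement cycles per task.
#' @param n_restarts NNMF restarts.
#' @param vaf_threshold VAF module-count criterion.
#' @param condition_shift_x Planted prone-condition COG shift (IED).
#' @param prone_gain Named prone gains per source.
#' @param stages Stages to run, a subset of
#'   `c("cmc", "modules", "separability", "condition_shift", "reconstruction")`.
#' @param out_dir Optional output directory for CSV tables and the resolved
#'   config.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 2L,
                            n_cycles_wrist = 10L, n_cycles_finger = 8L,
                            n_restarts = 10L, vaf_threshold = 0.90,
                            condition_shift_x = 0.8,
                            prone_gain = c(extensor = 1.4, flexor = 0.5),
                            stages = c("cmc", "modules", "separability",
                                       "condition_shift"),
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_cycles_wrist = as.integer(n_cycles_wrist),
                 n_cycles_finger = as.integer(n_cycles_finger),
                 n_restarts = as.integer(n_restarts),
                 vaf_threshold = vaf_threshold,
                 condition_shift_x = condition_shift_x,
                 prone_gain = prone_gain, stages = stages,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated subjects
#'
#' @param config A [pipeline_config()].
#' @return A report list with one data frame per stage table; written as
#'   CSV files (plus the resolved configuration as YAML when the `yaml`
#'   package is available) under `config$out_dir` if set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- config$seed + seq_len(config$n_subjects) - 1L
  report <- list(config = unclass(config))

  if ("cmc" %in% config$stages || "modules" %in% config$stages) {
    cmc_rows <- list()
    vaf_rows <- list()
    for (s in seq_along(seeds)) {
      cfg <- wrist_subject_config(seeds[s], n_cycles = config$n_cycles_wrist)
      proc <- tryCatch(process_recording(simulate_emg(cfg)),
                       error = function(e) stop("stage cmc/modules, subject ",
                                                s, ": ", conditionMessage(e),
                                                call. = FALSE))
      if ("cmc" %in% config$stages) {
        cmc_rows[[s]] <- data.frame(subject = s, task = "wrist_flex_ext",
                                    median_cmc = median_active_cmc(proc),
                                    n_cycles_kept = sum(proc$cycles$kept_mask),
                                    excluded_frac = proc$cycles$excluded_frac %||% 0)
      }
      if ("modules" %in% config$stages) {
        mods <- subject_modules(proc, N = 3L, n_restarts = config$n_restarts,
                                seed = seeds[s], select = TRUE, n_range = 1:10)
        vaf_rows[[s]] <- data.frame(subject = s,
                                    N = as.integer(names(mods$selection$vaf_curve)),
                                    vaf = unname(mods$selection$vaf_curve),
                                    selected = as.integer(names(mods$selection$vaf_curve)) ==
                                      mods$selection$N)
      }
    }
    if (length(cmc_rows)) report$cmc_table <- do.call(rbind, cmc_rows)
    if (length(vaf_rows)) report$vaf_table <- do.call(rbind, vaf_rows)
  }

  if ("separability" %in% config$stages) {
    ov_rows <- list()
    for (s in seq_along(seeds)) {
      res <- finger_separability_analysis(seeds[s],
                                          n_cycles = config$n_cycles_finger)
      ov_rows[[s]] <- data.frame(subject = s,
                                 finger = rownames(res$overlaps),
                                 overlap_vs_smallest = res$overlaps[, 1L],
                                 overlap_vs_largest = res$overlaps[, 2L],
                                 cog_distance_ied = res$cog_distances)
    }
    report$overlap_table <- do.call(rbind, ov_rows)
  }

  if ("condition_shift" %in% config$stages) {
    rows <- list()
    cogs_n <- list()
    cogs_p <- list()
    for (s in seq_along(seeds)) {
      res <- condition_pair_analysis(seeds[s],
                                     condition_shift_x = config$condition_shift_x,
                                     prone_gain = config$prone_gain,
                                     n_cycles = config$n_cycles_wrist,
                                     n_restarts = config$n_restarts)
      for (m in res$modules) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, module = m$label, match_r = m$r,
          shift_x_ied = m$shift_x, weight_ratio = m$weight_ratio)
        if (m$label == "extensor") {
          cogs_n[[length(cogs_n) + 1L]] <- m$cog_neutral
          cogs_p[[length(cogs_p) + 1L]] <- m$cog_prone
        }
      }
    }
    report$shift_table <- do.call(rbind, rows)
    if (length(cogs_n) >= 5L) {
      test <- cog_position_test(do.call(rbind, cogs_n), do.call(rbind, cogs_p),
                                axis = "x")
      report$cog_wilcoxon <- data.frame(axis = "x", p_value = test$p_value,
                                        n = test$n)
    }
  }

  if ("reconstruction" %in% config$stages) {
    r2_rows <- list()
    for (s in seq_along(seeds)) {
      res <- subset_comparison_analysis(seeds[s],
                                        n_cycles = max(config$n_cycles_wrist, 10L))
      r2_rows[[s]] <- data.frame(subject = s,
                                 fold = rep(seq_along(res$r2_ring), 2L),
                                 subset = rep(c("ring", "cog"),
                                              each = length(res$r2_ring)),
                                 r2 = c(res$r2_ring, res$r2_cog))
    }
    report$r2_table <- do.call(rbind, r2_rows)
  }

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

# Write the report tables as CSV plus the resolved config.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(report), "config")) {
    if (is.data.frame(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- report$config
    cfg$prone_gain <- as.list(cfg$prone_gain)
    yaml::write_yaml(cfg, file.path(out_dir, "pipeline_config.yaml"))
  }
  invisible(out_dir)
}
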