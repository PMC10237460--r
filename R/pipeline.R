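default_pipeline_config <- function() {
  list(
    seed = 1L,
    input_dir = NULL,
    simulate = list(n_users = 5, n_days = 28,
                    events_per_user = list(run = 4, high_stress_work = 2)),
    metrics = list(step_s = 30, block_s = 300, threshold_g = 0.05,
                   max_exceed_frac = 0, min_beats = 100),
    baseline = list(span_days = 28, min_days = 25,
                    rfd_mode = "hourly_over_daily"),
    impact = list(exclude_overlaps = TRUE, n_post_bins = 10,
                  hr_max_bpm = 190),
    infer = list(alpha = 0.05))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' YAML config with top-level keys `seed`, `input_dir` (optional: read
#' existing per-user directories instead of simulating), and per-stage blocks
#' `simulate`, `metrics`, `baseline`, `impact`, `infer`. Unset values fall
#' back to documented defaults.
#'
#' @param path Path to a YAML file, or a named list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_config(default_pipeline_config(), user)
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("configuration error: input_dir does not exist: ", cfg$input_dir)
  cfg
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  x <- as.data.frame(x)
  if ("load" %in% names(x)) x$load[is.na(x$load)] <- "n/a"
  data.table::fwrite(x, path)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> metric windows -> circadian baseline ->
#' event impact -> inference as one reproducible run. Writes `windows.csv`,
#' `baseline.csv`, `rfd_profiles.csv`, `event_bins.csv`, `event_auc.csv`,
#' `spline_fits.csv`, `dunnett.csv`, `tukey.csv`, a plain-text `summary.txt`,
#' and a `manifest.json` with the config snapshot, seed, package version and
#' MD5 digests of every output (re-running with the same manifest reproduces
#' identical outputs).
#'
#' @param config Path to a YAML config, or a config list
#'   (see [read_pipeline_config()]).
#' @param out_dir Output directory.
#' @param seed Optional override of the config seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate or load -----------------------------------------------------
  cohort <- stage("simulate", {
    if (is.null(cfg$input_dir)) {
      sim_args <- cfg$simulate
      sim_args$events_per_user <- unlist(sim_args$events_per_user)
      sim_args$rng_seed <- cfg$seed
      co <- simulate_cohort(do.call(sim_config, sim_args))
      data_dir <- file.path(out_dir, "data")
      write_cohort(co, data_dir)
      co
    } else {
      dirs <- list.dirs(cfg$input_dir, recursive = FALSE)
      if (length(dirs) == 0)
        stop("configuration error: no user directories in input_dir")
      users <- lapply(dirs, function(d) {
        u <- read_user_dir(d)
        u$user_id <- basename(d)
        u
      })
      structure(list(users = users, ground_truth = NULL, config = NULL),
                class = "sw_cohort")
    }
  })

  # --- metric windows -------------------------------------------------------
  windows <- stage("metrics", {
    w <- lapply(cohort$users, function(u) {
      wi <- do.call(compute_metric_windows,
                    c(list(beats = u$beats, motion = u$motion,
                           events = u$events), cfg$metrics))
      if (nrow(wi)) wi$user_id <- u$user_id
      wi
    })
    do.call(rbind, w[vapply(w, nrow, integer(1)) > 0])
  })
  outputs <- c(outputs, write_table(windows, out_dir, "windows.csv"))

  # --- circadian baseline ---------------------------------------------------
  baseline <- stage("baseline",
                    hourly_medians(windows, span_days = cfg$baseline$span_days,
                                   min_days = cfg$baseline$min_days))
  sleep <- do.call(rbind, lapply(cohort$users, function(u) {
    s <- u$sleep
    if (is.null(s) || nrow(s) == 0) return(NULL)
    s$user_id <- u$user_id
    s
  }))
  rfd <- stage("baseline", {
    clock <- relative_fractional_difference(baseline, mode = cfg$baseline$rfd_mode)
    aligned <- if (!is.null(sleep))
      align_to_sleep_wake(windows, sleep, baseline, mode = cfg$baseline$rfd_mode)
    rbind(clock, aligned)
  })
  outputs <- c(outputs, write_table(baseline, out_dir, "baseline.csv"),
               write_table(rfd, out_dir, "rfd_profiles.csv"))

  # --- event impact ---------------------------------------------------------
  events <- do.call(rbind, lapply(cohort$users, function(u) u$events))
  bins <- auc <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    events <- stage("impact", {
      cls <- tryCatch(classify_cohort_runs(cohort, baseline,
                                           hr_max_bpm = cfg$impact$hr_max_bpm),
                      error = function(e) NULL)
      if (!is.null(cls)) {
        events$load <- cls$load_classified[match(events$event_id, cls$event_id)]
        events$load[events$type != "run"] <- NA
      }
      events
    })
    bins <- stage("impact",
                  event_deviation_table(windows, events, baseline,
                                        exclude_overlaps = cfg$impact$exclude_overlaps,
                                        n_post_bins = cfg$impact$n_post_bins))
    auc <- stage("impact", auc_table(bins))
    outputs <- c(outputs, write_table(bins, out_dir, "event_bins.csv"),
                 write_table(auc, out_dir, "event_auc.csv"))
  }

  # --- inference ------------------------------------------------------------
  spline_rows <- stage("infer", {
    rows <- list()
    for (ax in unique(rfd$axis)) for (met in c("hr", "hrv")) {
      d <- rfd[rfd$axis == ax, ]
      y <- if (met == "hr") d$rfd_hr else d$rfd_hrv
      fitted <- tryCatch(fit_linear_spline(d$bin_center_h, y,
                                           default_knots(ax, met)),
                         error = function(e) NULL)
      if (is.null(fitted)) next
      s <- fitted$segments
      s$axis <- ax
      s$metric <- met
      rows[[length(rows) + 1]] <- s
    }
    do.call(rbind, rows)
  })
  if (!is.null(spline_rows))
    outputs <- c(outputs, write_table(spline_rows, out_dir, "spline_fits.csv"))

  dunnett_rows <- tukey_rows <- NULL
  if (!is.null(bins) && nrow(bins) > 0) {
    groups <- unique(data.frame(type = bins$type, load = bins$load,
                                stringsAsFactors = FALSE))
    dl <- list()
    for (i in seq_len(nrow(groups))) {
      sel <- bins$type == groups$type[i] &
        (is.na(groups$load[i]) | (!is.na(bins$load) & bins$load == groups$load[i]))
      for (met in c("delta_hr_bpm", "delta_hrv_ms")) {
        dn <- tryCatch(dunnett_vs_pre(bins[sel, ], metric = met,
                                      alpha = cfg$infer$alpha),
                       error = function(e) NULL)
        if (is.null(dn)) next
        dn$type <- groups$type[i]
        dn$load <- groups$load[i]
        dn$metric <- met
        dl[[length(dl) + 1]] <- as.data.frame(dn)
      }
    }
    dunnett_rows <- if (length(dl)) do.call(rbind, dl) else NULL
    if (!is.null(dunnett_rows))
      outputs <- c(outputs, write_table(dunnett_rows, out_dir, "dunnett.csv"))

    if (!is.null(auc) && nrow(auc) > 0) {
      tl <- list()
      for (met in c("auc_hr", "auc_hrv")) {
        tk <- tryCatch(tukey_auc_groups(auc[auc$type == "run", ], metric = met),
                       error = function(e) NULL, warning = function(w) NULL)
        if (is.null(tk)) next
        tk$metric <- met
        tl[[length(tl) + 1]] <- as.data.frame(tk)
      }
      tukey_rows <- if (length(tl)) do.call(rbind, tl) else NULL
      if (!is.null(tukey_rows))
        outputs <- c(outputs, write_table(tukey_rows, out_dir, "tukey.csv"))
    }
  }

  # --- summary + manifest ---------------------------------------------------
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(sprintf("stresswear pipeline run (seed %d)", cfg$seed), con)
  writeLines(sprintf("users analysed: %d (excluded: %d)",
                     nrow(attr(baseline, "daily")),
                     nrow(attr(baseline, "excluded"))), con)
  if (!is.null(spline_rows)) {
    writeLines("", con)
    writeLines("diurnal spline segments (axis, metric, from-to, beta, P):", con)
    for (i in seq_len(nrow(spline_rows)))
      writeLines(sprintf("  %-24s %-4s [%6.1f,%6.1f]  beta=%+.4f  P=%.3g",
                         spline_rows$axis[i], spline_rows$metric[i],
                         spline_rows$from[i], spline_rows$to[i],
                         spline_rows$beta[i], spline_rows$p_value[i]), con)
  }
  if (!is.null(dunnett_rows)) {
    writeLines("", con)
    writeLines("event-bin Dunnett comparisons vs Pre (type/load, metric, bin, estimate, adj P):", con)
    for (i in seq_len(nrow(dunnett_rows)))
      if (dunnett_rows$bin[i] != "Pre")
        writeLines(sprintf("  %-16s %-8s %-12s %-8s  %+8.3f  P=%.3g",
                           dunnett_rows$type[i],
                           ifelse(is.na(dunnett_rows$load[i]), "-",
                                  dunnett_rows$load[i]),
                           dunnett_rows$metric[i], dunnett_rows$bin[i],
                           dunnett_rows$estimate[i],
                           dunnett_rows$p_adjusted[i]), con)
  }
  if (!is.null(tukey_rows)) {
    writeLines("", con)
    writeLines("run-load AUC Tukey contrasts (metric, contrast, estimate, adj P):", con)
    for (i in seq_len(nrow(tukey_rows)))
      writeLines(sprintf("  %-8s %-20s %+10.1f  P=%.3g", tukey_rows$metric[i],
                         tukey_rows$contrast[i], tukey_rows$estimate[i],
                         tukey_rows$p_adjusted[i]), con)
  }
  close(con)
  outputs <- c(outputs, summary_path)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("stresswear")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "input_dir")],
    input_dir = cfg$input_dir,
    output_digests = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
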