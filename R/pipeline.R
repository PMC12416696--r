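# End-to-end orchestration: simulate/load -> clean -> classify -> devstats
# -> networks -> circadian, with deterministic per-stage seeds and a result
# manifest. Stage outputs are pure functions of (inputs, config, seed).

#' Pipeline configuration
#'
#' @param input Path to a canonical track file, or `NULL` to simulate.
#' @param input_dialect Dialect for [load_trackset()].
#' @param huddles Path to a huddle CSV (`start_s, end_s, x, y`), or `NULL`.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param out_dir Output directory.
#' @param seed Master seed; stage s uses `seed + s` (stages numbered in run
#'   order from 1), so each stage is independently reproducible.
#' @param stages Character vector of stages to run (in canonical order).
#' @param swap_rate_per_day Identity-swap corruption injected before
#'   cleaning (0 disables; exercises the repair stage).
#' @param jump_cm,refit_cm Switch-detector thresholds (see
#'   [detect_id_switches()]); `refit_cm = NULL` scales the 25 fps default
#'   0.5 cm by `25 / fps`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_dialect = "canonical-h5",
                            huddles = NULL, sim = sim_config(),
                            out_dir = "results", seed = 1,
                            stages = c("clean", "classify", "devstats",
                                       "networks", "circadian"),
                            swap_rate_per_day = 0,
                            jump_cm = 10, refit_cm = NULL) {
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  if (!is.null(huddles) && !file.exists(huddles))
    stop("huddle path does not exist: ", huddles)
  stopifnot(jump_cm > 0)
  structure(list(input = input, input_dialect = input_dialect,
                 huddles = huddles, sim = sim, out_dir = out_dir,
                 seed = seed, stages = stages,
                 swap_rate_per_day = swap_rate_per_day,
                 jump_cm = jump_cm, refit_cm = refit_cm),
            class = "pipeline_config")
}

pipe_log <- function(level, stage, msg) {
  message(sprintf("[%s] %-9s %s", level, stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order and writes every tabular artifact
#' (daily ethograms, rapid-development flags, hull overlaps, correlations,
#' network metrics, circadian transition report) plus a JSON manifest with
#' per-stage record counts and content hashes. Identical config and seed
#' reproduce identical artifact hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  manifest <- list(stages = list(), artifacts = list())
  artifacts <- character(0)
  put <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  stage_no <- 0L
  run_stage <- function(name, f) {
    stage_no <<- stage_no + 1L
    set.seed(config$seed + stage_no)
    t0 <- Sys.time()
    out <- tryCatch(f(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      records = if (is.data.frame(out)) nrow(out) else NA,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    pipe_log("INFO", name, sprintf("done in %ss",
                                   manifest$stages[[name]]$seconds))
    out
  }

  # --- input ---------------------------------------------------------------
  if (is.null(config$input)) {
    sim <- run_stage("simulate", function() {
      simulate_family(config$sim)
    })
    ts <- sim$tracks; huddles <- sim$huddles
    put(sim$ground_truth$budgets, "ground_truth_budgets.csv")
  } else {
    ts <- load_trackset(config$input, config$input_dialect)
    huddles <- if (!is.null(config$huddles)) {
      h <- utils::read.csv(config$huddles)
      huddle_track(h$start_s, h$end_s, h$x, h$y)
    } else NULL
    sim <- NULL
  }

  # --- clean ---------------------------------------------------------------
  if ("clean" %in% config$stages) {
    cleaned <- run_stage("clean", function() {
      if (config$swap_rate_per_day > 0) {
        inj <- inject_id_swaps(ts, config$swap_rate_per_day,
                               seed = config$seed + 101)
        ts <- inj$tracks
        put(as.data.frame(inj$log), "injected_swaps.csv")
      }
      refit <- if (is.null(config$refit_cm)) 0.5 * 25 / ts$fps else config$refit_cm
      ev <- detect_id_switches(ts, jump_cm = config$jump_cm, refit_cm = refit)
      put(as.data.frame(ev), "detected_swaps.csv")
      ts <- correct_id_switches(ts, ev)
      interpolate_gaps(ts, huddles)
    })
    ts <- cleaned$tracks; huddles <- cleaned$huddles
  }

  etho <- NULL
  if ("classify" %in% config$stages) {
    etho <- run_stage("classify", function() {
      daily_ethogram(ts, huddles)
    })
    for (b in names(etho))
      write_daily_matrix(etho[[b]], file.path(config$out_dir,
                                              paste0("ethogram_", b, ".csv")))
    artifacts <- c(artifacts,
                   file.path(config$out_dir,
                             paste0("ethogram_", names(etho), ".csv")))
    gsoc <- group_time_by_day(ts)
    put(gsoc, "group_socialization.csv")
    bud <- daily_time_budget(ts, huddles)
    put(bud, "daily_time_budget.csv")
  }

  if ("devstats" %in% config$stages) {
    run_stage("devstats", function() {
      if (is.null(etho)) stop("devstats requires the classify stage")
      animals <- ts$animals
      pups <- animals$name[animals$age_class == "pup"]
      flags <- list(); rel <- list()
      for (b in names(etho)) {
        r <- tryCatch(normalize_to_adult(etho[[b]], animals),
                      error = function(e) NULL)
        if (is.null(r)) next
        rel[[b]] <- r$values
        rd <- rapid_development_days(r$values)
        if (nrow(rd$table) > 0)
          flags[[b]] <- cbind(behavior = b, rd$table)
      }
      if (length(flags) > 0)
        put(do.call(rbind, flags), "rapid_development.csv")
      if (length(rel) >= 2) {
        nb <- names(rel)
        ov <- list()
        for (i in seq_along(nb)) for (j in seq_along(nb)) {
          if (j <= i) next
          h <- tryCatch(hull_overlap(rel[[nb[i]]], rel[[nb[j]]],
                                     seed = config$seed + 7),
                        error = function(e) NULL)
          if (!is.null(h))
            ov[[length(ov) + 1]] <- data.frame(
              behavior_a = nb[i], behavior_b = nb[j],
              n_pcs = h$n_pcs_used, percent = h$percent)
        }
        if (length(ov) > 0) put(do.call(rbind, ov), "hull_overlaps.csv")
        corr <- trajectory_correlations(rel)
        put(corr, "trajectory_correlations.csv")
      }
      data.frame(done = TRUE)
    })
  }

  if ("networks" %in% config$stages) {
    run_stage("networks", function() {
      met <- daily_network_metrics(ts)
      put(met, "network_metrics.csv")
      met
    })
  }

  if ("circadian" %in% config$stages) {
    run_stage("circadian", function() {
      nm <- ts$animals$name
      bl <- lapply(nm, function(a) roi_occupancy(ts, a, "food")$bouts)
      names(bl) <- nm
      prof <- daily_profiles(bl, ts)
      long <- expand.grid(animal = nm,
                          pnd = as.integer(dimnames(prof)[[2]]),
                          hour = 0:23)
      long$value <- prof[cbind(match(long$animal, dimnames(prof)[[1]]),
                               match(long$pnd, as.integer(dimnames(prof)[[2]])),
                               long$hour + 1)]
      put(long, "hourly_profiles.csv")
      pups <- ts$animals$name[ts$animals$age_class == "pup"]
      res <- tryCatch({
        tr <- find_transitions(prof[pups, , , drop = FALSE])
        put(tr$surface, "circadian_surface.csv")
        put(data.frame(t1 = tr$t1, t2 = tr$t2, J = tr$J,
                       degenerate = tr$degenerate), "circadian_transitions.csv")
        tr
      }, error = function(e) {
        pipe_log("WARN", "circadian", conditionMessage(e))
        NULL
      })
      data.frame(done = TRUE)
    })
  }

  artifacts <- unique(artifacts[file.exists(artifacts)])
  manifest$artifacts <- lapply(artifacts, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  manifest$config_hash <- digest_config(config)
  manifest$seed <- config$seed
  manifest$n_frames <- length(ts$time_s)
  manifest$elapsed_s <- round(as.numeric(difftime(Sys.time(), t_start,
                                                  units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# md5 of the deparsed config text
digest_config <- function(config) {
  s <- utils::capture.output(utils::str(config, digits.d = 12))
  tf <- tempfile()
  writeLines(s, tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}
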