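## CSV readers/writers with schema validation, YAML config round-trips,
## histogram reporting and the end-to-end pipeline.
##
## All coordinates are centimetres.  The matching-error sign convention
## is (mirrored active - target) in the passive-hand frame; column
## headers are explicit in every file written.

TRIAL_COLUMNS <- c("participant_id", "block", "target_id",
                   "target_x", "target_y", "passive_x", "passive_y",
                   "active_x", "active_y")
PARTICIPANT_COLUMNS <- c("participant_id", "group", "age", "sex",
                         "handedness", "platform", "passive_arm", "protocol")

check_schema <- function(df, required, numeric_cols, what, path) {
  if (nrow(df) == 0L) {
    stop(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' is missing column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf("%s file '%s': non-numeric `%s` at row(s) %s",
                   what, path, col,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Read / write trial tables
#'
#' CSV with columns `participant_id, block, target_id, target_x,
#' target_y, passive_x, passive_y, active_x, active_y` (coordinates in
#' cm).  Reading validates the schema and rejects duplicate
#' `(participant, block, target)` rows with their row numbers.
#'
#' @param path CSV file path.
#' @return `read_trials`: the validated data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, TRIAL_COLUMNS,
                     c("block", "target_id", "target_x", "target_y",
                       "passive_x", "passive_y", "active_x", "active_y"),
                     "trials", path)
  key <- paste(df$participant_id, df$block, df$target_id)
  if (anyDuplicated(key)) {
    stop(sprintf("trials file '%s': duplicate (participant, block, target) at row(s) %s",
                 path, paste(utils::head(which(duplicated(key)), 5), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @param digits Decimal places for coordinates (default 3; the robot
#'   resolution of 0.1 mm makes 3 lossless).
#' @export
write_trials <- function(trials, path, digits = 3) {
  out <- trials[, TRIAL_COLUMNS]
  for (col in c("target_x", "target_y", "passive_x", "passive_y",
                "active_x", "active_y")) {
    out[[col]] <- round(out[[col]], digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write participant tables
#'
#' @param path CSV file path.
#' @return `read_participants`: the validated data frame.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, PARTICIPANT_COLUMNS, "age", "participants", path)
}

#' @rdname read_participants
#' @param participants Participant table to write.
#' @export
write_participants <- function(participants, path) {
  cols <- intersect(c(PARTICIPANT_COLUMNS, "impaired"), names(participants))
  utils::write.csv(participants[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cohort configuration as YAML
#'
#' @param config An `apm_cohort_config`.
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  ## named numeric vectors become YAML maps so their names survive
  to_yamlable <- function(x) {
    if (is.list(x)) lapply(x, to_yamlable)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_yamlable(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fix_named_num <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE))) {
      unlist(x)
    } else x
  }
  for (f in c("protocol_mix", "platform_mix")) raw[[f]] <- fix_named_num(raw[[f]])
  for (g in c("control", "stroke")) {
    raw[[g]] <- lapply(raw[[g]], fix_named_num)
  }
  cfg <- cohort_config(n_control = raw$n_control, n_stroke = raw$n_stroke,
                       protocol_mix = raw$protocol_mix,
                       platform_mix = raw$platform_mix,
                       dual_arm_controls = raw$dual_arm_controls,
                       control = raw$control, stroke = raw$stroke)
  cfg
}

#' Per-parameter group histograms
#'
#' Overlaid control/stroke histograms with within-group percentage
#' normalization (each group's bin percentages sum to 100).  If `dir` is
#' given, one PNG per parameter is written; the binned counts are always
#' returned so they can be checked independently of the figures.
#'
#' @param params Parameter table.
#' @param groups Group label per row.
#' @param parameters Which parameters to plot.
#' @param dir Optional output directory for PNG files.
#' @param breaks Number of histogram cells (passed to [graphics::hist()]).
#' @return Invisibly, a named list per parameter with `breaks` and the
#'   per-group percentage matrices.
#' @export
plot_parameter_histograms <- function(params, groups,
                                      parameters = apm_parameter_names(),
                                      dir = NULL, breaks = 30) {
  groups <- as.character(groups)
  out <- lapply(parameters, function(p) {
    v <- params[[p]]
    br <- graphics::hist(v, breaks = breaks, plot = FALSE)$breaks
    tabs <- lapply(split(v, groups), function(g) {
      h <- graphics::hist(g, breaks = br, plot = FALSE)
      100 * h$counts / length(g)
    })
    if (!is.null(dir)) {
      grDevices::png(file.path(dir, paste0("hist_", p, ".png")),
                     width = 700, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      cols <- c("#4477AAAA", "#EE6677AA")
      ylim <- c(0, max(unlist(tabs)))
      mids <- (br[-1] + br[-length(br)]) / 2
      graphics::plot(mids, tabs[[1]], type = "h", lwd = 6, col = cols[1],
                     ylim = ylim, xlab = paste(p, "(cm)"),
                     ylab = "% of group", main = p)
      if (length(tabs) > 1) {
        graphics::lines(mids + diff(br)[1] / 4, tabs[[2]], type = "h",
                        lwd = 6, col = cols[2])
      }
      graphics::legend("topright", legend = names(tabs), fill = cols, bty = "n")
    }
    list(breaks = br, percent = tabs)
  })
  names(out) <- parameters
  invisible(out)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, compute the 12 APM parameters, fit the
#' normative and task-score models on controls, classify impairment with
#' the cut-off technique (cross-validated rates), run the classifier
#' comparison, and write all tables, models and figures to `out_dir`.
#'
#' @param config Cohort configuration for simulation; ignored when
#'   `trials`/`participants` are supplied.
#' @param trials,participants Optional pre-loaded tables (e.g. from
#'   [read_trials()]).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed Master seed for simulation, folds and models.
#' @param K Cross-validation folds for both the cut-off rates and the
#'   classifier comparison.
#' @param models Character vector of classifier names to run; `NULL`
#'   skips the ML comparison.
#' @param sidedness Sidedness map for the task score.
#' @param threshold Impairment cut-off (default 1.96).
#' @param figures Write histogram PNGs (default FALSE; figures are not
#'   text and are skipped in programmatic runs).
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config = cohort_config(), trials = NULL,
                         participants = NULL, out_dir = NULL, seed = 1L,
                         K = 10L, models = APM_MODEL_NAMES,
                         sidedness = default_sidedness(), threshold = 1.96,
                         figures = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(trials)) {
    cohort <- stage("simulate", generate_cohort(config, seed = seed))
    trials <- cohort$trials
    participants <- cohort$participants
  } else if (is.null(participants)) {
    stop("`participants` must accompany `trials`", call. = FALSE)
  }
  params <- stage("parameters", compute_parameters(trials, participants))
  is_ctrl <- participants$group == "control"
  norm <- stage("normative",
                fit_normative(params[is_ctrl, ], participants[is_ctrl, ]))
  z_all <- stage("zscore", predict(norm, params, participants))
  tsm <- stage("task_score_fit",
               fit_task_score(z_all[is_ctrl, ], sidedness))
  scores <- stage("task_score", predict(tsm, z_all))
  imp <- stage("cutoff", classify_impairment(z_all, scores, sidedness, threshold))
  rates <- stage("cutoff_cv",
                 impairment_rates_cv(params, participants, K = K,
                                     seed = seed, sidedness = sidedness,
                                     threshold = threshold))
  ml <- NULL
  if (!is.null(models) && length(models)) {
    specs <- lapply(models, model_spec, seed = seed)
    names(specs) <- toupper(models)
    ml <- stage("ml", run_experiment(zscore_matrix(z_all), participants$group,
                                     specs = specs, K = K, seed = seed))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_participants(participants, file.path(out_dir, "participants.csv"))
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(params, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(z_all, file.path(out_dir, "zscores.csv"),
                     row.names = FALSE)
    ts_tab <- data.frame(participant_id = participants$participant_id,
                         task_score = scores,
                         outlier = participants$participant_id %in%
                           tsm$outlier_ids,
                         impaired_overall = imp$overall)
    utils::write.csv(ts_tab, file.path(out_dir, "task_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(rates$rates, file.path(out_dir, "impairment_rates.csv"),
                     row.names = FALSE)
    write_normative_json(norm, file.path(out_dir, "normative_model.json"),
                         task_model = tsm)
    if (!is.null(ml)) {
      jsonlite::write_json(
        lapply(ml$models, function(m) {
          list(fold_metrics = as.data.frame(m$fold_metrics),
               mean = as.list(m$mean_metrics), sd = as.list(m$sd_metrics),
               auc = m$auc)
        }),
        file.path(out_dir, "ml_results.json"), auto_unbox = TRUE, digits = NA)
      roc_tab <- do.call(rbind, lapply(ml$models, function(m) {
        data.frame(model = m$name, fpr = m$roc$fpr, tpr = m$roc$tpr)
      }))
      utils::write.csv(roc_tab, file.path(out_dir, "roc_curves.csv"),
                       row.names = FALSE)
      imp_tab <- do.call(rbind, lapply(ml$models, function(m) {
        if (is.null(m$importance)) return(NULL)
        data.frame(model = m$name, feature = names(m$importance),
                   importance_pct = as.vector(m$importance))
      }))
      utils::write.csv(imp_tab, file.path(out_dir, "feature_importance.csv"),
                       row.names = FALSE)
    }
    if (figures) {
      plot_parameter_histograms(params, participants$group, dir = out_dir)
    }
    manifest <- list(seed = seed, K = K, threshold = threshold,
                     n_sessions = nrow(participants),
                     n_trials = nrow(trials),
                     models = if (is.null(ml)) character(0) else names(ml$models),
                     r_version = as.character(getRversion()),
                     package_version = as.character(utils::packageVersion("propriokit")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(participants = participants, trials = trials,
                 parameters = params, normative = norm, zscores = z_all,
                 task_score_model = tsm, task_scores = scores,
                 impairment = imp, rates = rates, ml = ml))
}
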