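#' Deterioration-index-only baseline predictions
#'
#' Reduces each hospitalization's raw index stream to the prediction grid
#' and emits one prediction per window, so the unaugmented index can be
#' evaluated with exactly the same aggregation and sweep machinery as the
#' fused model. The baseline predicts from admission onward (it does not
#' need a radiograph). Windows stop at exit from hospital; for the high-risk
#' task they additionally stop before the deterioration event.
#'
#' @param cohort a (filtered) `cohort`.
#' @param grid a [grid_spec()].
#' @return Data frame `hosp_id`, `window_start`, `risk`.
#' @export
baseline_predictions <- function(cohort, grid) {
  h <- cohort$hospitalizations
  idx_split <- split(cohort$index_scores, cohort$index_scores$hosp_id)
  rows <- lapply(seq_len(nrow(h)), function(i) {
    id <- h$hosp_id[i]
    idx <- idx_split[[id]]
    if (is.null(idx)) return(NULL)
    red <- reduce_index_to_windows(idx$time, idx$score, grid)
    red <- red[!is.na(red$score), , drop = FALSE]
    stop_at <- min(h$exit_time[i], grid$horizon_hours)
    if (grid$task == "high_risk" && !is.na(h$deterioration_time[i])) {
      stop_at <- min(stop_at, h$deterioration_time[i])
    }
    red <- red[red$window_start < stop_at, , drop = FALSE]
    if (nrow(red) == 0) return(NULL)
    data.frame(hosp_id = id, window_start = red$window_start,
               risk = red$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: cohort sizes (train, validation
#' and test are three disjoint simulated cohorts, with the fusion model
#' early-stopped on the validation cohort), simulator settings, training
#' settings and evaluation targets.
#'
#' @param n_train,n_valid,n_test hospitalizations per cohort.
#' @param sim named list of [sim_config()] overrides (everything except
#'   `n_patients` and `seed`, which the pipeline controls).
#' @param train named list of [train_config()] overrides (except `seed`).
#' @param npv_targets NPV targets for low-risk counting.
#' @param timepoints evaluation times in hours for the low-risk task.
#' @param n_boot bootstrap resamples for the AUROC confidence interval.
#' @param sens_target sensitivity anchor for the specificity report.
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_train = 1500, n_valid = 500, n_test = 1000,
                            sim = list(), train = list(),
                            npv_targets = c(0.95, 0.90),
                            timepoints = c(24, 32, 40, 48),
                            n_boot = 1000, sens_target = 0.8, seed = 1L) {
  stopifnot(is.list(sim), is.list(train))
  if (any(c("n_patients", "seed") %in% names(sim))) {
    stop("simulator size and seed are controlled by the pipeline", call. = FALSE)
  }
  for (t in timepoints) check_scalar(t, "timepoints", 4)
  for (t in npv_targets) check_probability(t, "npv_targets")
  check_scalar(n_boot, "n_boot", 1)
  check_probability(sens_target, "sens_target")
  check_scalar(seed, "seed")
  structure(list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 n_test = as.integer(n_test), sim = sim, train = train,
                 npv_targets = npv_targets, timepoints = timepoints,
                 n_boot = as.integer(n_boot), sens_target = sens_target,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ..., json = FALSE) {
  info <- list(...)
  if (json) {
    message(jsonlite::toJSON(c(list(stage = stage), info), auto_unbox = TRUE))
  } else {
    kv <- paste(names(info), unlist(info), sep = "=", collapse = " ")
    message(sprintf("[%s] %s", stage, kv))
  }
}

#' Run the end-to-end image-augmentation pipeline
#'
#' Simulates disjoint train/validation/test cohorts, applies the inclusion
#' filters, aligns score streams onto the prediction grid, trains the
#' low-risk and high-risk fusion models, predicts on the test cohort, and
#' evaluates both the augmented model and the deterioration-index-only
#' baseline with the NPV-sweep and AUROC protocols. Fully reproducible from
#' the configuration seed.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log per-stage row counts and exclusion tallies to stderr.
#' @param log_json emit logs as JSON lines instead of `key=value` text.
#' @return An object of class `evaluation_report`: filter tallies, low-risk
#'   NPV curves and counts (augmented and baseline, per timepoint and NPV
#'   target), and high-risk AUROC with bootstrap CI and
#'   sensitivity-anchored specificity for both models.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE,
                         log_json = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(stage, ...) {
    if (verbose) pipeline_log(stage, ..., json = log_json)
  }

  sizes <- c(train = cfg$n_train, valid = cfg$n_valid, test = cfg$n_test)
  cohorts <- list()
  tallies <- list()
  for (i in seq_along(sizes)) {
    nm <- names(sizes)[i]
    scfg <- do.call(sim_config, c(list(n_patients = sizes[[i]],
                                       seed = derive_seed(cfg$seed, i)),
                                  cfg$sim))
    raw <- simulate_cohort(scfg)
    filt <- apply_inclusion_filters(raw)
    cohorts[[nm]] <- filt$kept
    tally <- table(factor(filt$excluded$reason,
                          levels = c("no_oxygen", "no_xray_in_window",
                                     "early_event_or_discharge",
                                     "deterioration_before_xray")))
    tallies[[nm]] <- c(input = nrow(raw$hospitalizations),
                       kept = nrow(filt$kept$hospitalizations),
                       as.vector(tally))
    names(tallies[[nm]])[3:6] <- names(tally)
    say("filter", cohort = nm, input = nrow(raw$hospitalizations),
        kept = nrow(filt$kept$hospitalizations),
        excluded = nrow(filt$excluded))
  }

  tasks <- c("low_risk", "high_risk")
  grids <- lapply(stats::setNames(tasks, tasks), grid_spec)
  inst <- lapply(cohorts, function(co) {
    lapply(grids, function(g) build_instances(co, g))
  })
  for (nm in names(inst)) {
    say("align", cohort = nm,
        low_risk_instances = nrow(inst[[nm]]$low_risk),
        high_risk_instances = nrow(inst[[nm]]$high_risk))
  }

  models <- list()
  preds <- list()
  for (k in seq_along(tasks)) {
    task <- tasks[k]
    tcfg <- do.call(train_config, c(list(seed = derive_seed(cfg$seed, 100 + k)),
                                    cfg$train))
    models[[task]] <- train_fusion(inst$train[[task]], inst$valid[[task]],
                                   tcfg, task = task)
    say("fuse", task = task, best_epoch = models[[task]]$best_epoch,
        valid_bce = round(models[[task]]$valid_loss, 4))
    ti <- inst$test[[task]]
    preds[[task]] <- data.frame(hosp_id = ti$hosp_id,
                                window_start = ti$window_start,
                                risk = predict(models[[task]], ti),
                                stringsAsFactors = FALSE)
  }

  test_h <- cohorts$test$hospitalizations
  base <- lapply(grids, function(g) baseline_predictions(cohorts$test, g))

  # ---- low-risk protocol -------------------------------------------------
  low <- list()
  for (model_nm in c("augmented", "baseline")) {
    p <- if (model_nm == "augmented") preds$low_risk else base$low_risk
    per_time <- list()
    for (upto in cfg$timepoints) {
      risks <- suppressWarnings(aggregate_low_risk(p, test_h, upto))
      curve <- npv_sweep(risks)
      counts <- vapply(cfg$npv_targets,
                       function(t) count_low_risk_at_npv(curve, t), integer(1))
      per_time[[as.character(upto)]] <- list(
        n_patients = nrow(risks),
        counts = stats::setNames(as.list(counts), cfg$npv_targets),
        fraction = stats::setNames(as.list(counts / nrow(risks)),
                                   cfg$npv_targets)
      )
      if (upto == max(cfg$timepoints)) {
        per_time[[as.character(upto)]]$npv_curve <- curve
      }
    }
    low[[model_nm]] <- per_time
    say("evaluate", task = "low_risk", model = model_nm,
        n = per_time[[as.character(max(cfg$timepoints))]]$n_patients)
  }

  # ---- high-risk protocol ------------------------------------------------
  high <- list()
  for (model_nm in c("augmented", "baseline")) {
    p <- if (model_nm == "augmented") preds$high_risk else base$high_risk
    risks <- suppressWarnings(aggregate_high_risk(p, test_h))
    ci <- bootstrap_ci(risks, auroc, n_boot = cfg$n_boot,
                       seed = derive_seed(cfg$seed, 200))
    high[[model_nm]] <- list(
      n_patients = nrow(risks),
      auroc = auroc(risks$aggregated_score, risks$label),
      auroc_ci = as.list(ci),
      specificity_at_sens = specificity_at_sensitivity(
        risks$aggregated_score, risks$label, cfg$sens_target)
    )
    say("evaluate", task = "high_risk", model = model_nm,
        auroc = round(high[[model_nm]]$auroc, 4))
  }

  structure(list(
    config = cfg, filter_tallies = tallies, low_risk = low, high_risk = high,
    models = models
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Image-augmented deterioration index: evaluation report\n")
  tmax <- as.character(max(x$config$timepoints))
  for (nm in names(x$low_risk)) {
    cts <- x$low_risk[[nm]][[tmax]]$counts
    cat(sprintf("  low-risk @%sh (%s): %s\n", tmax, nm,
                paste(sprintf("NPV %s -> %d flagged", names(cts),
                              unlist(cts)), collapse = ", ")))
  }
  for (nm in names(x$high_risk)) {
    h <- x$high_risk[[nm]]
    cat(sprintf("  high-risk AUROC (%s): %.3f [%.3f, %.3f], spec@sens%.2f = %.3f\n",
                nm, h$auroc, h$auroc_ci$lower, h$auroc_ci$upper,
                x$config$sens_target, h$specificity_at_sens))
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' Serializes everything except the model objects (curves become arrays).
#'
#' @param report an `evaluation_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- unclass(report)
  payload$models <- NULL
  payload$config <- unclass(payload$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
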