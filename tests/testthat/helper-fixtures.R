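# Fixture builders and a memoised signal-recovery study shared by the fusion
# and acceptance tests (it is the expensive part of the suite, so it runs
# once).

make_hosp <- function(hosp_id = "H1", exit_time = 120,
                      deterioration_time = NA_real_,
                      deterioration_type = NA_character_, on_oxygen = TRUE) {
  data.frame(patient_id = paste0("P", hosp_id), hosp_id = hosp_id,
             admit_time = 0, exit_time = exit_time,
             deterioration_time = deterioration_time,
             deterioration_type = deterioration_type,
             on_oxygen = on_oxygen, stringsAsFactors = FALSE)
}

make_cohort <- function(hosp, xrays, index_scores) {
  structure(list(hospitalizations = hosp, xrays = xrays,
                 index_scores = index_scores), class = "cohort")
}

# A flat 15-minute index stream at a constant score.
flat_index <- function(hosp_id, upto = 120, score = 0.2) {
  t <- seq(0, upto, by = 0.25)
  data.frame(hosp_id = hosp_id, time = t, score = rep(score, length(t)),
             stringsAsFactors = FALSE)
}

# Instance-level synthetic classification sets for the fusion tests.
random_instances <- function(n, seed, rule = c("noise", "separable")) {
  rule <- match.arg(rule)
  set.seed(seed)
  df <- data.frame(
    hosp_id = sprintf("H%05d", seq_len(n)),
    window_start = sample(seq(4, 116, by = 4), n, replace = TRUE),
    image_score = runif(n), index_score = runif(n),
    hours_since_xray = runif(n, 0, 48), hours_since_admit = runif(n, 4, 120),
    stringsAsFactors = FALSE
  )
  if (rule == "noise") {
    df$label <- rbinom(n, 1, 0.5)
  } else {
    # linearly separable on index_score with a wide margin
    df$label <- rbinom(n, 1, 0.5)
    df$index_score <- ifelse(df$label == 1, runif(n, 0.8, 1), runif(n, 0, 0.2))
  }
  df
}

# Held-out binary cross-entropy of a trained model on an instance set.
bce_loss_for_test <- function(model, instances) {
  p <- pmin(pmax(predict(model, instances), 1e-12), 1 - 1e-12)
  y <- instances$label
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Per-seed end-to-end study: simulate train/valid/test cohorts (1500/500/1000
# hospitalizations), train the low- and/or high-risk fusion models, and
# compare against the index-only baseline on the test cohort.
run_signal_study_seed <- function(seed, w_image_only, tasks = c("low_risk",
                                                                "high_risk")) {
  sizes <- c(train = 1500, valid = 500, test = 1000)
  cohorts <- lapply(seq_along(sizes), function(i) {
    cfg <- sim_config(n_patients = sizes[[i]], w_image_only = w_image_only,
                      seed = 1000 * seed + i)
    apply_inclusion_filters(simulate_cohort(cfg))$kept
  })
  names(cohorts) <- names(sizes)
  out <- list(seed = seed)
  for (task in tasks) {
    g <- grid_spec(task)
    inst <- lapply(cohorts, build_instances, grid = g)
    m <- train_fusion(inst$train, inst$valid,
                      train_config(seed = seed), task = task)
    ti <- inst$test
    aug <- data.frame(hosp_id = ti$hosp_id, window_start = ti$window_start,
                      risk = predict(m, ti), stringsAsFactors = FALSE)
    base <- baseline_predictions(cohorts$test, g)
    h <- cohorts$test$hospitalizations
    if (task == "low_risk") {
      aug_r <- suppressWarnings(aggregate_low_risk(aug, h, 48))
      base_r <- suppressWarnings(aggregate_low_risk(base, h, 48))
      out$count_aug <- count_low_risk_at_npv(npv_sweep(aug_r), 0.95)
      out$count_base <- count_low_risk_at_npv(npv_sweep(base_r), 0.95)
    } else {
      aug_r <- suppressWarnings(aggregate_high_risk(aug, h))
      base_r <- suppressWarnings(aggregate_high_risk(base, h))
      out$auroc_aug <- auroc(aug_r$aggregated_score, aug_r$label)
      out$auroc_base <- auroc(base_r$aggregated_score, base_r$label)
    }
  }
  out
}

.study_cache <- new.env(parent = emptyenv())

# Memoised: 5 seeds with image-specific outcome signal (both tasks), and 5
# seeds without it (high-risk only).
signal_study <- function(arm = c("with_signal", "no_signal")) {
  arm <- match.arg(arm)
  if (!is.null(.study_cache[[arm]])) return(.study_cache[[arm]])
  res <- if (arm == "with_signal") {
    lapply(1:5, run_signal_study_seed, w_image_only = 1)
  } else {
    lapply(1:5, run_signal_study_seed, w_image_only = 0, tasks = "high_risk")
  }
  .study_cache[[arm]] <- res
  res
}
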