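#' Configuration for the synthetic cohort simulator
#'
#' Builds and validates the parameter set of the synthetic hospitalization
#' simulator. The simulator emulates the data regime of an image-augmented
#' deterioration study: every patient carries a shared latent severity `s`
#' that is visible (noisily) to both the EHR deterioration index and the
#' radiograph model, plus an image-specific latent `u` that only the
#' radiograph model can see. Both latents shift the log-odds of clinical
#' deterioration, so image augmentation has real signal to recover whenever
#' `w_image_only > 0`.
#'
#' @param n_patients number of hospitalizations to simulate (one per patient).
#' @param cadence_index cadence of the deterioration-index stream in minutes;
#'   must be 15 (EDI-like) or 240 (4-hourly, MCURES-like).
#' @param horizon_max maximum follow-up used for score streams, hours.
#' @param p_deteriorate_base probability of deterioration at latent severity 0.
#' @param w_shared log-odds weight of the shared latent in the outcome model.
#' @param w_image_only log-odds weight of the image-specific latent.
#' @param index_noise_sd standard deviation of per-observation noise on the
#'   index stream (logit scale).
#' @param image_noise_sd standard deviation of per-radiograph noise (logit
#'   scale).
#' @param los_mean mean length of stay, hours.
#' @param xray_window window after admission in which the first radiograph is
#'   taken, hours.
#' @param xray_mean_count mean number of radiographs per hospitalization
#'   (geometric count model, minimum one).
#' @param p_on_oxygen probability that a hospitalization requires supplemental
#'   oxygen (those that do not are removed by the inclusion filters).
#' @param a0,a1 intercept and shared-latent loading of the index score model
#'   `plogis(a0 + a1 * s + noise)`.
#' @param b0,b1,b2 intercept, shared-latent and image-latent loadings of the
#'   image score model `plogis(b0 + b1 * s + b2 * u + noise)`.
#' @param event_type_probs named probabilities of the deterioration event type
#'   among deteriorators (metadata only; renormalized to sum to one).
#' @param seed integer seed; identical seed and configuration give a
#'   byte-identical cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [apply_inclusion_filters()]
#' @export
sim_config <- function(n_patients,
                       cadence_index = 15,
                       horizon_max = 120,
                       p_deteriorate_base = 0.3,
                       w_shared = 1,
                       w_image_only = 1,
                       index_noise_sd = 0.5,
                       image_noise_sd = 0.5,
                       los_mean = 120,
                       xray_window = 48,
                       xray_mean_count = 1.8,
                       p_on_oxygen = 0.97,
                       a0 = -1.4, a1 = 1,
                       b0 = -1.4, b1 = 1, b2 = 1,
                       event_type_probs = c(death = 0.013, MV = 0.029,
                                            HHFNC = 0.250, IV_pressors = 0.013),
                       seed = 1L) {
  check_scalar(n_patients, "n_patients", 1)
  if (!cadence_index %in% c(15, 240)) {
    stop("'cadence_index' must be 15 or 240 minutes", call. = FALSE)
  }
  check_scalar(horizon_max, "horizon_max", 8)
  check_probability(p_deteriorate_base, "p_deteriorate_base")
  check_scalar(w_shared, "w_shared")
  check_scalar(w_image_only, "w_image_only")
  check_scalar(index_noise_sd, "index_noise_sd", 0)
  check_scalar(image_noise_sd, "image_noise_sd", 0)
  check_scalar(los_mean, "los_mean", 8)
  check_scalar(xray_window, "xray_window", 0)
  check_scalar(xray_mean_count, "xray_mean_count", 1)
  check_probability(p_on_oxygen, "p_on_oxygen")
  for (nm in c("a0", "a1", "b0", "b1", "b2")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(seed, "seed")
  if (!is.numeric(event_type_probs) || length(event_type_probs) != 4L ||
      any(!is.finite(event_type_probs)) || any(event_type_probs < 0) ||
      sum(event_type_probs) <= 0 ||
      !setequal(names(event_type_probs),
                c("death", "MV", "HHFNC", "IV_pressors"))) {
    stop("'event_type_probs' must be 4 non-negative probabilities named ",
         "death, MV, HHFNC, IV_pressors", call. = FALSE)
  }
  cfg <- list(
    n_patients = as.integer(n_patients), cadence_index = cadence_index,
    horizon_max = horizon_max, p_deteriorate_base = p_deteriorate_base,
    w_shared = w_shared, w_image_only = w_image_only,
    index_noise_sd = index_noise_sd, image_noise_sd = image_noise_sd,
    los_mean = los_mean, xray_window = xray_window,
    xray_mean_count = xray_mean_count, p_on_oxygen = p_on_oxygen,
    a0 = a0, a1 = a1, b0 = b0, b1 = b1, b2 = b2,
    event_type_probs = event_type_probs /
      sum(event_type_probs),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_patients: %d, index cadence: %d min, seed: %d\n",
              x$n_patients, as.integer(x$cadence_index), x$seed))
  cat(sprintf("  outcome: logit(p) = logit(%.3f) + %.2f*s + %.2f*u\n",
              x$p_deteriorate_base, x$w_shared, x$w_image_only))
  cat(sprintf("  index score:  plogis(%.2f + %.2f*s + N(0, %.2f))\n",
              x$a0, x$a1, x$index_noise_sd))
  cat(sprintf("  image score:  plogis(%.2f + %.2f*s + %.2f*u + N(0, %.2f))\n",
              x$b0, x$b1, x$b2, x$image_noise_sd))
  invisible(x)
}

#' Simulate a synthetic hospitalization cohort
#'
#' Generates, per patient, a shared latent severity `s ~ N(0,1)` and an
#' image-specific latent `u ~ N(0,1)`; a deterioration indicator
#' `Bernoulli(plogis(qlogis(p_deteriorate_base) + w_shared*s +
#' w_image_only*u))`; an event time uniform on (4, min(length of stay,
#' horizon)); radiograph times with the first uniform on (0, `xray_window`);
#' a deterioration-index stream at the configured cadence with scores
#' `plogis(a0 + a1*s + noise)`; and one image score per radiograph,
#' `plogis(b0 + b1*s + b2*u + noise)`. Per-patient random substreams are
#' derived deterministically from the seed and patient index, so cohort
#' membership is order-independent.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `cohort` with three data frames:
#'   \describe{
#'     \item{hospitalizations}{`patient_id`, `hosp_id`, `admit_time` (always
#'       0), `exit_time`, `deterioration_time` (`NA` if none),
#'       `deterioration_type` (`NA` if none), `on_oxygen`.}
#'     \item{xrays}{`hosp_id`, `time`, `image_score`, one row per radiograph.}
#'     \item{index_scores}{`hosp_id`, `time`, `score`, one row per index
#'       observation.}
#'   }
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 50, seed = 1))
#' head(coh$hospitalizations)
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, as.list(cfg))
  n <- cfg$n_patients
  event_types <- names(cfg$event_type_probs)

  hosp_rows <- vector("list", n)
  xray_rows <- vector("list", n)
  index_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(derive_seed(cfg$seed, i))
    s <- stats::rnorm(1)
    u <- stats::rnorm(1)

    # length of stay: 4h floor plus gamma tail, mean = los_mean
    los <- 4 + stats::rgamma(1, shape = 2, scale = (cfg$los_mean - 4) / 2)

    p_det <- stats::plogis(stats::qlogis(cfg$p_deteriorate_base) +
                             cfg$w_shared * s + cfg$w_image_only * u)
    deteriorates <- stats::runif(1) < p_det
    det_time <- NA_real_
    det_type <- NA_character_
    if (deteriorates) {
      det_time <- stats::runif(1, 4, min(los, cfg$horizon_max))
      det_type <- sample(event_types, 1, prob = cfg$event_type_probs)
    }
    exit_time <- los
    on_oxygen <- stats::runif(1) < cfg$p_on_oxygen

    # radiographs: first uniform on (0, xray_window), count geometric
    n_xray <- 1L + stats::rgeom(1, prob = 1 / cfg$xray_mean_count)
    first_xray <- stats::runif(1, 0, cfg$xray_window)
    later <- if (n_xray > 1L) {
      stats::runif(n_xray - 1L, first_xray, max(first_xray + 1e-3,
                                                min(exit_time, cfg$horizon_max)))
    } else numeric(0)
    xray_times <- sort(unique(c(first_xray, later)))
    image_scores <- stats::plogis(cfg$b0 + cfg$b1 * s + cfg$b2 * u +
                                    stats::rnorm(length(xray_times),
                                                 sd = cfg$image_noise_sd))

    # index stream from admission to exit (capped at the horizon)
    step <- cfg$cadence_index / 60
    idx_times <- seq(0, min(exit_time, cfg$horizon_max), by = step)
    idx_scores <- stats::plogis(cfg$a0 + cfg$a1 * s +
                                  stats::rnorm(length(idx_times),
                                               sd = cfg$index_noise_sd))

    hid <- sprintf("H%06d", i)
    hosp_rows[[i]] <- data.frame(
      patient_id = sprintf("P%06d", i), hosp_id = hid,
      admit_time = 0, exit_time = exit_time,
      deterioration_time = det_time, deterioration_type = det_type,
      on_oxygen = on_oxygen, stringsAsFactors = FALSE
    )
    xray_rows[[i]] <- data.frame(hosp_id = hid, time = xray_times,
                                 image_score = image_scores,
                                 stringsAsFactors = FALSE)
    index_rows[[i]] <- data.frame(hosp_id = hid, time = idx_times,
                                  score = idx_scores,
                                  stringsAsFactors = FALSE)
  }

  cohort <- list(
    hospitalizations = do.call(rbind, hosp_rows),
    xrays = do.call(rbind, xray_rows),
    index_scores = do.call(rbind, index_rows)
  )
  rownames(cohort$hospitalizations) <- NULL
  rownames(cohort$xrays) <- NULL
  rownames(cohort$index_scores) <- NULL
  class(cohort) <- "cohort"
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  h <- x$hospitalizations
  cat(sprintf("Cohort: %d hospitalizations, %d radiographs, %d index scores\n",
              nrow(h), nrow(x$xrays), nrow(x$index_scores)))
  cat(sprintf("  deteriorated: %d (%.1f%%)\n",
              sum(!is.na(h$deterioration_time)),
              100 * mean(!is.na(h$deterioration_time))))
  invisible(x)
}

#' Apply the study inclusion/exclusion filters to a cohort
#'
#' Removes hospitalizations that (a) never required supplemental oxygen,
#' (b) had no chest radiograph within the first 48 hours, (c) deteriorated or
#' were discharged within four hours of presentation, or (d) deteriorated
#' before their first radiograph. Each excluded hospitalization is tagged with
#' the first matching reason in the order (a)-(d).
#'
#' @param cohort a `cohort` list as returned by [simulate_cohort()] or
#'   [read_cohort()].
#' @param xray_window_hours radiograph inclusion window, hours (default 48).
#' @param early_hours early deterioration/discharge exclusion window (default 4).
#' @return A list with elements `kept` (a filtered `cohort`) and `excluded`
#'   (data frame `hosp_id`, `reason` with reasons `no_oxygen`,
#'   `no_xray_in_window`, `early_event_or_discharge`,
#'   `deterioration_before_xray`).
#' @export
apply_inclusion_filters <- function(cohort, xray_window_hours = 48,
                                    early_hours = 4) {
  h <- cohort$hospitalizations
  xr <- cohort$xrays
  idx <- cohort$index_scores
  known <- h$hosp_id
  bad <- setdiff(unique(c(xr$hosp_id, idx$hosp_id)), known)
  if (length(bad) > 0) {
    stop("score stream references unknown hosp_id: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  first_xray <- vapply(known, function(id) {
    t <- xr$time[xr$hosp_id == id]
    if (length(t) == 0) Inf else min(t)
  }, numeric(1))

  det <- h$deterioration_time
  reason <- rep(NA_character_, nrow(h))
  r_a <- !h$on_oxygen
  r_b <- first_xray > xray_window_hours
  r_c <- ifelse(is.na(det), h$exit_time <= early_hours, det <= early_hours)
  r_d <- !is.na(det) & det < first_xray
  reason[r_d] <- "deterioration_before_xray"
  reason[r_c] <- "early_event_or_discharge"
  reason[r_b] <- "no_xray_in_window"
  reason[r_a] <- "no_oxygen"

  keep_ids <- h$hosp_id[is.na(reason)]
  kept <- structure(list(
    hospitalizations = h[is.na(reason), , drop = FALSE],
    xrays = xr[xr$hosp_id %in% keep_ids, , drop = FALSE],
    index_scores = idx[idx$hosp_id %in% keep_ids, , drop = FALSE]
  ), class = "cohort")
  rownames(kept$hospitalizations) <- NULL
  rownames(kept$xrays) <- NULL
  rownames(kept$index_scores) <- NULL

  excluded <- data.frame(hosp_id = h$hosp_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}
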