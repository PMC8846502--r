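## Patient-level evaluation protocol: low-risk identification by a negative-
## predictive-value sweep over mean aggregated risk, high-risk discrimination
## by AUROC on maximum risk, with percentile bootstrap confidence intervals
## resampled at the hospitalization level.

#' Aggregate window predictions into a low-risk patient score
#'
#' Computes, per hospitalization, the mean of all window-level predicted
#' risks with `window_start < upto` hours. Hospitalizations whose
#' deterioration occurs before `upto` are excluded from the output (they
#' cannot be low-risk discharge candidates at that point), as are
#' hospitalizations with no prediction window before `upto` (with a
#' warning). The label marks whether the hospitalization ever deteriorates.
#'
#' @param predictions data frame with `hosp_id`, `window_start`, `risk`.
#' @param hospitalizations data frame with `hosp_id` and
#'   `deterioration_time` (`NA` when the patient never deteriorates).
#' @param upto evaluation time in hours, one of 24, 32, 40, 48.
#' @return Data frame `hosp_id`, `aggregated_score`, `label` (class
#'   `patient_risk`), one row per retained hospitalization.
#' @export
aggregate_low_risk <- function(predictions, hospitalizations, upto = 48) {
  if (!upto %in% c(24, 32, 40, 48)) {
    stop("'upto' must be one of 24, 32, 40, 48 hours", call. = FALSE)
  }
  h <- hospitalizations
  det <- h$deterioration_time[match(predictions$hosp_id, h$hosp_id)]
  if (anyNA(match(predictions$hosp_id, h$hosp_id))) {
    stop("predictions reference unknown hosp_id", call. = FALSE)
  }
  keep <- predictions$window_start < upto & !(!is.na(det) & det < upto)
  pred <- predictions[keep, , drop = FALSE]

  eligible <- h$hosp_id[is.na(h$deterioration_time) |
                          h$deterioration_time >= upto]
  eligible <- intersect(eligible, unique(predictions$hosp_id))
  dropped <- setdiff(eligible, unique(pred$hosp_id))
  if (length(dropped) > 0) {
    warning(sprintf("%d hospitalization(s) had no prediction window before %g h and were excluded",
                    length(dropped), upto), call. = FALSE)
  }
  agg <- tapply(pred$risk, pred$hosp_id, mean)
  out <- data.frame(hosp_id = names(agg), aggregated_score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$label <- as.integer(!is.na(h$deterioration_time[match(out$hosp_id,
                                                            h$hosp_id)]))
  out <- out[order(out$hosp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("patient_risk", "data.frame")
  out
}

#' Aggregate window predictions into a high-risk patient score
#'
#' Per-hospitalization maximum of all predicted risks (windows at and
#' immediately before a deterioration event are already censored upstream by
#' [make_instances()]). The label marks deterioration within the first five
#' days (120 h).
#'
#' @inheritParams aggregate_low_risk
#' @param horizon_hours label horizon (default 120).
#' @return Data frame `hosp_id`, `aggregated_score`, `label` (class
#'   `patient_risk`).
#' @export
aggregate_high_risk <- function(predictions, hospitalizations,
                                horizon_hours = 120) {
  h <- hospitalizations
  if (anyNA(match(predictions$hosp_id, h$hosp_id))) {
    stop("predictions reference unknown hosp_id", call. = FALSE)
  }
  dropped <- setdiff(h$hosp_id, unique(predictions$hosp_id))
  if (length(dropped) > 0) {
    warning(sprintf("%d hospitalization(s) had no predictions and were excluded",
                    length(dropped)), call. = FALSE)
  }
  agg <- tapply(predictions$risk, predictions$hosp_id, max)
  out <- data.frame(hosp_id = names(agg), aggregated_score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  det <- h$deterioration_time[match(out$hosp_id, h$hosp_id)]
  out$label <- as.integer(!is.na(det) & det <= horizon_hours)
  out <- out[order(out$hosp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("patient_risk", "data.frame")
  out
}

#' Negative-predictive-value sweep
#'
#' Sorts hospitalizations by ascending aggregated risk (ties broken by
#' `hosp_id` for determinism) and, for each threshold flagging the `k`
#' lowest-risk patients, computes the negative predictive value — the
#' fraction of flagged patients who never deteriorate — and the fraction of
#' the cohort flagged.
#'
#' @param risks a `patient_risk` data frame (`hosp_id`, `aggregated_score`,
#'   `label`).
#' @return Data frame of class `npv_curve`: `k`, `fraction_flagged`, `npv`.
#' @export
npv_sweep <- function(risks) {
  if (nrow(risks) < 1) stop("need at least one patient", call. = FALSE)
  o <- order(risks$aggregated_score, risks$hosp_id)
  lab <- risks$label[o]
  k <- seq_along(lab)
  out <- data.frame(k = k, fraction_flagged = k / length(lab),
                    npv = cumsum(lab == 0) / k)
  class(out) <- c("npv_curve", "data.frame")
  out
}

#' Number of low-risk patients identifiable at a target NPV
#'
#' The largest number `k` of flagged lowest-risk patients whose negative
#' predictive value still meets the target (0 if no `k` does). Because NPV
#' is not monotone in `k`, `strict_prefix = TRUE` instead returns the largest
#' `k` such that the NPV never dips below the target anywhere in `1..k`.
#'
#' @param curve an `npv_curve` from [npv_sweep()].
#' @param target NPV target in (0, 1].
#' @param strict_prefix use the conservative prefix rule.
#' @return Integer count of patients flagged low-risk.
#' @export
count_low_risk_at_npv <- function(curve, target, strict_prefix = FALSE) {
  if (!is.numeric(target) || target <= 0 || target > 1) {
    stop("'target' must be in (0, 1]", call. = FALSE)
  }
  ok <- curve$npv >= target
  if (strict_prefix) ok <- cumprod(ok) > 0
  if (!any(ok)) return(0L)
  as.integer(max(curve$k[ok]))
}

#' Area under the receiver operating characteristic curve
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' receives a higher score than a randomly chosen negative, counting ties as
#' one half. Computed from midranks.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (both classes must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specificity at an anchored sensitivity
#'
#' Chooses the highest decision threshold (positive iff score >= threshold)
#' whose sensitivity is at least `sens_target`, and reports the specificity
#' at that threshold.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (both classes must be present).
#' @param sens_target sensitivity floor (default 0.8).
#' @return Specificity in `[0, 1]`.
#' @export
specificity_at_sensitivity <- function(scores, labels, sens_target = 0.8) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("requires both classes", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  for (t in thr) {
    sens <- sum(scores >= t & labels == 1) / n1
    if (sens >= sens_target) {
      return(sum(scores < t & labels == 0) / n0)
    }
  }
  0 # sensitivity target unreachable even flagging everyone (cannot happen)
}

#' Percentile bootstrap confidence interval at the hospitalization level
#'
#' Resamples hospitalizations (rows of `risks`) with replacement `n_boot`
#' times and returns the 2.5th and 97.5th percentiles of the metric.
#' Resamples on which the metric is not computable (e.g. a single outcome
#' class for AUROC) are redrawn; if more than 10% of draws fail, an error is
#' raised.
#'
#' @param risks a `patient_risk` data frame.
#' @param metric function taking (`scores`, `labels`) and returning a single
#'   number, e.g. [auroc()].
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(risks, metric, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  n <- nrow(risks)
  set.seed(derive_seed(seed, 141421L))
  vals <- numeric(n_boot)
  redrawn <- 0L
  max_fail <- ceiling(0.1 * n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      ii <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric(risks$aggregated_score[ii], risks$label[ii]),
                    error = function(e) NA_real_)
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
      if (redrawn > max_fail) {
        stop(sprintf("metric failed on more than 10%% of resamples (%d failures)",
                     redrawn), call. = FALSE)
      }
    }
    vals[b] <- v
  }
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(stats::setNames(ci, c("lower", "upper")), n_redrawn = redrawn)
}

#' Exponentially weighted moving-average smoothing of an NPV curve
#'
#' Standard exponential smoothing of the NPV values over ascending `k`
#' (`y[1] = npv[1]`, `y[k] = alpha * npv[k] + (1 - alpha) * y[k-1]`).
#' Intended for plotting only; threshold counts always use the raw curve.
#'
#' @param curve an `npv_curve`.
#' @param alpha smoothing weight in (0, 1]; 1 is the identity.
#' @return The curve with `npv` replaced by its smoothed values.
#' @export
ewma_smooth <- function(curve, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be in (0, 1]", call. = FALSE)
  }
  y <- curve$npv
  for (i in seq_along(y)[-1]) {
    y[i] <- alpha * curve$npv[i] + (1 - alpha) * y[i - 1]
  }
  out <- curve
  out$npv <- y
  out
}

#' Plot an NPV sweep curve
#'
#' Fraction of patients flagged low-risk against the negative predictive
#' value at that flagging fraction, optionally smoothed for display.
#'
#' @param x an `npv_curve`.
#' @param alpha optional smoothing weight passed to [ewma_smooth()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.npv_curve <- function(x, alpha = NULL, ...) {
  y <- if (is.null(alpha)) x else ewma_smooth(x, alpha)
  graphics::plot(y$fraction_flagged, y$npv, type = "l",
                 xlab = "fraction flagged low-risk",
                 ylab = "negative predictive value", ylim = c(0, 1), ...)
  invisible(x)
}
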