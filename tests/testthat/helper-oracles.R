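# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/rank-based code paths: metrics are recomputed per subset / per
# pair by direct enumeration.

# NPV of flagging the k lowest-risk patients, recomputed from scratch per k.
oracle_npv_curve <- function(scores, labels, ids = as.character(seq_along(scores))) {
  n <- length(scores)
  npv <- numeric(n)
  for (k in seq_len(n)) {
    remaining <- seq_len(n)
    flagged <- integer(0)
    for (j in seq_len(k)) { # repeated selection of the minimum (score, id)
      best <- remaining[1]
      for (i in remaining) {
        if (scores[i] < scores[best] ||
            (scores[i] == scores[best] && ids[i] < ids[best])) best <- i
      }
      flagged <- c(flagged, best)
      remaining <- setdiff(remaining, best)
    }
    npv[k] <- sum(labels[flagged] == 0) / k
  }
  data.frame(k = seq_len(n), fraction_flagged = seq_len(n) / n, npv = npv)
}

# Largest k meeting the target, scanning the enumerated curve from the top.
oracle_count_at_npv <- function(curve, target) {
  for (k in rev(curve$k)) {
    if (curve$npv[curve$k == k] >= target) return(k)
  }
  0L
}

# All-pairs Mann-Whitney AUROC, ties counted one half.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Specificity at the highest threshold reaching the sensitivity target,
# enumerating every candidate threshold.
oracle_spec_at_sens <- function(scores, labels, sens_target) {
  best_spec <- NA_real_
  best_thr <- -Inf
  for (t in unique(scores)) {
    sens <- mean(scores[labels == 1] >= t)
    if (sens >= sens_target && t > best_thr) {
      best_thr <- t
      best_spec <- mean(scores[labels == 0] < t)
    }
  }
  best_spec
}
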