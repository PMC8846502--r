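test_that("NPV sweep matches hand-enumerated values", {
  risks <- data.frame(hosp_id = c("a", "b", "c", "d"),
                      aggregated_score = c(0.1, 0.2, 0.3, 0.4),
                      label = c(0L, 0L, 1L, 1L))
  curve <- npv_sweep(risks)
  expect_equal(curve$npv, c(1, 1, 2 / 3, 1 / 2))
  expect_equal(curve$fraction_flagged, (1:4) / 4)
  expect_equal(count_low_risk_at_npv(curve, 0.95), 2L)
  expect_equal(count_low_risk_at_npv(curve, 0.6), 3L)

  all0 <- npv_sweep(transform(risks, label = 0L))
  expect_true(all(all0$npv == 1))
  all1 <- npv_sweep(transform(risks, label = 1L))
  expect_true(all(all1$npv == 0))
  expect_equal(count_low_risk_at_npv(all1, 0.5), 0L)
})

test_that("NPV sweep and threshold count agree with brute force on random cohorts", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    scores <- round(runif(n), sample(1:2, 1)) # coarse rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    ids <- sample(sprintf("H%02d", 1:n))
    risks <- data.frame(hosp_id = ids, aggregated_score = scores,
                        label = labels, stringsAsFactors = FALSE)
    curve <- npv_sweep(risks)
    oracle <- oracle_npv_curve(scores, labels, ids)
    expect_equal(curve$npv, oracle$npv)
    target <- runif(1, 0.3, 1)
    expect_equal(count_low_risk_at_npv(curve, target),
                 oracle_count_at_npv(oracle, target))
  }
})

test_that("the strict-prefix count never exceeds the plain count", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    risks <- data.frame(hosp_id = sprintf("H%02d", 1:n),
                        aggregated_score = runif(n),
                        label = rbinom(n, 1, 0.3))
    curve <- npv_sweep(risks)
    for (target in c(0.5, 0.8, 0.95)) {
      expect_lte(count_low_risk_at_npv(curve, target, strict_prefix = TRUE),
                 count_low_risk_at_npv(curve, target))
    }
  }
})

test_that("threshold count is non-increasing in the NPV target", {
  set.seed(7)
  risks <- data.frame(hosp_id = sprintf("H%02d", 1:30),
                      aggregated_score = runif(30),
                      label = rbinom(30, 1, 0.3))
  curve <- npv_sweep(risks)
  counts <- vapply(seq(0.05, 1, by = 0.05),
                   function(t) count_low_risk_at_npv(curve, t), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("AUROC matches hand-computed and brute-force values", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(202)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("low-risk aggregation means windows before the cutoff and excludes early events", {
  preds <- data.frame(
    hosp_id = c("a", "a", "b", "c", "c"),
    window_start = c(8, 12, 20, 8, 44),
    risk = c(0.2, 0.4, 0.8, 0.3, 0.9), stringsAsFactors = FALSE)
  h <- rbind(make_hosp("a"), make_hosp("b", deterioration_time = 40),
             make_hosp("c", deterioration_time = 60))
  out <- aggregate_low_risk(preds, h, upto = 48)
  # b deteriorated at 40 h < 48 h: excluded from the low-risk pool
  expect_identical(out$hosp_id, c("a", "c"))
  expect_equal(out$aggregated_score, c(0.3, 0.6))
  expect_equal(out$label, c(0L, 1L))
  # at 24 h only windows before 24 contribute (prefix of the 48 h windows)
  out24 <- aggregate_low_risk(preds, h, upto = 24)
  expect_equal(out24$aggregated_score[out24$hosp_id == "c"], 0.3)
  # singleton mean passes through
  expect_equal(out24$aggregated_score[out24$hosp_id == "b"], 0.8)
  expect_error(aggregate_low_risk(preds, h, upto = 30), "24, 32, 40, 48")
})

test_that("high-risk aggregation takes the per-hospitalization maximum", {
  preds <- data.frame(hosp_id = c("a", "a", "a", "b"),
                      window_start = c(8, 12, 16, 8),
                      risk = c(0.1, 0.9, 0.3, 0.5), stringsAsFactors = FALSE)
  h <- rbind(make_hosp("a", deterioration_time = 30), make_hosp("b"))
  out <- aggregate_high_risk(preds, h)
  expect_equal(out$aggregated_score, c(0.9, 0.5))
  expect_equal(out$label, c(1L, 0L))
  # hospitalizations with no predictions are excluded with a warning
  h3 <- rbind(h, make_hosp("c"))
  expect_warning(out3 <- aggregate_high_risk(preds, h3), "no predictions")
  expect_identical(out3$hosp_id, c("a", "b"))
})

test_that("specificity at anchored sensitivity matches enumeration", {
  # perfect classifier: specificity 1 at any attainable sensitivity
  expect_equal(specificity_at_sensitivity(c(0.9, 0.8, 0.2, 0.1),
                                          c(1, 1, 0, 0), 0.8), 1)
  # five positives above every negative
  sc <- c(runif(5, 0.8, 1), runif(20, 0, 0.5))
  lb <- c(rep(1, 5), rep(0, 20))
  expect_equal(specificity_at_sensitivity(sc, lb, 0.8), 1)
  # random scores: specificity ~= 1 - sensitivity target
  set.seed(55)
  n <- 10000
  sc <- runif(n)
  lb <- rbinom(n, 1, 0.5)
  expect_lt(abs(specificity_at_sensitivity(sc, lb, 0.8) - 0.2), 3 / sqrt(n))
  # agreement with the enumeration oracle on small tied sets
  set.seed(56)
  for (rep in 1:100) {
    m <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.2), m, replace = TRUE)
    lb <- c(0, 1, rbinom(m - 2, 1, 0.5))
    expect_equal(specificity_at_sensitivity(sc, lb, 0.8),
                 oracle_spec_at_sens(sc, lb, 0.8))
  }
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  set.seed(77)
  risks <- data.frame(hosp_id = sprintf("H%03d", 1:120),
                      aggregated_score = runif(120),
                      label = rbinom(120, 1, 0.4))
  ci1 <- bootstrap_ci(risks, auroc, n_boot = 300, seed = 42)
  ci2 <- bootstrap_ci(risks, auroc, n_boot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], ci1[["upper"]])
  # constant metric gives a zero-width interval
  const <- function(scores, labels) 0.7
  ci <- bootstrap_ci(risks, const, n_boot = 100, seed = 1)
  expect_equal(as.numeric(ci), c(0.7, 0.7))
  # hopeless metric errors out once >10% of resamples fail
  broken <- function(scores, labels) stop("nope")
  expect_error(bootstrap_ci(risks, broken, n_boot = 100, seed = 1),
               "10%")
})

test_that("EWMA smoothing follows the closed-form recursion", {
  curve <- npv_sweep(data.frame(hosp_id = sprintf("H%02d", 1:10),
                                aggregated_score = (1:10) / 10,
                                label = rep(c(0L, 1L), 5)))
  expect_equal(ewma_smooth(curve, 1), curve)
  const <- curve
  const$npv <- rep(0.8, 10)
  expect_equal(ewma_smooth(const, 0.3)$npv, rep(0.8, 10))
  # alternating 0/1 values converge to the 2/3, 1/3 alternation
  alt <- curve
  alt$npv <- rep(c(1, 0), 20)[1:10]
  sm <- ewma_smooth(alt, 0.5)
  # closed form: y[k] = 0.5*x[k] + 0.5*y[k-1] with x alternating
  y <- alt$npv[1]
  for (i in 2:10) y[i] <- 0.5 * alt$npv[i] + 0.5 * y[i - 1]
  expect_equal(sm$npv, y)
  expect_lt(abs(sm$npv[9] - 2 / 3), 0.01)
  expect_lt(abs(sm$npv[10] - 1 / 3), 0.01)
  expect_error(ewma_smooth(curve, 0), "alpha")
})
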