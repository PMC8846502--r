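test_that("simulator is deterministic and order-independent per patient", {
  cfg <- sim_config(n_patients = 40, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  # the same patient index yields the same draws regardless of cohort size
  small <- simulate_cohort(sim_config(n_patients = 10, seed = 7))
  expect_identical(small$hospitalizations,
                   a$hospitalizations[1:10, , drop = FALSE])
})

test_that("latent weights of zero leave the base deterioration rate", {
  coh <- simulate_cohort(sim_config(n_patients = 10000, w_shared = 0,
                                    w_image_only = 0,
                                    p_deteriorate_base = 0.3,
                                    cadence_index = 240, seed = 3))
  frac <- mean(!is.na(coh$hospitalizations$deterioration_time))
  expect_lt(abs(frac - 0.30), 0.015)
})

test_that("noise-free index scores are constant and equal sigmoid(a0 + s)", {
  cfg <- sim_config(n_patients = 25, index_noise_sd = 0, a0 = -1, a1 = 1,
                    cadence_index = 240, seed = 9)
  coh <- simulate_cohort(cfg)
  per <- split(coh$index_scores$score, coh$index_scores$hosp_id)
  for (sc in per) expect_equal(max(sc) - min(sc), 0)
  # back out the shared latent and check it is standard-normal-ish across
  # patients (sanity on the score model, not a distributional test)
  s <- qlogis(vapply(per, function(x) x[1], numeric(1))) + 1
  expect_true(all(is.finite(s)))
})

test_that("emitted values respect the stated ranges", {
  coh <- simulate_cohort(sim_config(n_patients = 400, seed = 21))
  h <- coh$hospitalizations
  expect_true(all(coh$xrays$image_score >= 0 & coh$xrays$image_score <= 1))
  expect_true(all(coh$index_scores$score >= 0 & coh$index_scores$score <= 1))
  det <- h$deterioration_time
  expect_true(all(is.na(det) | (det > 4 & det <= h$exit_time)))
  expect_true(all(h$exit_time > 0))
  # radiograph times ascend within each hospitalization
  for (t in split(coh$xrays$time, coh$xrays$hosp_id)) {
    expect_false(is.unsorted(t, strictly = TRUE))
  }
})

test_that("image-specific latent correlates with the outcome iff weighted", {
  # reconstruct u from a noise-free image model to probe the outcome link
  probe <- function(w_u, seed) {
    cfg <- sim_config(n_patients = 10000, w_image_only = w_u,
                      image_noise_sd = 0, index_noise_sd = 0, a1 = 0, b1 = 0,
                      b0 = 0, b2 = 1, cadence_index = 240, seed = seed)
    coh <- simulate_cohort(cfg)
    first <- coh$xrays[!duplicated(coh$xrays$hosp_id), ]
    u <- qlogis(first$image_score)
    y <- as.integer(!is.na(coh$hospitalizations$deterioration_time[
      match(first$hosp_id, coh$hospitalizations$hosp_id)]))
    cor(u, y)
  }
  expect_gt(probe(1, seed = 4), 0.1)
  expect_lt(abs(probe(0, seed = 4)), 3 / sqrt(10000))
})

test_that("non-finite or invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 10, w_shared = NaN), "finite")
  expect_error(sim_config(n_patients = 10, index_noise_sd = -1), "must be in")
  expect_error(sim_config(n_patients = 10, cadence_index = 60), "15 or 240")
  expect_error(sim_config(n_patients = 10, p_deteriorate_base = 1.2),
               "must be in")
})

test_that("inclusion filters exclude by the first matching reason", {
  # hand-built cohort: one clean admission plus one violation of each rule
  mk <- function(id, ...) make_hosp(hosp_id = id, ...)
  h <- rbind(
    mk("A"),                                   # clean
    mk("B", on_oxygen = FALSE),                # (a)
    mk("C"),                                   # (b): first x-ray at 50 h
    mk("D", deterioration_time = 3),           # (c): early deterioration
    mk("E", exit_time = 3.5),                  # (c): early discharge
    mk("F", deterioration_time = 8)            # (d): x-ray at 10 h
  )
  xr <- data.frame(
    hosp_id = c("A", "B", "C", "D", "E", "F"),
    time = c(6, 6, 50, 1, 1, 10), image_score = 0.5,
    stringsAsFactors = FALSE
  )
  idx <- do.call(rbind, lapply(h$hosp_id, flat_index, upto = 4))
  res <- apply_inclusion_filters(make_cohort(h, xr, idx))

  expect_identical(res$kept$hospitalizations$hosp_id, "A")
  got <- setNames(res$excluded$reason, res$excluded$hosp_id)
  expect_identical(got[["B"]], "no_oxygen")
  expect_identical(got[["C"]], "no_xray_in_window")
  expect_identical(got[["D"]], "early_event_or_discharge")
  expect_identical(got[["E"]], "early_event_or_discharge")
  expect_identical(got[["F"]], "deterioration_before_xray")
  # first-matching-reason order: no oxygen AND late x-ray tags as no_oxygen
  h2 <- mk("G", on_oxygen = FALSE)
  xr2 <- data.frame(hosp_id = "G", time = 50, image_score = 0.5)
  res2 <- apply_inclusion_filters(make_cohort(h2, xr2, flat_index("G", 4)))
  expect_identical(res2$excluded$reason, "no_oxygen")
})

test_that("planting k violations per rule yields exactly k exclusions each", {
  k <- 3L
  clean <- lapply(sprintf("K%02d", 1:8), make_hosp)
  viol <- c(
    lapply(sprintf("A%02d", 1:k), make_hosp, on_oxygen = FALSE),
    lapply(sprintf("B%02d", 1:k), make_hosp),                   # x-ray late
    lapply(sprintf("C%02d", 1:k), make_hosp, deterioration_time = 2),
    lapply(sprintf("D%02d", 1:k), make_hosp, deterioration_time = 6)
  )
  h <- do.call(rbind, c(clean, viol))
  xr <- data.frame(hosp_id = h$hosp_id,
                   time = ifelse(startsWith(h$hosp_id, "B"), 60,
                          ifelse(startsWith(h$hosp_id, "D"), 10, 5)),
                   image_score = 0.4, stringsAsFactors = FALSE)
  idx <- do.call(rbind, lapply(h$hosp_id, flat_index, upto = 8))
  res <- apply_inclusion_filters(make_cohort(h, xr, idx))
  tally <- table(res$excluded$reason)
  expect_equal(unname(tally[c("no_oxygen", "no_xray_in_window",
                              "early_event_or_discharge",
                              "deterioration_before_xray")]),
               rep(k, 4), ignore_attr = TRUE)
  expect_equal(nrow(res$kept$hospitalizations) + nrow(res$excluded), nrow(h))
})

test_that("streams referencing unknown hospitalizations are an error", {
  h <- make_hosp("A")
  xr <- data.frame(hosp_id = c("A", "ZZ"), time = c(5, 5), image_score = 0.5)
  expect_error(apply_inclusion_filters(make_cohort(h, xr, flat_index("A", 8))),
               "unknown hosp_id")
})
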