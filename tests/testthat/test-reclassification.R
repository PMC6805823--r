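# all PTP tests use toy coefficients, not the shipped defaults
toy_ptp <- function(intercept = 0, age = 0, male = 0,
                    typical = 0, atypical = 0, non_specific = 0, none = 0) {
  ptp_model(intercept = intercept, age = age, male = male,
            symptom = c(typical = typical, atypical = atypical,
                        non_specific = non_specific, none = none))
}

test_that("pre-test probability is the inverse logit of the linear predictor", {
  expect_equal(compute_ptp(toy_ptp(), 50, "female", "typical"), 0.5)
  expect_equal(compute_ptp(toy_ptp(intercept = -2), 70, "male", "atypical"),
               1 / (1 + exp(2)), tolerance = 1e-12)
  # strictly increasing in age for a positive age coefficient
  p <- compute_ptp(toy_ptp(age = 0.05), c(40, 50, 60, 70), "male", "typical")
  expect_true(all(diff(p) > 0))
  expect_error(compute_ptp(toy_ptp(), 50, "male", "chest"), "unknown symptom")
})

test_that("PTP bands use 0.15/0.85 edges inclusive to intermediate", {
  expect_equal(as.character(ptp_band(0.149)), "low")
  expect_equal(as.character(ptp_band(0.15)), "intermediate")
  expect_equal(as.character(ptp_band(0.85)), "intermediate")
  expect_equal(as.character(ptp_band(0.86)), "high")
  expect_true(is.ordered(ptp_band(0.5)))
  expect_error(ptp_band(1.2), "\\[0, 1\\]")
  expect_error(ptp_band(-0.1), "\\[0, 1\\]")
})

test_that("disease levels follow the angiographic coding rules", {
  expect_equal(assign_disease_level(0, 0, NA), "non_cad")
  expect_equal(assign_disease_level(120, 30, NA), "mild_cad")
  expect_equal(assign_disease_level(400, 70, 60), "significant_cad")
  # CAG is decisive even with a zero CACS
  expect_equal(assign_disease_level(0, 0, 55), "significant_cad")
  # insignificant stenosis with zero calcium is still mild
  expect_equal(assign_disease_level(0, 30, NA), "mild_cad")
  expect_warning(out <- assign_disease_level(NA, NA, NA), "unclassifiable")
  expect_true(is.na(out))
})

test_that("reclassification moves only intermediate patients with score <= 20", {
  expect_equal(as.character(reclassify(ptp_band(0.5), 18)), "low")
  expect_equal(as.character(reclassify(ptp_band(0.5), 20)), "low")
  expect_equal(as.character(reclassify(ptp_band(0.5), 21)), "intermediate")
  expect_equal(as.character(reclassify(ptp_band(0.1), 95)), "low")
  expect_equal(as.character(reclassify(ptp_band(0.9), 3)), "high")
})

test_that("reclassification table matches hand enumeration on a toy cohort", {
  toy <- data.frame(
    patient_id = paste0("P", 1:4),
    ptp = c(0.5, 0.5, 0.5, 0.1),
    cad_score = c(10L, 10L, 30L, 50L),
    disease_level = c("significant_cad", "non_cad", "non_cad", "non_cad"))
  r <- reclassification_table(toy)
  expect_equal(unname(r$post["low"]), 3)
  expect_equal(r$down_events, 1)
  expect_equal(r$down_nonevents, 1)
  expect_equal(r$nri, -1 / 1 + 1 / 3)

  # no intermediate patient below the threshold: pre = post
  toy2 <- toy; toy2$cad_score <- c(30L, 40L, 30L, 50L)
  r2 <- reclassification_table(toy2)
  expect_equal(as.numeric(r2$pre), as.numeric(r2$post))

  # all low: identity table
  toy3 <- toy; toy3$ptp <- rep(0.05, 4)
  r3 <- reclassification_table(toy3)
  expect_equal(unname(r3$pre["low"]), 4)
  expect_equal(as.numeric(r3$pre), as.numeric(r3$post))

  toy4 <- toy; toy4$cad_score[2] <- NA
  expect_error(reclassification_table(toy4), "missing")
})

test_that("reclassification never moves anyone upward", {
  set.seed(12)
  for (i in 1:20) {
    n <- 200
    co <- data.frame(patient_id = paste0("P", 1:n),
                     ptp = stats::runif(n),
                     cad_score = sample(0:99, n, replace = TRUE),
                     disease_level = sample(disease_levels(), n, TRUE))
    r <- reclassification_table(co)
    expect_gte(unname(r$post["low"]), unname(r$pre["low"]))
    expect_equal(unname(r$post["high"]), unname(r$pre["high"]))
    expect_lte(r$down_events, r$events)
    expect_true(r$nri >= -2 && r$nri <= 2)
    # permuting patients leaves every count unchanged
    rp <- reclassification_table(co[sample.int(n), ])
    expect_equal(as.numeric(rp$pre), as.numeric(r$pre))
    expect_equal(rp$nri, r$nri)
  }
})

test_that("the NRI decomposes into event and non-event terms", {
  # no movement
  expect_equal(reclassification_result(0, 0, 50, 100)$nri, 0)
  # every non-event moved down, no events moved
  expect_equal(reclassification_result(0, 100, 50, 100)$nri, 1)
  r <- reclassification_result(down_events = 21, down_nonevents = 451,
                               events = 211, nonevents = 1462)
  expect_equal(r$nri, -21 / 211 + 451 / 1462, tolerance = 1e-12)
  expect_error(reclassification_result(0, 0, 0, 100), "at least one event")
})
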