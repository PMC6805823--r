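test_that("logistic fusion handles degenerate predictors", {
  set.seed(5)
  n <- 400
  y <- rep(c(0, 1), n / 2)
  expect_warning(
    m <- fit_logistic(rep(1, n), rnorm(n, 58, 8), rbinom(n, 1, 0.5),
                      rbinom(n, 1, 0.6), y),
    "constant predictor")
  expect_equal(unname(m$coefficients["acoustic"]), 0)
  # all-zero covariates, balanced labels: intercept-only fit near 0
  expect_warning(m0 <- fit_logistic(rep(0, n), rep(0, n), rep(0, n),
                                    rep(0, n), y))
  expect_lt(abs(m0$coefficients["(Intercept)"]), 0.05)
  expect_error(fit_logistic(rnorm(10), rnorm(10), rbinom(10, 1, 0.5),
                            rbinom(10, 1, 0.5), rep(1, 10)), "both classes")
})

test_that("perfect separation falls back to a flagged ridge fit", {
  set.seed(6)
  n <- 100
  acoustic <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  y <- rep(c(0, 1), each = n / 2)
  m <- fit_logistic(acoustic, rnorm(n, 58, 8), rbinom(n, 1, 0.5),
                    rbinom(n, 1, 0.6), y)
  expect_true(m$ridged)
  expect_true(all(is.finite(m$coefficients)))
  expect_gt(m$coefficients["acoustic"], 0)
})

test_that("scale calibration maps the 10th CAD percentile to the threshold", {
  # 100 equally spaced CAD linear predictors: exactly 90 map above 20
  lp <- seq(0, 99)
  an <- calibrate_scale(lp, rep(TRUE, 100))
  score <- pmin(pmax(floor(score_map(lp, an) + 0.5), 0), 99)
  expect_equal(sum(score > 20), 90)
  # the anchor itself still displays the threshold value
  q10 <- stats::quantile(lp, 0.1, type = 7, names = FALSE)
  expect_equal(floor(score_map(q10, an) + 0.5), 20)
  expect_gt(an$slope, 0)
  expect_error(calibrate_scale(rep(1, 100), rep(TRUE, 100)), "degenerate")
  expect_error(calibrate_scale(rnorm(30), rep(c(TRUE, FALSE), c(5, 25))),
               "at least 20")
})

test_that("integer scores round, clamp and preserve order", {
  lda <- structure(list(weights = c(1, rep(0, 7)), intercept = 0,
                        shrinkage = 0), class = "lda_weights")
  lg <- structure(list(coefficients = c("(Intercept)" = 0, acoustic = 1,
                                        age = 0, male = 0, hypertension = 0),
                       dropped = character(), ridged = FALSE,
                       converged = TRUE, se = NULL), class = "cad_logistic")
  an <- structure(list(slope = 2, offset = 10), class = "score_anchors")
  model <- cad_score_model(lda, lg, an)
  sc <- function(a) compute_cad_score(model, age = 60, sex = "male",
                                      hypertension = TRUE, acoustic = a)
  expect_equal(sc(5), 20L)        # 2*5 + 10
  expect_equal(sc(1e6), 99L)      # clamp high
  expect_equal(sc(-1e6), 0L)      # clamp low
  expect_true(sc(6) >= sc(5))     # monotone in the acoustic score
  # rank preservation on random linear predictors
  set.seed(8)
  lp <- rnorm(50)
  s <- score_map(lp, an)
  expect_identical(order(lp), order(s))
  expect_error(compute_cad_score(model, age = NA, sex = "male",
                                 hypertension = TRUE, acoustic = 1),
               "missing clinical information")
})

test_that("scores dichotomise at 20 (20 itself is normal)", {
  expect_equal(classify_score(20), "normal")
  expect_equal(classify_score(21), "abnormal")
  expect_equal(classify_score(0), "normal")
  expect_equal(classify_score(c(19, 20, 21, 99)),
               c("normal", "normal", "abnormal", "abnormal"))
  expect_error(classify_score(100), "0, 99")
  expect_error(classify_score(-1), "0, 99")
})

test_that("model JSON serialisation round-trips", {
  lda <- structure(list(weights = stats::setNames(rnorm(8),
                                                  acoustic_feature_names()),
                        intercept = 0.3, shrinkage = 0.1),
                   class = "lda_weights")
  lg <- structure(list(coefficients = c("(Intercept)" = -7, acoustic = 1.2,
                                        age = 0.05, male = 0.6,
                                        hypertension = 0.4),
                       dropped = character(), ridged = FALSE,
                       converged = TRUE, se = NULL), class = "cad_logistic")
  an <- structure(list(slope = 11.2, offset = 47.5), class = "score_anchors")
  model <- cad_score_model(lda, lg, an)
  f <- tempfile(fileext = ".json")
  write_cad_model(model, f)
  back <- read_cad_model(f)
  expect_equal(back$lda$weights, model$lda$weights)
  expect_equal(back$logistic$coefficients, model$logistic$coefficients)
  expect_equal(back$anchors$slope, model$anchors$slope)
  expect_equal(back$threshold, 20L)
})
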