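#' Logistic fusion of the acoustic score with clinical covariates
#'
#' Maximum-likelihood logistic regression of the significant-CAD indicator
#' on four predictors: acoustic score, age (years), sex (male = 1) and
#' hypertension (1 = systolic blood pressure >= 140 mmHg or current
#' antihypertensive treatment). Constant predictors are dropped with a
#' warning (their coefficient is not identifiable). Under perfect
#' separation the fit falls back to a ridge-penalised estimate
#' (penalty 1e-4), flagged in the result.
#'
#' @param acoustic numeric acoustic scores.
#' @param age numeric, years.
#' @param sex `"male"`/`"female"`, or 0/1 with male = 1, or logical.
#' @param hypertension logical or 0/1.
#' @param labels logical (or 0/1) significant-CAD indicator.
#' @return object of class `cad_logistic`: list with `coefficients` (named,
#'   full predictor set with 0 for dropped terms), `dropped`, `ridged`,
#'   `converged`.
#' @export
fit_logistic <- function(acoustic, age, sex, hypertension, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  male <- encode_male(sex)
  X <- cbind(acoustic = acoustic, age = age, male = male,
             hypertension = as.numeric(hypertension))
  if (nrow(X) != length(y)) stop("length mismatch", call. = FALSE)
  const <- apply(X, 2, function(v) stats::var(v) < 1e-12)
  if (any(const))
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "),
            " (coefficient not identifiable)", call. = FALSE)
  Xf <- X[, !const, drop = FALSE]
  dat <- if (ncol(Xf) > 0) data.frame(y = y, Xf) else data.frame(y = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  ridged <- FALSE
  if (sep || !fit$converged || any(abs(stats::coef(fit)[-1]) > 50)) {
    # (quasi-)separation: ridge-penalised refit keeps coefficients finite
    gf <- glmnet::glmnet(Xf, y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    cf <- as.numeric(stats::coef(gf))
    names(cf) <- rownames(stats::coef(gf))
    ridged <- TRUE
  } else {
    cf <- stats::coef(fit)
    names(cf)[1] <- "(Intercept)"
  }
  full <- c("(Intercept)", colnames(X))
  coefs <- stats::setNames(rep(0, length(full)), full)
  coefs[names(cf)] <- cf
  structure(list(coefficients = coefs,
                 dropped = colnames(X)[const],
                 ridged = ridged,
                 converged = ridged || fit$converged,
                 se = if (!ridged) summary(fit)$coefficients[, 2] else NULL),
            class = "cad_logistic")
}

encode_male <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    bad <- !sex %in% c("male", "female")
    if (any(bad)) stop("sex must be 'male' or 'female'", call. = FALSE)
    as.numeric(sex == "male")
  } else as.numeric(sex)
}

#' @export
print.cad_logistic <- function(x, ...) {
  cat("<cad_logistic>", if (x$ridged) "(ridge fallback)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Linear predictor of the logistic fusion
#'
#' @param model a `cad_logistic`.
#' @param acoustic,age,sex,hypertension predictor values; missing values
#'   raise an error (a patient without complete clinical information cannot
#'   be scored).
#' @return numeric linear predictor (log-odds scale).
#' @export
linear_predictor <- function(model, acoustic, age, sex, hypertension) {
  stopifnot(inherits(model, "cad_logistic"))
  male <- encode_male(sex)
  X <- cbind(1, acoustic, age, male, as.numeric(hypertension))
  if (anyNA(X))
    stop("missing clinical information (age, sex or hypertension status); ",
         "cannot compute a CAD-score", call. = FALSE)
  drop(X %*% model$coefficients)
}

#' Calibrate the 0-99 score scaling
#'
#' Determines the affine map from the logistic linear predictor to the
#' score scale. The offset anchors the rule-out guarantee on the displayed
#' integer score: the empirical 10th percentile (linear-interpolation
#' quantile) of the linear predictors of significant-CAD training patients
#' maps to the very top of the threshold's rounding bin, so the anchor
#' itself still displays the threshold (20) while (essentially) every
#' diseased patient above it displays a score greater than 20 — making 90%
#' of diseased training patients score above the threshold after rounding.
#' The slope spreads the 2.5th-97.5th percentile span of all training
#' linear predictors over the score interval `[5, 75]`, filling the display
#' range without saturating it.
#'
#' @param lp numeric linear predictors of the training cohort.
#' @param labels significant-CAD indicator (logical or 0/1).
#' @param threshold decision threshold (default 20).
#' @param target fraction of diseased patients to place above the threshold
#'   (default 0.9).
#' @param span_quantiles quantiles of all linear predictors that define the
#'   spread anchor (default `c(0.025, 0.975)`).
#' @param span_range score interval those quantiles map onto (default
#'   `c(5, 75)`).
#' @param min_cases minimum number of diseased training patients (default 20).
#' @return object of class `score_anchors`: list with `slope` (> 0) and
#'   `offset`.
#' @export
calibrate_scale <- function(lp, labels, threshold = 20, target = 0.9,
                            span_quantiles = c(0.025, 0.975),
                            span_range = c(5, 75), min_cases = 20) {
  y <- as.logical(labels)
  if (sum(y) < min_cases)
    stop("need at least ", min_cases,
         " diseased training patients to calibrate", call. = FALSE)
  qs <- stats::quantile(lp, span_quantiles, names = FALSE, type = 7)
  if (diff(qs) < 1e-12)
    stop("degenerate linear-predictor spread; cannot calibrate",
         call. = FALSE)
  slope <- diff(span_range) / diff(qs)
  q_cad <- stats::quantile(lp[y], 1 - target, names = FALSE, type = 7)
  # the anchor maps to threshold + 0.5 - eps: it still rounds to the
  # threshold, while anything above it rounds past it, so the `target`
  # fraction of diseased patients exceeds the threshold on the integer scale
  structure(list(slope = slope,
                 offset = threshold + 0.5 - 1e-9 - slope * q_cad),
            class = "score_anchors")
}

#' @export
print.score_anchors <- function(x, ...) {
  cat(sprintf("<score_anchors> score = %.4f * lp + %.4f\n", x$slope, x$offset))
  invisible(x)
}

#' Map linear predictors to the continuous score scale
#'
#' The order-preserving affine map `slope * lp + offset` without rounding or
#' clamping; [compute_cad_score()] adds integer rounding and the `[0, 99]`
#' clamp.
#'
#' @param lp numeric linear predictors.
#' @param anchors a `score_anchors`.
#' @return numeric continuous scores.
#' @export
score_map <- function(lp, anchors) {
  stopifnot(inherits(anchors, "score_anchors"))
  anchors$slope * lp + anchors$offset
}

#' The fitted CAD-score model
#'
#' Bundles the three fitted stages: the acoustic linear discriminant, the
#' logistic fusion, and the scaling anchors, plus the fixed decision
#' threshold of 20.
#'
#' @param lda an `lda_weights`.
#' @param logistic a `cad_logistic`.
#' @param anchors a `score_anchors`.
#' @return object of class `cad_score_model`.
#' @export
cad_score_model <- function(lda, logistic, anchors) {
  stopifnot(inherits(lda, "lda_weights"), inherits(logistic, "cad_logistic"),
            inherits(anchors, "score_anchors"))
  structure(list(lda = lda, logistic = logistic, anchors = anchors,
                 threshold = 20L),
            class = "cad_score_model")
}

#' @export
print.cad_score_model <- function(x, ...) {
  cat("<cad_score_model> threshold", x$threshold, "\n")
  print(x$lda); print(x$logistic); print(x$anchors)
  invisible(x)
}

#' Compute integer 0-99 CAD-scores
#'
#' Applies the full fitted model to patient inputs: acoustic features ->
#' acoustic score -> logistic linear predictor -> affine scaling -> rounded
#' (half up) and clamped to `[0, 99]`. Strictly non-decreasing in the
#' acoustic score.
#'
#' @param model a `cad_score_model`.
#' @param features feature matrix (or vector) for the recordings, or `NULL`
#'   if `acoustic` is given directly.
#' @param age,sex,hypertension clinical covariates; missing values raise an
#'   error (patients with missing clinical information cannot be scored).
#' @param acoustic optional precomputed acoustic scores.
#' @return integer vector of scores in `[0, 99]`.
#' @export
compute_cad_score <- function(model, features = NULL, age, sex, hypertension,
                              acoustic = NULL) {
  stopifnot(inherits(model, "cad_score_model"))
  if (is.null(acoustic)) {
    if (is.null(features)) stop("need features or acoustic scores", call. = FALSE)
    acoustic <- acoustic_score(features, model$lda)
  }
  lp <- linear_predictor(model$logistic, acoustic, age, sex, hypertension)
  raw <- score_map(lp, model$anchors)
  as.integer(pmin(pmax(floor(raw + 0.5), 0), 99))
}

#' Dichotomise a CAD-score at the rule-out threshold
#'
#' A score above 20 is `abnormal`; 20 or below is `normal` (the rule-out
#' category).
#'
#' @param score integer scores in `[0, 99]`.
#' @return character vector, `"abnormal"` or `"normal"`.
#' @export
classify_score <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 99))
    stop("scores must lie in [0, 99]", call. = FALSE)
  ifelse(score > 20, "abnormal", "normal")
}

#' Serialise a CAD-score model to JSON and back
#'
#' @param model a `cad_score_model`.
#' @param path file path (`.json`).
#' @return `read_cad_model()` returns the model; `write_cad_model()` returns
#'   `path` invisibly.
#' @export
write_cad_model <- function(model, path) {
  stopifnot(inherits(model, "cad_score_model"))
  jsonlite::write_json(list(
    lda = list(weights = as.list(model$lda$weights),
               intercept = model$lda$intercept,
               shrinkage = model$lda$shrinkage),
    logistic = list(coefficients = as.list(model$logistic$coefficients),
                    ridged = model$logistic$ridged),
    anchors = list(slope = model$anchors$slope,
                   offset = model$anchors$offset),
    threshold = model$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cad_model
#' @export
read_cad_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lda <- structure(list(weights = unlist(j$lda$weights),
                        intercept = j$lda$intercept,
                        shrinkage = j$lda$shrinkage), class = "lda_weights")
  logistic <- structure(list(coefficients = unlist(j$logistic$coefficients),
                             dropped = character(), ridged = j$logistic$ridged,
                             converged = TRUE, se = NULL),
                        class = "cad_logistic")
  anchors <- structure(list(slope = j$anchors$slope, offset = j$anchors$offset),
                       class = "score_anchors")
  cad_score_model(lda, logistic, anchors)
}
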