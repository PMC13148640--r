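## Quadrupedal-versus-bipedal inference: allometric mass estimation from
## stylopodial circumferences, repeated-LDA stance classification, the
## humeral-vs-femoral circumference regression, and the static
## centre-of-mass criterion for bipedal standing.

#' Body mass from stylopodial circumferences
#'
#' The published quadrupedal allometric mass estimator on combined
#' humeral plus femoral midshaft circumference:
#' log10(mass in g) = 2.749 * log10(Ch + Cf in mm) - 1.104,
#' returned in kg. This coefficient set reproduces the printed worked
#' example (circumferences 14 and 13 mm give 0.68 kg).
#'
#' @param humeral_circumference humeral midshaft circumference (mm).
#' @param femoral_circumference femoral midshaft circumference (mm).
#' @return estimated body mass (kg).
#' @export
campione_evans_mass <- function(humeral_circumference,
                                femoral_circumference) {
  if (any(humeral_circumference <= 0) || any(femoral_circumference <= 0))
    stop("circumferences must be positive (mm)")
  grams <- 10^(2.749 * log10(humeral_circumference +
                             femoral_circumference) - 1.104)
  grams / 1000
}

#' Default battery of LDA stance tests
#'
#' The published repeated-LDA protocol ran 22 distinct training-set
#' analyses whose exact definitions are not printed; this default battery
#' (non-canonical, for synthetic work) uses the 15 non-empty predictor
#' subsets of the four morphometric features plus 7 seeded 75% training
#' subsamples on all four features, totalling 22 tests.
#'
#' @param predictors character vector of the four feature names.
#' @return list of 22 test specs, each `list(predictors =, frac =)`.
#' @export
default_lda_test_specs <- function(predictors = c("body_mass",
                                                  "dimensionless_com",
                                                  "forelimb_length",
                                                  "hindlimb_length")) {
  specs <- list()
  for (k in seq_along(predictors)) {
    for (cmb in utils::combn(predictors, k, simplify = FALSE)) {
      specs[[length(specs) + 1L]] <- list(predictors = cmb, frac = 1)
    }
  }
  for (i in 1:7) {
    specs[[length(specs) + 1L]] <- list(predictors = predictors, frac = 0.75)
  }
  specs
}

#' Repeated-LDA stance classification of a focal taxon
#'
#' Fits a two-class linear discriminant (pooled covariance, via
#' [MASS::lda()]) for each test specification - a predictor subset and/or
#' a seeded training subsample of the labelled taxa - and reports the
#' posterior probability that the focal taxon (labelled "unknown") is
#' quadrupedal, the per-test call, and the majority tally. Tests whose
#' pooled covariance is singular are marked failed rather than dropped.
#'
#' @param dataset data.frame with the predictor columns and a `stance`
#'   column in c("biped", "quadruped", "unknown").
#' @param focal_row row index (or logical) of the focal taxon.
#' @param test_specs list of specs as from [default_lda_test_specs()].
#' @param seed integer seed controlling subsample draws.
#' @param prior "proportional" (class frequencies; default) or "equal".
#' @return list of class `lda_verdict`: `posteriors` (P(quadruped) per
#'   test; NA = failed), `calls` ("quadruped"/"biped"/NA), `tally`
#'   (quadrupedal calls), `n_tests`, `majority`.
#' @export
lda_stance_tests <- function(dataset, focal_row, test_specs = NULL,
                             seed = 1,
                             prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  if (is.null(test_specs)) test_specs <- default_lda_test_specs()
  focal <- dataset[focal_row, , drop = FALSE]
  if (nrow(focal) != 1) stop("focal_row must select exactly one row")
  if (!identical(focal$stance, "unknown"))
    stop("focal taxon must be labelled 'unknown'")
  labelled <- dataset[dataset$stance %in% c("biped", "quadruped"), ,
                      drop = FALSE]
  if (length(unique(labelled$stance)) < 2)
    stop("need both labelled classes in the training data")
  set.seed(seed)
  posteriors <- rep(NA_real_, length(test_specs))
  for (i in seq_along(test_specs)) {
    spec <- test_specs[[i]]
    train <- labelled
    if (!is.null(spec$frac) && spec$frac < 1) {
      idx <- sort(sample(nrow(labelled), ceiling(spec$frac * nrow(labelled))))
      train <- labelled[idx, , drop = FALSE]
      if (length(unique(train$stance)) < 2) next  # failed: one class drawn
    }
    x <- as.matrix(train[, spec$predictors, drop = FALSE])
    g <- factor(train$stance, levels = c("biped", "quadruped"))
    pr <- if (prior == "equal") c(0.5, 0.5) else as.numeric(table(g)) / nrow(train)
    fit <- tryCatch(MASS::lda(x, grouping = g, prior = pr),
                    error = function(e) NULL)
    if (is.null(fit)) next  # failed (e.g. singular pooled covariance)
    pred <- stats::predict(fit,
                           as.matrix(focal[, spec$predictors, drop = FALSE]))
    posteriors[i] <- pred$posterior[1, "quadruped"]
  }
  calls <- ifelse(is.na(posteriors), NA_character_,
                  ifelse(posteriors > 0.5, "quadruped", "biped"))
  tally <- sum(calls == "quadruped", na.rm = TRUE)
  structure(list(posteriors = posteriors, calls = calls, tally = tally,
                 n_tests = length(test_specs),
                 majority = if (tally > length(test_specs) / 2)
                   "quadruped" else "biped"),
            class = "lda_verdict")
}

#' @export
print.lda_verdict <- function(x, ...) {
  cat(sprintf("%d of %d tests predict quadrupedalism (majority: %s)\n",
              x$tally, x$n_tests, x$majority))
  invisible(x)
}

point_in_polygon <- function(pt, poly) {
  # ray-casting parity; poly is an ordered n x 2 matrix
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > pt[2]) != (yj > pt[2])) &&
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi))
      inside <- !inside
    j <- i
  }
  inside
}

#' Humeral-versus-femoral circumference regression
#'
#' Ordinary least squares of log10 humeral on log10 femoral circumference
#' across taxa of known stance, with per-class convex hulls and a report
#' of whether the focal taxon falls inside each class's morphospace hull.
#'
#' @param data data.frame with columns `log_humeral`, `log_femoral`,
#'   `stance` (class labels; the focal row labelled "unknown").
#' @param focal_row index of the focal taxon (optional).
#' @return list of class `circ_regression`: `fit` (lm), `slope`,
#'   `intercept`, `r_squared`, `hulls` (per class, ordered vertex
#'   matrices), `focal_in_hull` (named logical).
#' @export
circumference_regression <- function(data, focal_row = NULL) {
  need <- c("log_humeral", "log_femoral", "stance")
  if (!all(need %in% names(data))) stop("data lacks columns: ",
    paste(setdiff(need, names(data)), collapse = ", "))
  labelled <- data[data$stance != "unknown", , drop = FALSE]
  if (nrow(labelled) < 3) stop("need at least 3 labelled points")
  if (stats::sd(labelled$log_femoral) < 1e-12)
    stop("degenerate input: femoral circumferences are collinear/constant")
  fit <- stats::lm(log_humeral ~ log_femoral, data = labelled)
  hulls <- list(); focal_in <- logical(0)
  focal_pt <- if (!is.null(focal_row))
    c(data$log_femoral[focal_row], data$log_humeral[focal_row]) else NULL
  for (cl in unique(labelled$stance)) {
    sub <- labelled[labelled$stance == cl, , drop = FALSE]
    if (nrow(sub) >= 3) {
      xy <- cbind(sub$log_femoral, sub$log_humeral)
      h <- grDevices::chull(xy)
      hulls[[cl]] <- xy[h, , drop = FALSE]
      if (!is.null(focal_pt))
        focal_in[cl] <- point_in_polygon(focal_pt, hulls[[cl]])
    }
  }
  structure(list(fit = fit, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 hulls = hulls, focal_in_hull = focal_in),
            class = "circ_regression")
}

#' Static bipedalism criterion
#'
#' For static bipedal standing the whole-body centre of mass must lie
#' less than one femur length cranial to the hips (otherwise the knee
#' cannot be positioned cranial to the COM and the knee extensors cannot
#' act against gravity). Ratios in [0.6, 1.0) are flagged as "pushing
#' the limits" of static bipedalism.
#'
#' @param com_offset cranial offset of the COM from the hip midpoint (m).
#' @param femur_length femur length (m).
#' @return list of class `bipedalism_check` with `ratio_pct`, `verdict`
#'   in c("passes", "marginal", "fails"), and `detail`.
#' @export
static_bipedalism_check <- function(com_offset, femur_length) {
  if (femur_length <= 0) stop("femur_length must be positive")
  ratio <- com_offset / femur_length
  verdict <- if (ratio >= 1) "fails"
             else if (ratio >= 0.6) "marginal"
             else "passes"
  detail <- switch(verdict,
    fails = "COM >= one femur length cranial to the hips: fails static criterion",
    marginal = "COM within one femur length but pushing the limits of static bipedalism",
    passes = "COM well within one femur length cranial to the hips")
  structure(list(ratio_pct = 100 * ratio, verdict = verdict,
                 detail = detail),
            class = "bipedalism_check")
}
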