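# GA-quartile-stratified random fold assignment; balanced folds within strata.
make_folds <- function(y, n_folds, seed, strata = NULL) {
  if (is.null(strata)) {
    br <- unique(stats::quantile(y, probs = seq(0, 1, 0.25), names = FALSE))
    strata <- if (length(br) > 1L) cut(y, breaks = br, include.lowest = TRUE,
                                       labels = FALSE) else rep(1L, length(y))
  }
  foldid <- integer(length(y))
  local_seed(seed, {
    for (g in unique(strata)) {
      idx <- which(strata == g)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  foldid
}

#' Train an elastic-net gestational-age clock
#'
#' Regresses gestational age (weeks) on CpG beta values with an elastic-net
#' penalty (`glmnet`), mixing parameter `alpha = 0.5` by default, and selects
#' the shrinkage `lambda` minimizing the mean cross-validated MSE over
#' `n_folds` folds. Folds are assigned by `fold_seed`, stratified by GA
#' quartile. Coefficients are reported on the original beta scale;
#' zero coefficients are dropped, so the model is sparse.
#'
#' A robust-clock training set includes complicated pregnancies; a
#' control-clock set is restricted via `sample_filter`; a refined clock is
#' obtained by passing the parent clock's probes as `probe_subset` together
#' with an uncomplicated-term filter (see [filter_uncomplicated_term()]).
#'
#' @param beta Beta matrix (samples in rows), no missing cells — run
#'   [impute_missing()] first.
#' @param sheet Sample sheet with `sample_id` and `ga_weeks`.
#' @param alpha Elastic-net mixing parameter in \[0, 1\]; 0.5 by default.
#' @param n_folds Number of CV folds (default 10).
#' @param fold_seed Seed controlling the fold assignment.
#' @param sample_filter Optional predicate `function(sheet) logical`,
#'   selecting training samples.
#' @param probe_subset Optional character vector restricting candidate
#'   probes (must be a subset of `colnames(beta)`).
#' @param lambda Optional fixed shrinkage value; skips cross-validation.
#' @param standardize Standardize predictors internally during fitting
#'   (coefficients are still reported on the beta scale).
#' @param name Model name stored in the result.
#' @return A [clock_model()] with training provenance in `$training`.
#' @export
train_clock <- function(beta, sheet, alpha = 0.5, n_folds = 10, fold_seed = 1L,
                        sample_filter = NULL, probe_subset = NULL, lambda = NULL,
                        standardize = TRUE, name = "clock") {
  validate_beta(beta)
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2)
  sheet <- align_sheet(beta, sheet)
  keep <- rep(TRUE, nrow(beta))
  filter_desc <- "all samples"
  if (!is.null(sample_filter)) {
    keep <- as.logical(sample_filter(sheet))
    keep[is.na(keep)] <- FALSE
    filter_desc <- paste(deparse(body(sample_filter)), collapse = " ")
  }
  if (any(keep & is.na(sheet$ga_weeks)))
    stop("retained samples with missing ga_weeks: ",
         paste(sheet$sample_id[keep & is.na(sheet$ga_weeks)], collapse = ", "))
  probes <- colnames(beta)
  if (!is.null(probe_subset)) {
    extra <- setdiff(probe_subset, probes)
    if (length(extra)) stop("probe_subset not in beta: ",
                            paste(utils::head(extra, 5), collapse = ", "))
    probes <- probe_subset
  }
  x <- beta[keep, probes, drop = FALSE]
  y <- sheet$ga_weeks[keep]
  if (anyNA(x)) stop("beta contains missing values; run impute_missing() first")
  if (nrow(x) < n_folds) stop("fewer samples than CV folds")
  if (ncol(x) < 2L) stop("need at least two candidate probes")
  if (stats::sd(y) == 0) stop("constant gestational age in training set")

  if (is.null(lambda)) {
    foldid <- make_folds(y, n_folds, fold_seed)
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                            standardize = standardize,
                            nlambda = 100, lambda.min.ratio = 1e-4)
    lambda_sel <- cv$lambda.min
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
    cv_mse <- min(cv$cvm)
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = standardize,
                          nlambda = 100, lambda.min.ratio = 1e-4, thresh = 1e-12)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                                alpha = alpha, standardize = standardize,
                                thresh = 1e-12))[, 1]
    lambda_sel <- lambda
    cv_mse <- NA_real_
  }
  clock_model(name, intercept = cf[1], coefficients = cf[-1],
              alpha = alpha, lambda = lambda_sel,
              training = list(n_samples = nrow(x), n_probes = ncol(x),
                              n_folds = n_folds, fold_seed = fold_seed,
                              filter = filter_desc, standardize = standardize,
                              cv_mse = cv_mse))
}

#' Uncomplicated-term sample filter
#'
#' Selects control pregnancies delivered at term: `condition == "control"`
#' and `ga_weeks > 36`. Used to derive a refined clock from a parent clock's
#' probe set.
#'
#' @param sheet Sample sheet.
#' @return Logical vector over rows of `sheet`.
#' @export
filter_uncomplicated_term <- function(sheet) {
  !is.na(sheet$ga_weeks) & sheet$ga_weeks > 36 &
    !is.na(sheet$condition) & sheet$condition == "control"
}

#' Predict gestational age from a clock model
#'
#' Predicted GA is the model intercept plus the coefficient-weighted sum of
#' beta values at the model's CpGs. Works with any coefficient table read via
#' [read_clock()], so externally published clocks can be applied for
#' comparison.
#'
#' @param model A [clock_model()].
#' @param beta Beta matrix (samples in rows).
#' @param on_missing_probe `"error"` (default) to fail when model probes are
#'   absent from `beta`, or `"impute_value"` to fill them with
#'   `missing_value`.
#' @param missing_value Beta value substituted for absent probes under the
#'   `"impute_value"` policy.
#' @return Named numeric vector of predicted GA (weeks), one per sample.
#' @export
predict_ga <- function(model, beta, on_missing_probe = c("error", "impute_value"),
                       missing_value = 0.5) {
  stopifnot(inherits(model, "clock_model"))
  on_missing_probe <- match.arg(on_missing_probe)
  validate_beta(beta)
  probes <- names(model$coefficients)
  absent <- setdiff(probes, colnames(beta))
  if (length(absent) && on_missing_probe == "error")
    stop("model probes missing from beta: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10))
  present <- setdiff(probes, absent)
  x <- beta[, present, drop = FALSE]
  if (length(absent)) {
    fill <- matrix(missing_value, nrow(beta), length(absent),
                   dimnames = list(rownames(beta), absent))
    x <- cbind(x, fill)
  }
  pred <- model$intercept +
    as.vector(x[, probes, drop = FALSE] %*% model$coefficients)
  setNames(pred, rownames(beta))
}

#' @param object A `clock_model`.
#' @param newdata Beta matrix (samples in rows).
#' @param ... Passed to [predict_ga()].
#' @rdname predict_ga
#' @export
predict.clock_model <- function(object, newdata, ...) {
  predict_ga(object, newdata, ...)
}

#' Gestational-age acceleration
#'
#' GA acceleration is the raw residual from regressing the DNAm GA estimate
#' on observed GA (ordinary least squares). By construction it is
#' uncorrelated with observed GA; positive values mean an epigenetically
#' "older" placenta than gestation would predict. Standardized residuals
#' (raw divided by their sample SD) are also provided.
#'
#' @param predicted Predicted GA vector (weeks).
#' @param observed Observed GA vector (weeks), same length, non-constant.
#' @param mode Which residual `residuals()` returns: `"raw"` (default) or
#'   `"standardized"`.
#' @return Object of class `ga_acceleration` with per-sample raw and
#'   standardized residuals plus the calibration slope and intercept.
#' @export
ga_acceleration <- function(predicted, observed, mode = c("raw", "standardized")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 samples")
  if (anyNA(predicted) || anyNA(observed)) stop("missing values in GA vectors")
  if (stats::sd(observed) == 0) stop("constant observed GA")
  fit <- stats::lm(predicted ~ observed)
  raw <- unname(stats::residuals(fit))
  s <- stats::sd(raw)
  structure(list(raw_residuals = setNames(raw, names(predicted)),
                 standardized_residuals = setNames(
                   if (s > 0) raw / s else raw * 0, names(predicted)),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 mode = mode),
            class = "ga_acceleration")
}

#' @export
print.ga_acceleration <- function(x, ...) {
  cat(sprintf("GA acceleration (%s residuals), n = %d\n",
              x$mode, length(x$raw_residuals)))
  cat(sprintf("  calibration: predicted = %.3f + %.3f * observed\n",
              x$intercept, x$slope))
  cat(sprintf("  raw residual SD: %.3f weeks\n", stats::sd(x$raw_residuals)))
  invisible(x)
}

#' @export
residuals.ga_acceleration <- function(object, ...) {
  if (object$mode == "raw") object$raw_residuals else object$standardized_residuals
}

#' Train a DNA-methylation fetal-sex classifier
#'
#' Logistic elastic net (`alpha = 0.5`, binomial deviance, lambda by
#' cross-validation) of fetal sex on autosomal CpG beta values, for imputing
#' sex in cohorts that stripped sex chromosomes or did not report sex.
#'
#' @param beta Beta matrix (samples in rows), autosomal probes; supply
#'   `manifest` to enforce the autosomal restriction.
#' @param sheet Sample sheet with a `sex` column in `{male, female}`
#'   (samples with unknown sex are dropped).
#' @param alpha,n_folds,fold_seed,standardize As in [train_clock()].
#' @param positive_class Which sex the logistic score models; default
#'   `"female"`.
#' @param manifest Optional probe manifest used to drop non-autosomal probes.
#' @return Object of class `sex_classifier` (intercept, sparse log-odds
#'   coefficients, positive class).
#' @export
train_sex_classifier <- function(beta, sheet, alpha = 0.5, n_folds = 10,
                                 fold_seed = 1L, positive_class = "female",
                                 standardize = TRUE, manifest = NULL) {
  validate_beta(beta)
  stopifnot(positive_class %in% c("male", "female"))
  sheet <- align_sheet(beta, sheet)
  if (!is.null(manifest)) {
    auto <- intersect_probes(manifest, autosomes_only = TRUE)
    beta <- beta[, colnames(beta) %in% auto, drop = FALSE]
  }
  keep <- sheet$sex %in% c("male", "female")
  x <- beta[keep, , drop = FALSE]
  sex <- sheet$sex[keep]
  if (anyNA(x)) stop("beta contains missing values; run impute_missing() first")
  if (length(unique(sex)) < 2L) stop("both sexes must be present in training data")
  if (nrow(x) < n_folds) stop("fewer samples than CV folds")
  negative <- setdiff(c("male", "female"), positive_class)
  y <- factor(sex, levels = c(negative, positive_class))
  foldid <- make_folds(seq_along(y), n_folds, fold_seed, strata = y)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, type.measure = "deviance",
                          standardize = standardize,
                          nlambda = 100, lambda.min.ratio = 1e-4)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  coefs <- cf[-1][cf[-1] != 0]
  structure(list(intercept = unname(cf[1]),
                 coefficients = coefs,
                 positive_class = positive_class,
                 alpha = alpha, lambda = cv$lambda.min,
                 n_features = length(coefs),
                 training = list(n_samples = nrow(x), n_probes = ncol(x),
                                 n_folds = n_folds, fold_seed = fold_seed)),
            class = "sex_classifier")
}

#' @export
print.sex_classifier <- function(x, ...) {
  cat(sprintf("Fetal sex classifier: %d CpG(s), positive class '%s'\n",
              x$n_features, x$positive_class))
  cat(sprintf("  elastic net: alpha = %g, lambda = %.4g\n", x$alpha, x$lambda))
  invisible(x)
}

#' Predict fetal sex from methylation
#'
#' @param classifier A `sex_classifier` from [train_sex_classifier()].
#' @param beta Beta matrix (samples in rows); all classifier probes must be
#'   present.
#' @return Data frame with `sample_id`, `probability` (of the positive
#'   class) and `sex`. A probability of exactly 0.5 is resolved to the
#'   negative class.
#' @export
predict_sex <- function(classifier, beta) {
  stopifnot(inherits(classifier, "sex_classifier"))
  validate_beta(beta)
  probes <- names(classifier$coefficients)
  absent <- setdiff(probes, colnames(beta))
  if (length(absent))
    stop("classifier probes missing from beta: ",
         paste(utils::head(absent, 10), collapse = ", "))
  eta <- classifier$intercept +
    as.vector(beta[, probes, drop = FALSE] %*% classifier$coefficients)
  p <- stats::plogis(eta)
  negative <- setdiff(c("male", "female"), classifier$positive_class)
  data.frame(sample_id = rownames(beta),
             probability = p,
             sex = ifelse(p > 0.5, classifier$positive_class, negative),
             stringsAsFactors = FALSE)
}
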