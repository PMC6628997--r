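#' Evaluate clock predictions against observed gestational age
#'
#' Accuracy is summarized by the median absolute error (MAE, weeks) between
#' predicted and observed GA, with a seeded percentile-bootstrap 95% CI over
#' paired resamples, and by the Pearson correlation with a Fisher-z 95% CI.
#'
#' @param predicted,observed Numeric GA vectors of equal length `n >= 3`.
#' @param bootstrap_reps Bootstrap replicates for the MAE CI (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @param subgroup Optional label carried into the result.
#' @return Object of class `clock_eval` with elements `mae`, `mae_ci`,
#'   `pearson_r`, `r_ci`, `n`, `subgroup`.
#' @export
evaluate_clock <- function(predicted, observed, bootstrap_reps = 1000L,
                           seed = 1L, subgroup = NULL) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]
  observed <- observed[ok]
  n <- length(observed)
  if (n < 3L) stop("need at least 3 paired values")
  if (stats::sd(observed) == 0) stop("constant observed GA: r undefined")
  abs_err <- abs(predicted - observed)
  mae <- stats::median(abs_err)
  mae_ci <- local_seed(seed, {
    reps <- vapply(seq_len(bootstrap_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      stats::median(abs_err[idx])
    }, numeric(1))
    unname(stats::quantile(reps, c(0.025, 0.975)))
  })
  # constant predictions (e.g. an intercept-only clock) leave r undefined
  # but MAE is still meaningful
  r <- if (stats::sd(predicted) == 0) NA_real_ else stats::cor(predicted, observed)
  r_ci <- if (!is.na(r) && n > 3 && abs(r) < 1) {
    zr <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  structure(list(mae = mae, mae_ci = mae_ci, pearson_r = r, r_ci = r_ci,
                 n = n, subgroup = subgroup,
                 predicted = predicted, observed = observed),
            class = "clock_eval")
}

#' @export
print.clock_eval <- function(x, ...) {
  cat(sprintf("Clock evaluation%s (n = %d)\n",
              if (!is.null(x$subgroup)) paste0(" [", x$subgroup, "]") else "", x$n))
  cat(sprintf("  MAE = %.2f weeks, 95%% CI [%.2f, %.2f]\n",
              x$mae, x$mae_ci[1], x$mae_ci[2]))
  cat(sprintf("  Pearson r = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$pearson_r, x$r_ci[1], x$r_ci[2]))
  invisible(x)
}

#' @export
plot.clock_eval <- function(x, ...) {
  graphics::plot(x$observed, x$predicted, pch = 20,
                 xlab = "observed GA (weeks)", ylab = "predicted GA (weeks)", ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}

#' @export
as.data.frame.clock_eval <- function(x, ...) {
  data.frame(subgroup = if (is.null(x$subgroup)) "all" else x$subgroup,
             n = x$n, mae = x$mae, mae_lo = x$mae_ci[1], mae_hi = x$mae_ci[2],
             r = x$pearson_r, r_lo = x$r_ci[1], r_hi = x$r_ci[2],
             stringsAsFactors = FALSE)
}

#' Compare several clocks on the same data
#'
#' Applies each clock via [predict_ga()] and evaluates it with
#' [evaluate_clock()], overall and within optional subgroups (e.g. late
#' gestation `ga_weeks > 25`, or per pregnancy condition). Empty subgroups
#' are omitted with a warning.
#'
#' @param models Named list of [clock_model()] objects.
#' @param beta Beta matrix (samples in rows).
#' @param sheet Sample sheet with `ga_weeks`.
#' @param subgroups Optional named list of predicates `function(sheet)
#'   logical`; the unfiltered evaluation is labelled `"all"`.
#' @param bootstrap_reps,seed Passed to [evaluate_clock()].
#' @param on_missing_probe Passed to [predict_ga()].
#' @return Data frame with one row per model x subgroup.
#' @export
compare_clocks <- function(models, beta, sheet, subgroups = NULL,
                           bootstrap_reps = 1000L, seed = 1L,
                           on_missing_probe = "error") {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- paste0("clock", seq_along(models))
  sheet <- align_sheet(beta, sheet)
  groups <- c(list(all = function(s) rep(TRUE, nrow(s))), subgroups)
  rows <- list()
  for (mn in names(models)) {
    pred <- predict_ga(models[[mn]], beta, on_missing_probe = on_missing_probe)
    for (gn in names(groups)) {
      keep <- as.logical(groups[[gn]](sheet))
      keep[is.na(keep)] <- FALSE
      keep <- keep & !is.na(sheet$ga_weeks)
      if (!any(keep)) {
        warning("subgroup '", gn, "' is empty; omitted")
        next
      }
      ev <- evaluate_clock(pred[keep], sheet$ga_weeks[keep],
                           bootstrap_reps = bootstrap_reps, seed = seed,
                           subgroup = gn)
      df <- as.data.frame(ev)
      df <- cbind(model = mn, df, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
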