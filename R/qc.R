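#' Intersect probe sets across array manifests
#'
#' Cross-platform harmonization: the probes shared by every manifest,
#' optionally restricted to autosomes (chromosomes 1-22). Clocks trained on
#' the shared autosomal set apply to data from either Illumina platform.
#'
#' @param manifests A manifest data frame or a list of them
#'   (see [read_manifest()]).
#' @param autosomes_only Drop X/Y probes (default `TRUE`).
#' @return Character vector of shared probe ids; a warning (not an error) if
#'   the intersection is empty.
#' @export
intersect_probes <- function(manifests, autosomes_only = TRUE) {
  if (is.data.frame(manifests)) manifests <- list(manifests)
  if (length(manifests) < 1L) stop("at least one manifest is required")
  sets <- lapply(manifests, function(m) {
    ids <- m$probe_id
    if (autosomes_only) ids <- ids[m$chromosome %in% as.character(1:22)]
    ids
  })
  out <- Reduce(intersect, sets)
  if (length(out) == 0L) warning("probe intersection is empty")
  out
}

#' Gold-standard methylation profile
#'
#' The inter-sample median beta per CpG, the reference profile against which
#' individual samples are screened for quality and from which missing values
#' are imputed.
#'
#' @param beta Beta matrix (samples in rows); missing entries are ignored
#'   per probe.
#' @return Named numeric vector of per-probe medians. Probes missing in every
#'   sample get `NA` and are listed in the `"all_missing"` attribute.
#' @export
gold_standard <- function(beta) {
  validate_beta(beta)
  if (nrow(beta) < 1L) stop("need at least one sample")
  med <- apply(beta, 2L, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  all_missing <- names(med)[is.na(med)]
  if (length(all_missing)) attr(med, "all_missing") <- all_missing
  med
}

#' Detect outlying samples against the gold-standard profile
#'
#' Three-step recipe: (1) compute the gold-standard profile (per-probe median
#' over all samples, prospective outliers included — no iteration); (2)
#' correlate each sample with it (Pearson, over probes non-missing in both);
#' (3) exclude samples whose correlation falls below `min_correlation`.
#'
#' @param beta Beta matrix (samples in rows).
#' @param min_correlation Exclusion threshold, default 0.9.
#' @return A `qc_report`: gold standard, per-sample correlations, excluded
#'   sample ids with reasons (`"low_correlation"` or `"constant profile"`).
#' @export
detect_outliers <- function(beta, min_correlation = 0.9) {
  validate_beta(beta)
  stopifnot(min_correlation > 0, min_correlation < 1)
  if (nrow(beta) < 3L)
    warning("fewer than 3 samples: gold-standard correlation is degenerate")
  gold <- gold_standard(beta)
  rs <- setNames(rep(NA_real_, nrow(beta)), rownames(beta))
  reasons <- character(0)
  for (i in seq_len(nrow(beta))) {
    x <- beta[i, ]
    ok <- !is.na(x) & !is.na(gold)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0) {
      reasons[rownames(beta)[i]] <- "constant profile"
      next
    }
    rs[i] <- stats::cor(x[ok], gold[ok])
  }
  low <- names(rs)[!is.na(rs) & rs < min_correlation]
  reasons[low] <- "low_correlation"
  excluded <- rownames(beta)[rownames(beta) %in% names(reasons)]
  structure(list(gold_standard = gold,
                 sample_correlations = rs,
                 excluded_samples = excluded,
                 reasons = reasons[excluded],
                 min_correlation = min_correlation,
                 n_samples = nrow(beta),
                 n_imputed = NA_integer_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d samples, %d excluded (r < %g)\n",
              x$n_samples, length(x$excluded_samples), x$min_correlation))
  if (length(x$excluded_samples))
    cat("  excluded:", paste(sprintf("%s [%s]", x$excluded_samples, x$reasons),
                             collapse = ", "), "\n")
  rs <- x$sample_correlations
  cat(sprintf("  correlation range: [%.4f, %.4f]\n",
              min(rs, na.rm = TRUE), max(rs, na.rm = TRUE)))
  if (!is.na(x$n_imputed)) cat("  imputed cells:", x$n_imputed, "\n")
  invisible(x)
}

#' Impute missing beta values from the gold-standard profile
#'
#' Every missing cell is replaced by that probe's gold-standard median;
#' observed cells are untouched. Whether imputation is applied to training
#' data only is a pipeline decision made by the caller — this is a pure
#' transform.
#'
#' @param beta Beta matrix (samples in rows), possibly with `NA` cells.
#' @param gold Per-probe median vector covering all probes of `beta`;
#'   computed from `beta` itself when omitted.
#' @return Beta matrix with no missing cells; the number of imputed cells is
#'   in the `"n_imputed"` attribute.
#' @export
impute_missing <- function(beta, gold = NULL) {
  validate_beta(beta)
  if (is.null(gold)) gold <- gold_standard(beta)
  if (!all(colnames(beta) %in% names(gold)))
    stop("gold vector does not cover probes: ",
         paste(setdiff(colnames(beta), names(gold)), collapse = ", "))
  gold <- gold[colnames(beta)]
  miss <- is.na(beta)
  need <- colSums(miss) > 0
  dead <- names(gold)[need & is.na(gold)]
  if (length(dead))
    stop("cannot impute probes with missing gold-standard value: ",
         paste(dead, collapse = ", "))
  out <- beta
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)
    out[miss] <- gold[idx[, 2]]
  }
  attr(out, "n_imputed") <- sum(miss)
  out
}
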