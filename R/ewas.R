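#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweight downweighting around the median.
#' With `m_x = median(x)` and `d_x = median(|x - m_x|)`, observations are
#' scored `u_i = (x_i - m_x) / (9 d_x)`, weighted `a_i = (1 - u_i^2)^2` for
#' `|u_i| < 1` (zero otherwise), and correlated on the weighted deviations.
#' If either median absolute deviation is zero the Pearson correlation is
#' returned instead, flagged via the `"method"` attribute.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in \[-1, 1\] with attribute `"method"` equal to
#'   `"bicor"` or `"pearson"` (fallback); `NA` with attribute `"reason"` if
#'   all weight collapses.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; subset first")
  dx <- stats::median(abs(x - stats::median(x)))
  dy <- stats::median(abs(y - stats::median(y)))
  if (dx == 0 || dy == 0) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out <- NA_real_
      attr(out, "reason") <- "zero variance"
      return(out)
    }
    out <- stats::cor(x, y)
    attr(out, "method") <- "pearson"
    return(out)
  }
  xt <- .biweight(x, dx)
  yt <- .biweight(y, dy)
  sx <- sqrt(sum(xt^2))
  sy <- sqrt(sum(yt^2))
  if (sx == 0 || sy == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance after weighting"
    return(out)
  }
  out <- sum(xt * yt) / (sx * sy)
  attr(out, "method") <- "bicor"
  out
}

.biweight <- function(x, d) {
  m <- stats::median(x)
  u <- (x - m) / (9 * d)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  (x - m) * a
}

# z from the two-sided Student-t p-value, sign-preserving and underflow-safe.
.z_from_t <- function(t_stat, df, r) {
  logp_half <- stats::pt(abs(t_stat), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(logp_half, lower.tail = FALSE, log.p = TRUE)
  sign(r) * pmin(z, 40)
}

#' Per-stratum EWAS screen of gestational age
#'
#' For every probe, the biweight midcorrelation between beta values and GA
#' within one stratum, the Student-t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))`, its two-sided p-value, and the
#' sign-preserving normal-quantile Z. Probes with missing cells use
#' pairwise-complete observations; the per-probe `n` is recorded. A perfect
#' `|r| = 1` yields the smallest representable p and Z capped at +/-40.
#'
#' @param beta Beta matrix (samples in rows).
#' @param sheet Sample sheet; stratum membership is taken from the `stratum`
#'   column when present (non-`NA`), else from `condition`.
#' @param stratum Stratum label to screen.
#' @return Data frame with columns `probe_id`, `n`, `bicor`, `t`, `p`, `z`,
#'   `fallback` (Pearson fallback flag).
#' @export
stratum_screen <- function(beta, sheet, stratum) {
  validate_beta(beta)
  sheet <- align_sheet(beta, sheet)
  lab <- sheet$stratum
  if (is.null(lab)) lab <- sheet$condition
  lab[is.na(lab)] <- sheet$condition[is.na(lab)]
  idx <- which(lab == stratum & !is.na(sheet$ga_weeks))
  if (!any(lab == stratum, na.rm = TRUE))
    stop("stratum not present in sample sheet: ", stratum)
  if (length(idx) < 4L) stop("stratum '", stratum, "' has fewer than 4 usable samples")
  x <- beta[idx, , drop = FALSE]
  ga <- sheet$ga_weeks[idx]
  p_ids <- colnames(x)

  if (!anyNA(x)) {
    res <- .screen_complete(x, ga)
  } else {
    res <- t(vapply(seq_along(p_ids), function(j) {
      ok <- !is.na(x[, j])
      nj <- sum(ok)
      if (nj < 4L) return(c(n = nj, r = NA_real_, fb = NA_real_))
      r <- bicor(x[ok, j], ga[ok])
      c(n = nj, r = as.numeric(r),
        fb = as.numeric(identical(attr(r, "method"), "pearson")))
    }, numeric(3)))
  }
  n <- res[, 1]
  r <- res[, 2]
  fallback <- res[, 3] == 1
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  logp_half <- stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE, log.p = TRUE)
  p <- pmax(2 * exp(logp_half), .Machine$double.xmin)
  z <- .z_from_t(t_stat, n - 2, r)
  perfect <- !is.na(r) & abs(r) >= 1
  p[perfect] <- .Machine$double.xmin
  z[perfect] <- sign(r[perfect]) * 40
  data.frame(probe_id = p_ids, n = as.integer(n), bicor = r,
             t = t_stat, p = p, z = z, fallback = fallback,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorized biweight screen for a complete (no-NA) stratum matrix.
.screen_complete <- function(x, ga) {
  n <- nrow(x)
  mx <- apply(x, 2L, stats::median)
  dev <- sweep(x, 2L, mx)
  dx <- apply(abs(dev), 2L, stats::median)
  my <- stats::median(ga)
  dy <- stats::median(abs(ga - my))
  r <- rep(NA_real_, ncol(x))
  fb <- rep(0, ncol(x))

  normal <- dx > 0 & dy > 0
  if (any(normal)) {
    u <- sweep(dev[, normal, drop = FALSE], 2L, 9 * dx[normal], "/")
    a <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- dev[, normal, drop = FALSE] * a
    uy <- (ga - my) / (9 * dy)
    ay <- (1 - uy^2)^2 * (abs(uy) < 1)
    yt <- (ga - my) * ay
    sx <- sqrt(colSums(xt^2))
    sy <- sqrt(sum(yt^2))
    num <- as.vector(crossprod(xt, yt))
    rr <- ifelse(sx > 0 & sy > 0, num / (sx * sy), NA_real_)
    r[normal] <- rr
  }
  flat <- which(!normal)
  for (j in flat) {
    if (stats::sd(x[, j]) == 0 || stats::sd(ga) == 0) next
    r[j] <- stats::cor(x[, j], ga)
    fb[j] <- 1
  }
  cbind(n = rep(n, ncol(x)), r = r, fb = fb)
}

#' Weighted Stouffer meta-analysis of stratum Z scores
#'
#' Combines per-stratum Z statistics with weights equal to the square root
#' of the stratum sample size:
#' `meta_z = sum(z_i * sqrt(n_i)) / sqrt(sum(n_i))`.
#'
#' @param z Numeric vector of stratum Z scores.
#' @param n Integer vector of stratum sample sizes (same length, all >= 1).
#' @return The combined Z score.
#' @examples
#' stouffer_meta(c(-9.4, -3.9), c(831, 70))  # -10.11
#' @export
stouffer_meta <- function(z, n) {
  if (length(z) != length(n)) stop("z and n must have equal length")
  if (length(z) < 1L) stop("need at least one stratum")
  if (any(n < 1)) stop("all sample sizes must be >= 1")
  sum(z * sqrt(n)) / sqrt(sum(n))
}

#' Two-sided normal p-value from a Z score
#'
#' `p = 2 * (1 - pnorm(|z|))`, computed on the log scale so far-tail values
#' do not underflow (|z| near 10 gives ~1e-24 rather than 0).
#'
#' @param z Finite Z score (vectorized).
#' @return p-value(s) in (0, 1].
#' @examples
#' p_from_z(10.1)  # ~5.5e-24
#' @export
p_from_z <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  pmax(exp(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)),
       .Machine$double.xmin)
}

#' Stratified epigenome-wide association study of gestational age
#'
#' Runs [stratum_screen()] within each stratum (guarding against confounding
#' by pregnancy condition, e.g. preeclampsia shortening gestation while
#' altering methylation), combines stratum Z scores per probe with
#' [stouffer_meta()], converts to meta p-values with [p_from_z()], and flags
#' genome-wide significance at `threshold`.
#'
#' @param beta Beta matrix (samples in rows).
#' @param sheet Sample sheet.
#' @param strata Character vector of stratum labels (condition labels by
#'   default convention), e.g. `c("control", "preeclampsia")`.
#' @param threshold Genome-wide significance threshold on the meta p-value,
#'   default `1e-7`.
#' @return Data frame of class `ewas_table`, sorted by `meta_p` ascending,
#'   with per-stratum columns `n_<s>`, `bicor_<s>`, `p_<s>`, `z_<s>` plus
#'   `meta_z`, `meta_p`, `significant`.
#' @export
run_ewas <- function(beta, sheet, strata, threshold = 1e-7) {
  stopifnot(length(strata) >= 1L, threshold > 0, threshold < 1)
  screens <- lapply(strata, function(s) stratum_screen(beta, sheet, s))
  names(screens) <- strata
  out <- data.frame(probe_id = screens[[1]]$probe_id, stringsAsFactors = FALSE)
  for (s in strata) {
    sc <- screens[[s]]
    if (!identical(sc$probe_id, out$probe_id))
      sc <- sc[match(out$probe_id, sc$probe_id), ]
    out[[paste0("n_", s)]] <- sc$n
    out[[paste0("bicor_", s)]] <- sc$bicor
    out[[paste0("p_", s)]] <- sc$p
    out[[paste0("z_", s)]] <- sc$z
  }
  zmat <- as.matrix(out[paste0("z_", strata)])
  nmat <- as.matrix(out[paste0("n_", strata)])
  out$meta_z <- rowSums(zmat * sqrt(nmat)) / sqrt(rowSums(nmat))
  out$meta_p <- p_from_z(ifelse(is.na(out$meta_z), 0, out$meta_z))
  out$meta_p[is.na(out$meta_z)] <- NA_real_
  out$significant <- !is.na(out$meta_p) & out$meta_p < threshold
  ord <- order(out$meta_p, -abs(out$meta_z), out$probe_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ewas_table", "data.frame"),
            strata = strata, threshold = threshold)
}

#' @export
print.ewas_table <- function(x, n = 10L, ...) {
  cat(sprintf("EWAS of GA: %d probes, strata [%s], %d significant at %g\n",
              nrow(x), paste(attr(x, "strata"), collapse = ", "),
              sum(x$significant, na.rm = TRUE), attr(x, "threshold")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @export
plot.ewas_table <- function(x, ...) {
  lp <- -log10(x$meta_p)
  graphics::plot(seq_along(lp)[order(x$probe_id)], lp[order(x$probe_id)],
                 pch = 20, cex = 0.4, xlab = "probe index",
                 ylab = expression(-log[10](meta~p)), ...)
  graphics::abline(h = -log10(attr(x, "threshold")), col = "red", lty = 2)
  invisible(x)
}

#' Tabulate significant EWAS probes by annotation
#'
#' Cross-tabulates genome-wide-significant probes by CpG-island relation and
#' counts significant CpGs per gene (a probe annotated to several genes
#' contributes to each). Gene ranking breaks count ties alphabetically.
#'
#' @param table An `ewas_table` from [run_ewas()].
#' @param manifest Probe manifest ([read_manifest()]); probes it does not
#'   cover are counted as unannotated.
#' @return List with `island_counts` (named integer vector over island
#'   relations plus `unannotated`), `gene_counts` (data frame `gene`,
#'   `n_cpg`, sorted), and `n_significant`.
#' @export
annotate_and_tabulate <- function(table, manifest) {
  sig <- table$probe_id[table$significant]
  m <- match(sig, manifest$probe_id)
  rel <- manifest$island_relation[m]
  rel[is.na(m)] <- "unannotated"
  rel[is.na(rel)] <- "unannotated"
  island_counts <- vapply(c(.island_levels, "unannotated"),
                          function(l) sum(rel == l), integer(1))
  genes <- manifest$genes[m[!is.na(m)]]
  gl <- unlist(strsplit(genes[!is.na(genes) & genes != ""], ";", fixed = TRUE))
  gl <- trimws(gl)
  gl <- gl[gl != ""]
  if (length(gl)) {
    tab <- table(gl)
    gene_counts <- data.frame(gene = names(tab), n_cpg = as.integer(tab),
                              stringsAsFactors = FALSE)
    gene_counts <- gene_counts[order(-gene_counts$n_cpg, gene_counts$gene), ]
    rownames(gene_counts) <- NULL
  } else {
    gene_counts <- data.frame(gene = character(0), n_cpg = integer(0))
  }
  list(island_counts = island_counts, gene_counts = gene_counts,
       n_significant = length(sig))
}
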