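#' Read a methylation beta matrix from delimited text
#'
#' Reads a CSV or TSV beta matrix (the delimiter is sniffed from the header
#' line) into the canonical samples-in-rows form. GEO series-matrix style
#' files, which store probes in rows, are the default orientation.
#'
#' @param path Path to a delimited text file with one identifier column and
#'   an identifier header row.
#' @param orientation `"probes_in_rows"` (GEO convention, default) or
#'   `"samples_in_rows"`.
#' @param missing_tokens Character vector of cell values treated as missing.
#' @return Numeric matrix, samples in rows, probes in columns, values in
#'   \[0, 1\] with `NA` for missing entries.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,S1,S2", "cg01,0.1,0.9", "cg02,0.5,0.5"), f)
#' b <- read_beta_matrix(f)
#' dim(b)  # 2 samples x 2 probes
#' @export
read_beta_matrix <- function(path, orientation = c("probes_in_rows", "samples_in_rows"),
                             missing_tokens = c("", "NA")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = missing_tokens, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("beta matrix file needs an id column plus data columns")
  row_ids <- as.character(df[[1L]])
  if (anyDuplicated(row_ids))
    stop("duplicate identifier(s) in rows: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(col_ids))
    stop("duplicate identifier(s) in header: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at row %s, column %s",
                   m[bad[1, , drop = FALSE]], row_ids[bad[1, 1]], col_ids[bad[1, 2]]))
    m <- num
  }
  dimnames(m) <- list(row_ids, col_ids)
  if (orientation == "probes_in_rows") m <- t(m)
  validate_beta(m)
  m
}

#' Write a beta matrix to delimited text
#'
#' Values are written at full double precision so a write/read round trip is
#' the identity to better than 1e-12.
#'
#' @param beta Numeric beta matrix, samples in rows (canonical form).
#' @param path Output file path; `.tsv` extension selects tab separation.
#' @param orientation Layout of the written file; default matches the GEO
#'   probes-in-rows convention.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(beta, path,
                              orientation = c("probes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  validate_beta(beta)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- if (orientation == "probes_in_rows") t(beta) else beta
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(paste(c("id", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)),
                    function(i) paste(c(rownames(m)[i], fmt(m[i, ])), collapse = sep),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a clock model object
#'
#' A clock model is a sparse linear predictor of gestational age (weeks):
#' intercept plus a weighted sum of beta values at its CpG probes. The same
#' container carries any published coefficient table (e.g. other placental or
#' cord-blood clocks) for comparison via [predict_ga()].
#'
#' @param name Model name.
#' @param intercept Intercept (weeks).
#' @param coefficients Named numeric vector, probe id -> weight (weeks per
#'   unit beta). Zero entries are dropped.
#' @param alpha,lambda Elastic-net mixing and shrinkage parameters used in
#'   training, `NA` for externally supplied tables.
#' @param training Optional free-form list describing the training run.
#' @return Object of class `clock_model` with element `n_features`, the
#'   number of nonzero coefficients.
#' @export
clock_model <- function(name, intercept, coefficients,
                        alpha = NA_real_, lambda = NA_real_, training = NULL) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be a named vector keyed by probe id")
  coefficients <- coefficients[coefficients != 0]
  if (anyDuplicated(names(coefficients)))
    stop("duplicate probe id(s) in coefficients: ",
         paste(unique(names(coefficients)[duplicated(names(coefficients))]),
               collapse = ", "))
  structure(list(name = as.character(name),
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 alpha = as.numeric(alpha),
                 lambda = as.numeric(lambda),
                 n_features = length(coefficients),
                 training = training),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock '%s': intercept %.4g weeks, %d CpG(s)\n",
              x$name, x$intercept, x$n_features))
  if (!is.na(x$alpha))
    cat(sprintf("  elastic net: alpha = %g, lambda = %.4g\n", x$alpha, x$lambda))
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.clock_model <- function(object, ...) {
  cf <- object$coefficients
  cat(sprintf("Clock '%s'\n  CpGs: %d  intercept: %.4g weeks\n",
              object$name, object$n_features, object$intercept))
  if (length(cf))
    cat(sprintf("  coefficient range: [%.4g, %.4g], %d positive / %d negative\n",
                min(cf), max(cf), sum(cf > 0), sum(cf < 0)))
  if (!is.null(object$training$filter))
    cat("  training filter:", object$training$filter, "\n")
  invisible(object)
}

#' Read a clock coefficient file
#'
#' Expects the conventional layout of published clock supplements: a CSV with
#' header `CpG,Coefficient` and the intercept row labelled `(Intercept)`.
#'
#' @param path CSV file path.
#' @param name Model name; defaults to the file stem.
#' @param require_intercept If `TRUE` (default) a missing intercept row is an
#'   error; if `FALSE` the intercept falls back to zero.
#' @return A [clock_model()].
#' @export
read_clock <- function(path, name = NULL, require_intercept = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("clock file must have two columns: CpG, Coefficient")
  ids <- as.character(df[[1L]])
  raw <- df[[2L]]
  if (length(ids) == 0L) stop("clock file has no coefficient rows: ", path)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals))
    stop("non-numeric coefficient for row(s): ",
         paste(ids[is.na(vals)], collapse = ", "))
  is_int <- ids == "(Intercept)"
  if (sum(is_int) > 1L) stop("multiple (Intercept) rows")
  if (!any(is_int) && require_intercept)
    stop("clock file lacks an (Intercept) row: ", path)
  intercept <- if (any(is_int)) vals[is_int] else 0
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  clock_model(name, intercept, setNames(vals[!is_int], ids[!is_int]))
}

#' Write a clock coefficient file
#'
#' Zero-valued coefficients are dropped on write; the file round-trips
#' through [read_clock()] with identical intercept and coefficients.
#'
#' @param model A [clock_model()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  cf <- model$coefficients[model$coefficients != 0]
  lines <- c("CpG,Coefficient",
             sprintf("(Intercept),%.17g", model$intercept),
             sprintf("%s,%.17g", names(cf), cf))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `ga_weeks`, `sex`, `condition`,
#'   `stratum`, `platform` (only `sample_id` is mandatory; absent columns are
#'   filled with defaults).
#' @return Data frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample sheet needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!"ga_weeks" %in% names(df)) df$ga_weeks <- NA_real_
  df$ga_weeks <- as.numeric(df$ga_weeks)
  bad <- !is.na(df$ga_weeks) & (df$ga_weeks <= 0 | df$ga_weeks >= 50)
  if (any(bad))
    stop("ga_weeks out of (0, 50) for: ", paste(df$sample_id[bad], collapse = ", "))
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  if (!"condition" %in% names(df)) df$condition <- "control"
  if (!"stratum" %in% names(df)) df$stratum <- NA_character_
  if (!"platform" %in% names(df)) df$platform <- "other"
  df
}

#' Write a sample sheet
#' @param sheet Data frame as returned by [read_sample_sheet()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, na = "")
  invisible(path)
}

.island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

#' Read a probe manifest
#'
#' @param path CSV with columns `probe_id`, `chromosome` ("1".."22","X","Y"),
#'   `island_relation` (Island/N_Shore/S_Shore/N_Shelf/S_Shelf/OpenSea) and
#'   `genes` (semicolon-joined symbols).
#' @return Data frame with `genes` kept as the semicolon-joined string.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome")
  if (!all(need %in% names(df)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id(s) in manifest: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  df$chromosome <- as.character(df$chromosome)
  if (!"island_relation" %in% names(df)) df$island_relation <- NA_character_
  known <- is.na(df$island_relation) | df$island_relation %in% .island_levels
  if (!all(known))
    stop("unknown island_relation value(s): ",
         paste(unique(df$island_relation[!known]), collapse = ", "))
  if (!"genes" %in% names(df)) df$genes <- ""
  df$genes[is.na(df$genes)] <- ""
  df
}

#' Write a probe manifest
#' @param manifest Data frame as returned by [read_manifest()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}
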