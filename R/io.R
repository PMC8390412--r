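#' Default column mapping for measure tables
#'
#' @param ... Overrides, e.g. `phenotype = "irt_score"`, or `pcs = c(...)`
#'   with five principal-component column names.
#' @return Named list mapping measure-table roles to input column names.
#' @export
measure_columns <- function(...) {
  cols <- list(person = "person", family = "family", age = "age",
               phenotype = "phenotype", pgs = "pgs", sex = "sex",
               array = "array", pcs = paste0("pc", 1:5), wave = "wave")
  over <- list(...)
  bad <- setdiff(names(over), names(cols))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  cols[names(over)] <- over
  if (length(cols$pcs) != 5) stop("pcs mapping must name 5 columns")
  cols
}

#' Read and validate a measure table
#'
#' Reads a CSV or TSV (by extension) with a header, maps input columns onto
#' the measure-table roles, coerces types, drops (and counts) rows with
#' missing values in model columns, and rejects duplicated (person, wave)
#' rows.
#'
#' @param path Path to a delimited file with a header row.
#' @param columns Column mapping from [measure_columns()]. The `wave`
#'   mapping is optional in the file; all other roles are required.
#' @return Measure table with canonical column names and attribute
#'   `n_dropped` (rows removed for missing model fields).
#' @export
read_measures <- function(path, columns = measure_columns()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(unlist(columns[c("person", "family", "age", "phenotype", "pgs",
                             "sex", "array")], use.names = FALSE),
            columns$pcs)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("schema error: input is missing mapped column(s): ",
         paste(absent, collapse = ", "))
  out <- data.frame(
    person = as.character(raw[[columns$person]]),
    family = as.character(raw[[columns$family]]),
    age = as.numeric(raw[[columns$age]]),
    phenotype = as.numeric(raw[[columns$phenotype]]),
    pgs = as.numeric(raw[[columns$pgs]]),
    sex = as.numeric(raw[[columns$sex]]),
    array = as.character(raw[[columns$array]]),
    stringsAsFactors = FALSE
  )
  for (i in 1:5) out[[paste0("pc", i)]] <- as.numeric(raw[[columns$pcs[i]]])
  has_wave <- columns$wave %in% names(raw)
  if (has_wave) out$wave <- as.character(raw[[columns$wave]])

  model_cols <- setdiff(names(out), "wave")
  ok <- stats::complete.cases(out[model_cols])
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(n_dropped, " row(s) dropped for missing model fields")
  out <- out[ok, , drop = FALSE]
  if (has_wave && anyDuplicated(out[c("person", "wave")]))
    stop("duplicate (person, wave) rows in input")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# full-precision numeric formatting so TSV output round-trips exactly;
# locale-independent decimal point
fmt_full <- function(x) {
  if (is.double(x)) vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), "") else as.character(x)
}

write_tsv_full <- function(df, path) {
  out <- df
  for (cl in names(out)) out[[cl]] <- fmt_full(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write rolling-analysis outputs
#'
#' Writes `rolling_results.tsv` (one row per focus age, full numeric
#' precision so a round-trip read reproduces the values exactly),
#' `pooled_fit.tsv` (term, estimate, SE, z, p of the pooled model), and
#' `run_log.json` (configuration echo, seed, variance components, package
#' version) into `outdir`.
#'
#' @param results A non-empty `rolling_result`.
#' @param fit The pooled `wlmm_fit` (optional, `NULL` to skip).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, fit = NULL, outdir) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty results; nothing written")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, "rolling_results.tsv")
  write_tsv_full(as.data.frame(results), paths)
  log <- list(config = attr(results, "config"),
              failures = attr(results, "failures"),
              package_version = as.character(utils::packageVersion("rollscore")),
              r_version = R.version.string)
  if (!is.null(fit)) {
    pf <- file.path(outdir, "pooled_fit.tsv")
    write_tsv_full(summary(fit)$coefficients, pf)
    paths <- c(paths, pf)
    log$pooled <- list(var_family = fit$var_family,
                       var_slope = fit$var_slope, sigma2 = fit$sigma2,
                       logLik = fit$logLik, method = fit$method,
                       pseudo_r2 = fit$pseudo_r2)
  }
  lp <- file.path(outdir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, lp))
}

#' Read back a rolling-results table
#'
#' @param path Path to a `rolling_results.tsv` written by [write_results()].
#' @return Data frame with the rolling-result columns at full precision.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}
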