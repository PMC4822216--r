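#' Write a result object to disk
#'
#' Serializes any result produced by this package — a `curve_fit`, an
#' `efficiency_estimate`, an `ancova_fit`, an `efficiency_distribution`,
#' or a plain results tibble (distribution summary, volume comparison,
#' fold-change table) — as JSON, CSV or a plain-text report. JSON keeps
#' full floating-point precision, so a written estimate re-parses to the
#' original values; text reports round to 2 decimals for reading.
#'
#' @param results A result object from this package.
#' @param path Output path.
#' @param format One of `"json"`, `"csv"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("cannot write to ", path, ": no such directory"))
  switch(
    format,
    json = jsonlite::write_json(report_payload(results), path,
                                auto_unbox = TRUE, digits = NA, na = "null"),
    csv = readr::write_csv(report_table(results), path, progress = FALSE),
    text = writeLines(utils::capture.output(print(results)), path)
  )
  invisible(path)
}

# Plain-list view of a result, suitable for lossless JSON round-tripping.
report_payload <- function(results) {
  if (inherits(results, "curve_fit")) {
    results[c("target", "group", "slope", "intercept", "se_slope",
              "se_intercept", "n_points", "df", "r_squared", "residual_sd",
              "n_excluded")]
  } else if (inherits(results, "efficiency_estimate")) {
    unclass(results)
  } else if (inherits(results, "ancova_fit")) {
    list(target = results$target, factor = results$factor_field,
         terms = results$terms, sse_full = results$sse_full,
         df_residual = results$df_residual, per_level = results$per_level)
  } else if (inherits(results, "efficiency_distribution")) {
    list(k = attr(results, "k"), seed = attr(results, "seed"),
         exhaustive = attr(results, "exhaustive"),
         n_resamples = nrow(results),
         quantile_type = 7L,
         efficiencies = results$efficiency)
  } else if (inherits(results, "simulated_series")) {
    list(truth = unclass(results$truth),
         per_step_mean_copies = results$per_step_mean_copies,
         table = dplyr::select(tibble::as_tibble(results$table),
                               -dplyr::any_of("draw")))
  } else if (is.data.frame(results)) {
    tibble::as_tibble(results)
  } else {
    abort("write_report does not know this result type")
  }
}

# Tabular view for CSV output.
report_table <- function(results) {
  if (inherits(results, c("curve_fit", "efficiency_estimate", "ancova_fit"))) {
    tidy(results)
  } else if (inherits(results, "simulated_series")) {
    dplyr::select(tibble::as_tibble(results$table), -dplyr::any_of("draw"))
  } else if (is.data.frame(results)) {
    dplyr::select(tibble::as_tibble(results), -dplyr::any_of("draw"))
  } else {
    abort("write_report does not know this result type")
  }
}
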