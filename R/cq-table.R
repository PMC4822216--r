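#' Assemble and validate a table of Cq measurements
#'
#' A Cq table is a long-format tibble with one row per qPCR reaction:
#' columns `target`, `group` (optional factor level such as the instrument
#' or dilution-series id), `dilution_step` (0 = undiluted stock),
#' `log10_rel_conc` (log10 of relative concentration; the stock is coded
#' `stock_log10` and every 10-fold dilution subtracts 1), `replicate`
#' (1-based index within a (target, group, step) cell) and `cq`
#' (quantification cycle, `NA` for reactions that never crossed threshold).
#' Missing Cq values are kept as explicit rows: dropping them silently would
#' understate replicate scatter, which is exactly the failure mode the
#' missing-data bookkeeping here is meant to expose.
#'
#' @param data A data frame with at least `target`, `dilution_step`,
#'   `replicate` and `cq` columns. `group` defaults to `""` when absent;
#'   `log10_rel_conc` is derived from `dilution_step` when absent.
#' @param stock_log10 log10 relative concentration assigned to the stock
#'   (dilution step 0). Relative, not absolute: only concentration ratios
#'   matter for the efficiency estimate.
#' @param dilution_factor Fold-dilution between successive steps, used when
#'   `log10_rel_conc` must be derived.
#'
#' @return A tibble of class `cq_table`, validated (unique reaction keys,
#'   concentration strictly decreasing with dilution step, positive finite
#'   Cq where present).
#' @examples
#' cq_table(data.frame(
#'   target = "18S", dilution_step = rep(0:5, each = 2),
#'   replicate = rep(1:2, 6), cq = 15 + 3.32 * rep(0:5, each = 2)
#' ))
#' @export
cq_table <- function(data, stock_log10 = 6, dilution_factor = 10) {
  stopifnot(is.data.frame(data))
  needed <- c("target", "dilution_step", "replicate", "cq")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cq_table input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  if (!"group" %in% names(out)) out$group <- ""
  if (!"log10_rel_conc" %in% names(out)) {
    out$log10_rel_conc <- stock_log10 - out$dilution_step * log10(dilution_factor)
  }
  core <- c("target", "group", "dilution_step", "log10_rel_conc",
            "replicate", "cq")
  out <- out[c(core, setdiff(names(out), core))]
  out$target <- as.character(out$target)
  out$group <- as.character(out$group)
  out$dilution_step <- as.integer(out$dilution_step)
  out$replicate <- as.integer(out$replicate)
  out$cq <- as.numeric(out$cq)
  validate_cq_table(out)
  class(out) <- c("cq_table", class(out))
  out
}

#' Validate the invariants of a Cq table
#'
#' Checks reaction-key uniqueness, that `log10_rel_conc` strictly decreases
#' with `dilution_step` within each (target, group) series, and that present
#' Cq values are finite and positive. Called by [cq_table()] and
#' [read_cq_table()]; exported so externally assembled tables can be checked.
#'
#' @param data A data frame shaped like a Cq table.
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_cq_table <- function(data) {
  key <- paste(data$target, data$group, data$dilution_step, data$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    abort(sprintf(
      "duplicate reaction key (target=%s, group=%s, step=%d, replicate=%d) at row %d",
      data$target[dup], data$group[dup], data$dilution_step[dup],
      data$replicate[dup], dup
    ))
  }
  bad_cq <- !is.na(data$cq) & (!is.finite(data$cq) | data$cq <= 0)
  if (any(bad_cq)) {
    abort(sprintf("non-finite or non-positive Cq at row %d",
                  which(bad_cq)[1]))
  }
  series <- paste(data$target, data$group, sep = "\r")
  o <- order(series, data$dilution_step, method = "radix")
  s <- series[o]
  st <- data$dilution_step[o]
  cc <- data$log10_rel_conc[o]
  n <- length(s)
  if (n > 1) {
    same <- s[-1] == s[-n]
    dconc <- cc[-1] - cc[-n]
    dstep <- st[-1] - st[-n]
    # within a series: concentration strictly decreasing as the step grows,
    # and constant within a step
    viol <- same & ((dstep > 0 & dconc >= 0) | (dstep == 0 & dconc != 0))
    if (any(viol)) {
      i <- o[which(viol)[1] + 1]
      abort(sprintf(
        "log10_rel_conc is not strictly decreasing with dilution_step for target=%s group=%s",
        data$target[i], data$group[i]
      ))
    }
  }
  invisible(data)
}

#' Read Cq measurements from a CSV file
#'
#' Expects a comma-separated, UTF-8 file with a header. Column names are
#' mapped onto the Cq-table fields via `columns`; cells in the `cq` column
#' matching one of `missing_markers` (after trimming whitespace) become
#' explicit missing records — rows are never dropped. Any other
#' non-numeric Cq cell is a parse error naming the offending row.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping Cq-table fields to the
#'   file's header names.
#' @param missing_markers Cell values treated as "no Cq" (reaction never
#'   crossed threshold). `">40"` covers the common instrument convention of
#'   censoring at the cycle limit.
#' @inheritParams cq_table
#' @return A validated [cq_table()] with exactly one row per file row.
#' @export
read_cq_table <- function(path,
                          columns = c(target = "target", group = "group",
                                      dilution_step = "dilution_step",
                                      log10_rel_conc = "log10_rel_conc",
                                      replicate = "replicate", cq = "cq"),
                          missing_markers = c("", "NA", "NaN", ">40"),
                          stock_log10 = 6, dilution_factor = 10) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  present <- columns[columns %in% names(raw)]
  needed <- c("target", "dilution_step", "replicate", "cq")
  if (!all(needed %in% names(present))) {
    abort(paste0("CSV header lacks required column(s): ",
                 paste(columns[setdiff(needed, names(present))], collapse = ", ")))
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (field in names(present)) out[[field]] <- raw[[present[[field]]]]

  parse_num <- function(x, field) {
    val <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(val) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("malformed numeric value '%s' in column '%s' at data row %d",
                    x[bad[1]], field, bad[1]))
    }
    val
  }
  cq_raw <- trimws(out$cq)
  is_missing <- is.na(cq_raw) | cq_raw %in% missing_markers
  out$cq <- NA_real_
  out$cq[!is_missing] <- parse_num(cq_raw[!is_missing], "cq")
  out$dilution_step <- parse_num(out$dilution_step, "dilution_step")
  out$replicate <- parse_num(out$replicate, "replicate")
  if ("log10_rel_conc" %in% names(out)) {
    out$log10_rel_conc <- parse_num(out$log10_rel_conc, "log10_rel_conc")
  }
  cq_table(out, stock_log10 = stock_log10, dilution_factor = dilution_factor)
}

#' Write a Cq table to CSV
#'
#' Missing Cq values are written as empty cells, so a write/read cycle
#' preserves the table (numeric values to 6 significant digits or better).
#'
#' @param data A Cq table (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(data, path) {
  core <- c("target", "group", "dilution_step", "log10_rel_conc",
            "replicate", "cq")
  readr::write_csv(as.data.frame(data)[intersect(c(core, names(data)), names(data))],
                   path, na = "", progress = FALSE)
  invisible(path)
}

n_missing_cq <- function(data) sum(is.na(data$cq))

#' @export
print.cq_table <- function(x, ...) {
  n_miss <- n_missing_cq(x)
  cat(sprintf(
    "<cq_table> %d reactions, %d target(s), %d group(s), %d missing Cq\n",
    nrow(x), dplyr::n_distinct(x$target), dplyr::n_distinct(x$group), n_miss
  ))
  NextMethod()
}
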