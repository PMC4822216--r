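#' Fold change implied by a Cq difference
#'
#' Relative quantification converts a Cq difference between two conditions
#' into a fold change through the amplification efficiency:
#' `FC = (1 + E)^dCq`. At perfect doubling (E = 1), each Cq of separation
#' is a factor of two.
#'
#' @param efficiency Amplification efficiency, > 0.
#' @param delta_cq Cq difference between the conditions (cycles).
#' @param exponent_offset Subtracted from `delta_cq` in the exponent; 0 by
#'   default. Set to 1 to use the single-stranded-template convention in
#'   which the first cycle creates the complement rather than doubling.
#' @return The fold change.
#' @examples
#' fold_change(1, 10)    # 1024
#' fold_change(0.8, 10)  # about 357
#' @export
fold_change <- function(efficiency, delta_cq, exponent_offset = 0) {
  if (any(efficiency <= 0)) abort("efficiency must be > 0")
  (1 + efficiency)^(delta_cq - exponent_offset)
}

#' Fold-change error from efficiency misestimation
#'
#' Ratio of the fold change computed with an assumed efficiency to the one
#' implied by the true efficiency, for the same Cq difference:
#' `(1 + E_assumed)^dCq / (1 + E_true)^dCq`. A value of 1.67 means the
#' reported fold change overstates the truth by 67%. The error grows
#' geometrically with `delta_cq`, which is why efficiency precision matters
#' most for large expression differences.
#'
#' @param efficiency_true Efficiency that generated the data, > 0.
#' @param efficiency_assumed Efficiency used in the calculation, > 0.
#' @inheritParams fold_change
#' @return The multiplicative error ratio (1 = unbiased).
#' @examples
#' fold_change_error(0.9, 1.0, 10)  # about 1.67
#' @export
fold_change_error <- function(efficiency_true, efficiency_assumed, delta_cq,
                              exponent_offset = 0) {
  fold_change(efficiency_assumed, delta_cq, exponent_offset) /
    fold_change(efficiency_true, delta_cq, exponent_offset)
}

#' Fold-change error over a grid of efficiencies and Cq differences
#'
#' Tabulates [fold_change()] and [fold_change_error()] over the cross
#' product of assumed efficiencies and Cq differences at a fixed true
#' efficiency — the numbers behind an impact-of-misestimation figure.
#'
#' @inheritParams fold_change_error
#' @param efficiency_assumed Vector of assumed efficiencies.
#' @param delta_cq Vector of Cq differences.
#' @return A tibble with one row per grid point: `delta_cq`,
#'   `efficiency_assumed`, `efficiency_true`, `fold_change_true`,
#'   `fold_change_assumed`, `error_ratio`, `error_pct`
#'   (`100 * (error_ratio - 1)`).
#' @export
fold_change_table <- function(efficiency_true, efficiency_assumed, delta_cq,
                              exponent_offset = 0) {
  grid <- tidyr::expand_grid(delta_cq = delta_cq,
                             efficiency_assumed = efficiency_assumed)
  grid |>
    dplyr::mutate(
      efficiency_true = efficiency_true,
      fold_change_true = fold_change(efficiency_true, .data$delta_cq,
                                     exponent_offset),
      fold_change_assumed = fold_change(.data$efficiency_assumed,
                                        .data$delta_cq, exponent_offset),
      error_ratio = .data$fold_change_assumed / .data$fold_change_true,
      error_pct = 100 * (.data$error_ratio - 1)
    )
}
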