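#' Published stage-by-class spine rates (partial)
#'
#' The printed summary values for granule-cell spine density in the eel
#' olfactory bulb: per-stage mean densities (spines/10 um) for the classes
#' that were reported, the per-stage totals, and the pooled (across-stage)
#' class means. Cells that were never printed are `NA`; they are filled by
#' [calibrate_rate_table()].
#'
#' @return List with `rates` (4 x 4 matrix, rows = stages glass/elver/
#'   yellow/silver, columns = classes M/LT/S/F, `NA` where unprinted),
#'   `totals` (per-stage totals) and `pooled` (per-class pooled means).
#' @export
printed_spine_rates <- function() {
  stages <- c("glass", "elver", "yellow", "silver")
  rates <- matrix(NA_real_, nrow = 4, ncol = 4,
                  dimnames = list(stages, SPINE_CLASSES))
  rates["glass", c("M", "LT", "F")] <- c(2.65, 2.60, 0.18)
  rates["elver", "M"] <- 2.33
  rates["yellow", c("M", "S")] <- c(1.50, 1.28)
  rates["silver", c("M", "S")] <- c(2.52, 1.65)
  list(
    rates = rates,
    totals = c(glass = 6.67, elver = 4.45, yellow = 3.73, silver = 5.71),
    pooled = c(M = 2.25, LT = 1.51, S = 1.31, F = 0.07)
  )
}

#' Calibrate a complete stage-by-class rate table from printed values
#'
#' Fills the unprinted cells of the published stage-by-class mean-rate
#' matrix under three constraints: (a) each stage's class rates sum to its
#' printed total; (b) the pooled (balanced across-stage) class means match
#' the printed pooled values within +-0.02 (+-0.01 for F); (c) the
#' qualitative equalities reported alongside the means hold (elver S = LT;
#' the filopodium rate decreases across stages towards zero).
#'
#' The fill proceeds in two steps. First, missing filopodium cells share
#' the pooled-F residual `4 * pooled_F - sum(printed F)` in fixed
#' decreasing proportions (`f_split`, default 0.6/0.3/0.1 in stage order),
#' reflecting the reported progressive disappearance of filopodia. Second,
#' each stage's remaining residual (total minus known cells) is assigned to
#' its single missing cell, or split equally when two cells (S and LT) are
#' missing, which enforces the reported S = LT equalities.
#'
#' @param printed printed values as returned by [printed_spine_rates()].
#' @param phi dispersion multiplier attached to the table (variance =
#'   `phi * mean` for per-class segment counts; 1 = Poisson).
#' @param f_split proportions (summing to 1) in which the pooled-F residual
#'   is shared among stages with an unprinted F rate, in stage order.
#' @return An object of class `"stage_rate_table"`: list with `rates`
#'   (complete 4 x 4 matrix), `provenance` (matrix of `"printed"` /
#'   `"derived"` tags), `totals`, `pooled`, `phi`.
#' @examples
#' rt <- calibrate_rate_table()
#' rowSums(rt$rates)  # the printed stage totals
#' @export
calibrate_rate_table <- function(printed = printed_spine_rates(), phi = 1,
                                 f_split = c(0.6, 0.3, 0.1)) {
  if (phi <= 0) stop("phi must be positive")
  rates <- printed$rates
  totals <- printed$totals
  pooled <- printed$pooled
  prov <- ifelse(is.na(rates), "derived", "printed")
  stages <- rownames(rates)
  if (any(rates > totals[stages], na.rm = TRUE))
    stop("infeasible printed values: a class mean exceeds its stage total")

  # step 1: pooled-F constraint shares the F residual across missing cells
  f_missing <- which(is.na(rates[, "F"]))
  if (length(f_missing)) {
    resid_f <- length(stages) * pooled["F"] -
      sum(rates[, "F"], na.rm = TRUE)
    if (resid_f < 0)
      stop("infeasible calibration: negative filopodium residual")
    w <- f_split[seq_along(f_missing)]
    rates[f_missing, "F"] <- resid_f * w / sum(w)
  }

  # step 2: per-stage residual fill (single missing cell, or S = LT split)
  for (s in stages) {
    miss <- which(is.na(rates[s, ]))
    if (!length(miss)) next
    resid <- totals[s] - sum(rates[s, ], na.rm = TRUE)
    if (resid < 0)
      stop("infeasible calibration: negative residual for stage ", s)
    rates[s, miss] <- resid / length(miss)
  }

  out <- structure(
    list(rates = rates, provenance = prov, totals = totals,
         pooled = pooled, phi = phi),
    class = "stage_rate_table")
  validate_rate_table(out)
  out
}

#' Validate a stage-by-class rate table
#'
#' Checks the calibration invariants: all rates non-negative, row sums
#' match the stage totals within +-0.02, and pooled (balanced across-stage)
#' class means match the printed pooled values within +-0.02 (+-0.01 for
#' F).
#'
#' @param rt a `"stage_rate_table"`.
#' @return `rt`, invisibly; stops on violation.
#' @export
validate_rate_table <- function(rt) {
  stopifnot(inherits(rt, "stage_rate_table"))
  if (any(rt$rates < 0)) stop("rate table has negative rates")
  if (any(abs(rowSums(rt$rates) - rt$totals) > 0.02))
    stop("rate table rows do not sum to the stage totals")
  pooled_fit <- colMeans(rt$rates)
  tol <- c(M = 0.02, LT = 0.02, S = 0.02, F = 0.01)
  if (any(abs(pooled_fit - rt$pooled) > tol[names(pooled_fit)]))
    stop("pooled class means drift from the printed pooled values")
  invisible(rt)
}

#' Build a rate table directly from a rate matrix
#'
#' Used when rates are estimated from data (e.g. by
#' [simulate.spine_study()]) rather than calibrated from printed values.
#'
#' @param rates stage x class numeric matrix (columns M, LT, S, F).
#' @param phi dispersion multiplier (variance = `phi * mean`).
#' @return A `"stage_rate_table"` whose totals/pooled are recomputed from
#'   `rates`.
#' @export
as_rate_table <- function(rates, phi = 1) {
  if (phi <= 0) stop("phi must be positive")
  rates <- as.matrix(rates[, SPINE_CLASSES, drop = FALSE])
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("rates must be finite and non-negative")
  structure(
    list(rates = rates,
         provenance = matrix("derived", nrow(rates), ncol(rates),
                             dimnames = dimnames(rates)),
         totals = rowSums(rates), pooled = colMeans(rates), phi = phi),
    class = "stage_rate_table")
}

#' @export
print.stage_rate_table <- function(x, ...) {
  cat("stage_rate_table (spines/10 um, phi =", x$phi, ")\n")
  m <- cbind(round(x$rates, 3), total = round(rowSums(x$rates), 3))
  print(m)
  derived <- which(x$provenance == "derived", arr.ind = TRUE)
  if (nrow(derived))
    cat("derived cells:",
        paste(rownames(x$rates)[derived[, 1]],
              colnames(x$rates)[derived[, 2]], sep = ":", collapse = ", "),
        "\n")
  invisible(x)
}
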