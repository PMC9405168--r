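#' Spine class labels
#'
#' The four morphological classes: mushroom (M), long thin (LT), stubby
#' (S) and filopodium (F).
#' @export
SPINE_CLASSES <- c("M", "LT", "S", "F")

#' Classify one spine from its metrics
#'
#' Deterministic rule-based classification from head/neck geometry:
#' \itemize{
#'   \item headed, neck diameter greater than neck length: mushroom (M);
#'   \item headed, neck length greater than or equal to its diameter:
#'     long thin (LT) — ties go to LT because M requires a strictly
#'     thicker-than-long neck;
#'   \item headless, total length under 1 um: stubby (S);
#'   \item headless, total length over `headless_filopodium_min_length`
#'     (default 10 um): filopodium (F);
#'   \item headless, in between: assigned to S but flagged as "extended"
#'     (`gap_flag = TRUE`), because the printed criteria leave headless
#'     protrusions of 1-10 um unassigned. The flag keeps the partition
#'     exhaustive while making the ambiguity auditable.
#' }
#'
#' @param metrics a [spine_metrics()] object.
#' @param headless_filopodium_min_length headless protrusions strictly
#'   longer than this (um) are filopodia. Default 10 um.
#' @return An object of class `"spine_class"`: list with `label` (one of
#'   `"M"`, `"LT"`, `"S"`, `"F"`) and `extended` (logical gap flag, only
#'   ever TRUE for S).
#' @examples
#' classify_spine(spine_metrics(1.2, TRUE, head_diameter = 0.8,
#'                              neck_max_diameter = 0.4, neck_length = 0.3))
#' @export
classify_spine <- function(metrics, headless_filopodium_min_length = 10) {
  stopifnot(inherits(metrics, "spine_metrics"))
  if (metrics$has_head) {
    label <- if (metrics$neck_max_diameter > metrics$neck_length) "M" else "LT"
    extended <- FALSE
  } else if (metrics$total_length < 1) {
    label <- "S"; extended <- FALSE
  } else if (metrics$total_length > headless_filopodium_min_length) {
    label <- "F"; extended <- FALSE
  } else {
    label <- "S"; extended <- TRUE
  }
  structure(list(label = label, extended = extended), class = "spine_class")
}

#' @export
print.spine_class <- function(x, ...) {
  cat(x$label, if (x$extended) "(extended stubby, gap rule)" else "", "\n")
  invisible(x)
}

#' Classify a table of spines
#'
#' Vectorised classification over a spine geometry table (the TSV layout of
#' [read_spine_table()]). Appends a `class` column (M/LT/S/F) and a
#' `gap_flag` column marking headless protrusions of 1-10 um assigned to S
#' by the gap rule.
#'
#' @param spines data frame with columns `total_length_um`, `has_head`,
#'   `head_diameter_um`, `neck_max_diameter_um`, `neck_length_um`.
#' @param headless_filopodium_min_length see [classify_spine()].
#' @return `spines` with `class` and `gap_flag` columns appended.
#' @export
classify_spines <- function(spines, headless_filopodium_min_length = 10) {
  need <- c("total_length_um", "has_head", "head_diameter_um",
            "neck_max_diameter_um", "neck_length_um")
  if (!all(need %in% names(spines)))
    stop("spine table must have columns ", paste(need, collapse = ", "))
  has_head <- as.logical(spines$has_head)
  label <- character(nrow(spines))
  gap <- logical(nrow(spines))
  headed_M <- has_head & spines$neck_max_diameter_um > spines$neck_length_um
  label[headed_M] <- "M"
  label[has_head & !headed_M] <- "LT"
  hl <- !has_head
  label[hl & spines$total_length_um < 1] <- "S"
  label[hl & spines$total_length_um > headless_filopodium_min_length] <- "F"
  in_gap <- hl & spines$total_length_um >= 1 &
    spines$total_length_um <= headless_filopodium_min_length
  label[in_gap] <- "S"
  gap[in_gap] <- TRUE
  spines$class <- factor(label, levels = SPINE_CLASSES)
  spines$gap_flag <- gap
  spines
}

#' Class counts for a set of spines
#'
#' @param spines data frame already carrying `class`/`gap_flag` columns, or
#'   raw metrics columns (then classified first).
#' @param ... passed to [classify_spines()] when classification is needed.
#' @return Named integer vector with counts for M, LT, S, F, the number of
#'   gap-rule ("extended") stubby spines, and the total.
#' @export
count_classes <- function(spines, ...) {
  if (!("class" %in% names(spines))) spines <- classify_spines(spines, ...)
  cls <- factor(spines$class, levels = SPINE_CLASSES)
  counts <- as.integer(table(cls))
  names(counts) <- SPINE_CLASSES
  c(counts,
    S_extended = sum(spines$gap_flag %||% FALSE),
    total = nrow(spines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
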