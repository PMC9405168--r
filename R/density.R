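#' Per-segment spine densities
#'
#' Converts spine counts on each dendritic segment into densities per
#' 10 um of dendritic arc length, per class and in total. Densities are
#' normalised by each segment's actual arc length (segments are traced "at
#' least 10 um" long, so lengths vary): `density = count / arc_length *
#' 10`. Gap-rule stubby spines (`gap_flag`) count toward S and toward the
#' total, and their tally is carried separately for auditing.
#'
#' @param segments data frame with columns `segment_id`, `stage`,
#'   `arc_length_um` (and optionally `animal_id`).
#' @param spines classified spine table ([classify_spines()]) with columns
#'   `segment_id`, `class`, `gap_flag`. Spines whose `segment_id` is not in
#'   `segments` are an error.
#' @param min_length segments shorter than this (um) are rejected unless
#'   `allow_short = TRUE`; reflects the tracing rule that segments are at
#'   least 10 um long.
#' @param allow_short set TRUE to accept segments shorter than
#'   `min_length`.
#' @return Data frame with one row per segment: counts (`count_M` ...
#'   `count_F`, `count_S_extended`, `count_total`) and densities
#'   (`density_M` ... `density_F`, `density_total`, spines/10 um).
#' @examples
#' seg <- data.frame(segment_id = "s1", stage = "glass", arc_length_um = 12.5)
#' sp <- data.frame(segment_id = rep("s1", 8),
#'                  class = factor(c(rep("M", 4), rep("LT", 3), "S"),
#'                                 levels = SPINE_CLASSES),
#'                  gap_flag = FALSE)
#' segment_density(seg, sp)$density_total  # 6.4
#' @export
segment_density <- function(segments, spines, min_length = 10,
                            allow_short = FALSE) {
  need <- c("segment_id", "stage", "arc_length_um")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(segments$arc_length_um) | segments$arc_length_um <= 0))
    stop("segment arc lengths must be positive")
  if (!allow_short && any(segments$arc_length_um < min_length))
    stop("segment(s) shorter than ", min_length,
         " um; traced segments must be at least that long ",
         "(use allow_short = TRUE to override)")
  if (!all(c("class", "gap_flag") %in% names(spines)))
    stop("spines must be classified first (see classify_spines)")
  if (nrow(spines) && !all(spines$segment_id %in% segments$segment_id))
    stop("spine table references unknown segment_id(s)")

  sid <- factor(spines$segment_id, levels = segments$segment_id)
  cls <- factor(spines$class, levels = SPINE_CLASSES)
  counts <- table(sid, cls)
  out <- segments[, intersect(c("segment_id", "stage", "animal_id",
                                "arc_length_um"), names(segments)),
                  drop = FALSE]
  for (c in SPINE_CLASSES) out[[paste0("count_", c)]] <- as.integer(counts[, c])
  out$count_S_extended <-
    as.integer(table(factor(spines$segment_id[spines$gap_flag],
                            levels = segments$segment_id)))
  out$count_total <- as.integer(rowSums(counts))
  scale <- 10 / out$arc_length_um
  for (c in SPINE_CLASSES)
    out[[paste0("density_", c)]] <- out[[paste0("count_", c)]] * scale
  out$density_total <- out$count_total * scale
  rownames(out) <- NULL
  out
}

#' Stage-by-class summary of spine densities
#'
#' Mean, standard error (sample SD / sqrt(n)) and n of per-segment
#' densities, for every stage x class cell, per-stage totals, and pooled
#' across-stage class means (pooled over all segments; for a balanced
#' design this equals the average of the stage means).
#'
#' @param density data frame of per-segment densities
#'   ([segment_density()]).
#' @return Data frame in long form: `stage` (a stage name or `"pooled"`),
#'   `measure` (`"M"`, `"LT"`, `"S"`, `"F"` or `"total"`), `mean`, `se`,
#'   `n`. Class `"stage_summary"`.
#' @export
stage_summary <- function(density) {
  if (!nrow(density)) stop("no density records")
  stages <- unique(as.character(density$stage))
  n_by_stage <- table(factor(density$stage, levels = stages))
  if (any(n_by_stage < 2L))
    stop("standard error undefined: stage(s) with fewer than 2 segments: ",
         paste(names(n_by_stage)[n_by_stage < 2L], collapse = ", "))
  measures <- c(SPINE_CLASSES, "total")
  rows <- list()
  for (s in c(stages, "pooled")) {
    sel <- if (s == "pooled") rep(TRUE, nrow(density))
           else density$stage == s
    for (m in measures) {
      v <- density[[paste0("density_", m)]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        stage = s, measure = m, mean = mean(v),
        se = stats::sd(v) / sqrt(length(v)), n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stage_summary", "data.frame")
  out
}

#' Regressions of spine density on log-transformed biometrics
#'
#' Ordinary least-squares regression of per-animal mean spine density on
#' each of log10 total length (TL, cm), log10 total weight (TW, g) and
#' log10 brain weight (BW, g). The wide spread of body sizes across life
#' stages is down-weighted by the log transform. A correlation is flagged
#' significant only when R^2 >= 0.7 AND the slope's two-sided t-test p is
#' below `alpha`.
#'
#' @param animals data frame with columns `TL_cm`, `TW_g`, `BW_g` (all
#'   positive) and `mean_density` (per-animal mean total spine density,
#'   spines/10 um). At least 3 animals.
#' @param alpha significance level for the slope test (default 0.05).
#' @param r2_min minimum R^2 for the significance flag (default 0.7).
#' @return Data frame with one row per biometric: `metric`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `significant`.
#' @export
biometric_regressions <- function(animals, alpha = 0.05, r2_min = 0.7) {
  need <- c("TL_cm", "TW_g", "BW_g", "mean_density")
  if (!all(need %in% names(animals)))
    stop("animals must have columns ", paste(need, collapse = ", "))
  if (nrow(animals) < 3L) stop("need at least 3 animals")
  metrics <- c(TL = "TL_cm", TW = "TW_g", BW = "BW_g")
  rows <- lapply(names(metrics), function(mn) {
    x <- animals[[metrics[mn]]]
    if (any(!is.finite(x)) || any(x <= 0))
      stop("biometric ", metrics[mn], " must be positive")
    y <- animals$mean_density
    if (stats::sd(y) == 0) {
      # constant response: no explainable variance
      return(data.frame(metric = mn, slope = 0, intercept = y[1],
                        r_squared = 0, p_value = 1, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ log10(x))
    sm <- summary(fit)
    p <- sm$coefficients[2, 4]
    r2 <- sm$r.squared
    data.frame(metric = mn, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, p_value = p,
               significant = r2 >= r2_min && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
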