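#' Fit the spine-density study analysis
#'
#' The central analysis of the package: given classified (or classifiable)
#' spine tables on dendritic segments, it computes per-segment densities,
#' the stage-by-class summary (mean +- SE), and the full nonparametric
#' battery — for each stage a tie-corrected Kruskal-Wallis test across the
#' four spine classes with Dunn's pairwise Z post hoc, for each class (and
#' for the totals) the same across life stages — plus, when biometrics are
#' supplied, the regressions of per-animal mean density on log-transformed
#' body metrics. Normality of the total densities is checked with
#' Shapiro-Wilk but only reported: the pipeline always stays on the
#' nonparametric path.
#'
#' @param segments data frame (`segment_id`, `stage`, `arc_length_um`,
#'   optionally `animal_id`) or a `"study_dataset"` from
#'   [generate_study()] (then `spines`/`animals` are taken from it).
#' @param spines spine geometry table; classified with
#'   [classify_spines()] if it has no `class` column.
#' @param animals optional biometrics (`animal_id`, `TL_cm`, `TW_g`,
#'   `BW_g`); requires `animal_id` on the segments.
#' @param adjust multiplicity adjustment passed to [dunn_posthoc()].
#' @param allow_short accept segments shorter than 10 um.
#' @return An object of class `"spine_study"` with components `density`
#'   (per-segment densities), `summary` ([stage_summary()]),
#'   `tests` (`$by_stage`, `$by_class`, `$total`: each a list with `kw`
#'   and `dunn`), `normality`, `regressions` (or NULL), `adjust`, `call`.
#' @examples
#' ds <- generate_study(study_config(seed = 42, segments_per_stage = 30),
#'                      include_polylines = FALSE)
#' fit <- spine_study(ds)
#' coef(fit)
#' @export
spine_study <- function(segments, spines = NULL, animals = NULL,
                        adjust = c("none", "bonferroni", "holm"),
                        allow_short = FALSE) {
  adjust <- match.arg(adjust)
  cl <- match.call()
  if (inherits(segments, "study_dataset")) {
    ds <- segments
    segments <- ds$segments
    if (is.null(spines)) spines <- ds$spines
    if (is.null(animals)) animals <- ds$animals
  }
  if (is.null(spines)) stop("a spine table is required")
  if (!("class" %in% names(spines))) spines <- classify_spines(spines)
  density <- segment_density(segments, spines, allow_short = allow_short)
  summary_tab <- stage_summary(density)
  stages <- unique(as.character(density$stage))

  by_stage <- lapply(stages, function(s) {
    d <- density[density$stage == s, ]
    groups <- lapply(SPINE_CLASSES, function(c) d[[paste0("density_", c)]])
    names(groups) <- SPINE_CLASSES
    run_rank_battery(groups, adjust)
  })
  names(by_stage) <- stages

  stage_groups <- function(col) {
    g <- lapply(stages, function(s) density[[col]][density$stage == s])
    names(g) <- stages
    g
  }
  by_class <- lapply(SPINE_CLASSES, function(c)
    run_rank_battery(stage_groups(paste0("density_", c)), adjust))
  names(by_class) <- SPINE_CLASSES
  total <- run_rank_battery(stage_groups("density_total"), adjust)

  normality <- tryCatch(normality_check(density$density_total),
                        error = function(e) NULL)

  regressions <- NULL
  if (!is.null(animals) && "animal_id" %in% names(density)) {
    md <- tapply(density$density_total, density$animal_id, mean)
    an <- animals[animals$animal_id %in% names(md), , drop = FALSE]
    an$mean_density <- as.numeric(md[an$animal_id])
    regressions <- biometric_regressions(an)
    attr(regressions, "animals") <- an
  }

  structure(
    list(density = density, summary = summary_tab,
         tests = list(by_stage = by_stage, by_class = by_class,
                      total = total),
         normality = normality, regressions = regressions,
         adjust = adjust, stages = stages, call = cl),
    class = "spine_study")
}

# one KW + Dunn block; degenerate data (all values identical) propagates
# as a NULL kw with the message retained
run_rank_battery <- function(groups, adjust) {
  res <- tryCatch(
    list(kw = kruskal_wallis(groups),
         dunn = dunn_posthoc(groups, adjust = adjust),
         error = NULL),
    error = function(e) list(kw = NULL, dunn = NULL,
                             error = conditionMessage(e)))
  res
}

#' @export
print.spine_study <- function(x, ...) {
  cat("spine_study:", nrow(x$density), "segments,",
      length(x$stages), "stages\n")
  cat("\nMean total density (spines/10 um):\n")
  tot <- x$summary[x$summary$measure == "total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %-8s %5.2f +- %.2f  (n = %d)\n", tot$stage[i],
                tot$mean[i], tot$se[i], tot$n[i]))
  if (!is.null(x$tests$total$kw))
    cat(sprintf("\nTotal density across stages: H = %.2f, df = %d, p = %.3g %s\n",
                x$tests$total$kw$H, x$tests$total$kw$df, x$tests$total$kw$p,
                significance_code(x$tests$total$kw$p)))
  invisible(x)
}

#' @export
summary.spine_study <- function(object, ...) {
  structure(list(fit = object), class = "summary.spine_study")
}

#' @export
print.summary.spine_study <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nStage x class mean densities (spines/10 um):\n")
  print(round(coef(fit), 3))
  if (!is.null(fit$normality))
    cat(sprintf("\nShapiro-Wilk on total densities: W = %.3f, p = %.3g (%s)\n",
                fit$normality$W, fit$normality$p,
                if (fit$normality$is_normal) "consistent with normality"
                else "non-normal; rank tests used"))
  cat("\nDunn post hoc, total density across stages (adjust =",
      fit$adjust, "):\n")
  print(format_dunn(fit$tests$total$dunn))
  if (!is.null(fit$regressions)) {
    cat("\nRegressions of per-animal mean density on log10 biometrics:\n")
    r <- fit$regressions
    for (i in seq_len(nrow(r)))
      cat(sprintf("  %s: R^2 = %.3f, p = %.3g%s\n", r$metric[i],
                  r$r_squared[i], r$p_value[i],
                  if (r$significant[i]) " (significant)" else ""))
  }
  invisible(x)
}

format_dunn <- function(d) {
  if (is.null(d)) return(invisible(NULL))
  data.frame(pair = paste(d$group_a, d$group_b, sep = " - "),
             Z = round(d$Z, 3), p = signif(d$p_adjusted, 4),
             code = d$code)
}

#' Stage-by-class mean density matrix
#'
#' @param object a `"spine_study"` fit.
#' @param ... unused.
#' @return Numeric matrix, rows = stages, columns = M, LT, S, F, total
#'   (mean densities, spines/10 um).
#' @export
coef.spine_study <- function(object, ...) {
  s <- object$summary
  s <- s[s$stage != "pooled", ]
  stats::xtabs(mean ~ stage + measure, data = s)[
    object$stages, c(SPINE_CLASSES, "total"), drop = FALSE]
}

#' Simulate new studies from a fitted spine study
#'
#' Uses the fitted stage-by-class mean densities as the rate table of the
#' synthetic generator and draws `nsim` new studies of the same per-stage
#' segment counts.
#'
#' @param object a `"spine_study"` fit.
#' @param nsim number of studies.
#' @param seed integer seed (mandatory for reproducibility).
#' @param phi count dispersion for the simulated studies.
#' @param include_polylines passed to [generate_study()].
#' @param ... unused.
#' @return A list of `nsim` `"study_dataset"` objects.
#' @export
simulate.spine_study <- function(object, nsim = 1, seed, phi = 1,
                                 include_polylines = FALSE, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- coef(object)[, SPINE_CLASSES, drop = FALSE]
  rt <- as_rate_table(rates, phi = phi)
  n_per_stage <- as.integer(table(factor(object$density$stage,
                                         levels = object$stages)))
  lapply(seq_len(nsim), function(i)
    generate_study(
      study_config(stages = object$stages,
                   segments_per_stage = max(n_per_stage),
                   animals_per_stage = rep(1L, length(object$stages)),
                   seed = seed + i - 1L, phi = phi),
      rate_table = rt, include_polylines = include_polylines))
}

#' Bar plot of stage-by-class mean spine densities
#'
#' Grouped bars (one group per life stage, one bar per spine class) with
#' +- SE whiskers, in the layout of the study's density figures.
#'
#' @param x a `"spine_study"` fit.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.spine_study <- function(x, ...) {
  s <- x$summary[x$summary$stage != "pooled" &
                   x$summary$measure != "total", ]
  mean_m <- stats::xtabs(mean ~ measure + stage, data = s)[
    SPINE_CLASSES, x$stages, drop = FALSE]
  se_m <- stats::xtabs(se ~ measure + stage, data = s)[
    SPINE_CLASSES, x$stages, drop = FALSE]
  mids <- graphics::barplot(mean_m, beside = TRUE,
                            ylim = c(0, max(mean_m + se_m) * 1.15),
                            ylab = "spine density (spines/10 um)",
                            legend.text = rownames(mean_m),
                            args.legend = list(x = "topright", bty = "n"),
                            ...)
  graphics::arrows(mids, mean_m - se_m, mids, mean_m + se_m,
                   angle = 90, code = 3, length = 0.03)
  invisible(mids)
}
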