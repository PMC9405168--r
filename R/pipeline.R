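#' Read / write the pipeline's tab-separated tables
#'
#' The pipeline exchanges three plain TSV layouts:
#' \itemize{
#'   \item spine tables: `segment_id`, `stage`, `total_length_um`,
#'     `has_head`, `head_diameter_um`, `neck_max_diameter_um`,
#'     `neck_length_um` (plus `class`/`gap_flag` once classified);
#'   \item segment tables: `segment_id`, `stage`, `arc_length_um`
#'     (optionally `animal_id`);
#'   \item biometrics: `animal_id`, `stage`, `TL_cm`, `TW_g`, `BW_g`.
#' }
#'
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_spine_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "total_length_um", "has_head",
            "head_diameter_um", "neck_max_diameter_um", "neck_length_um")
  if (!all(need %in% names(d)))
    stop("spine table ", path, " lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$has_head <- as.logical(d$has_head)
  d
}

#' @rdname pipeline_io
#' @param x table to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_segment_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "stage", "arc_length_um")
  if (!all(need %in% names(d)))
    stop("segment table ", path, " lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' @rdname pipeline_io
#' @export
read_biometrics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "stage", "TL_cm", "TW_g", "BW_g")
  if (!all(need %in% names(d)))
    stop("biometrics table ", path, " lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Run the end-to-end analysis pipeline
#'
#' Generates (or loads) a study, classifies its spines, computes densities
#' and summaries, runs the Kruskal-Wallis / Dunn battery and the biometric
#' regressions, and writes every result table plus a JSON run manifest to
#' `out_dir`. In `"synthetic"` mode the study comes from
#' [generate_study()] under `config`; in `"from_files"` mode it is read
#' from the TSV inputs and the generator is never touched.
#'
#' Output files: `spines_classified.tsv`, `density.tsv`, `summary.tsv`,
#' `kruskal_wallis.tsv`, `dunn.tsv`, `regressions.tsv`, and
#' `manifest.json`. Identical configuration + seed (+ inputs) reproduce
#' identical output tables.
#'
#' @param config a [study_config()] (synthetic mode only).
#' @param mode `"synthetic"` or `"from_files"`.
#' @param inputs for `"from_files"`: list with `segments` and `spines`
#'   paths, optionally `biometrics`.
#' @param out_dir output directory (created if absent).
#' @param rate_table rate table for synthetic mode; default
#'   [calibrate_rate_table()].
#' @param adjust multiplicity adjustment for Dunn's test.
#' @param include_polylines simulate polylines in synthetic mode.
#' @param quiet suppress progress messages (written to stderr).
#' @return The run manifest (class `"run_manifest"`), invisibly; the
#'   fitted `"spine_study"` is attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config = NULL,
                         mode = c("synthetic", "from_files"),
                         inputs = NULL, out_dir,
                         rate_table = calibrate_rate_table(),
                         adjust = c("none", "bonferroni", "holm"),
                         include_polylines = FALSE, quiet = FALSE) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  input_hashes <- NULL
  if (mode == "synthetic") {
    if (!inherits(config, "study_config"))
      stop("synthetic mode requires a study_config")
    say("generating synthetic study (seed ", config$seed, ")")
    segments <- generate_study(config, rate_table = rate_table,
                               include_polylines = include_polylines)
    spines <- NULL; animals <- NULL
    seed <- config$seed
  } else {
    if (is.null(inputs) || is.null(inputs$segments) || is.null(inputs$spines))
      stop("from_files mode requires inputs$segments and inputs$spines")
    paths <- unlist(inputs)
    missing_in <- paths[!file.exists(paths)]
    if (length(missing_in))
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    say("loading study from files")
    segments <- read_segment_table(inputs$segments)
    spines <- read_spine_table(inputs$spines)
    animals <- if (!is.null(inputs$biometrics))
      read_biometrics(inputs$biometrics) else NULL
    input_hashes <- as.list(tools::md5sum(paths))
    seed <- NULL
    config <- NULL
  }

  say("classifying spines and fitting the study")
  fit <- spine_study(segments, spines, animals, adjust = adjust)

  say("writing result tables to ", out_dir)
  out <- c(
    spines_classified = "spines_classified.tsv",
    density = "density.tsv", summary = "summary.tsv",
    kruskal_wallis = "kruskal_wallis.tsv", dunn = "dunn.tsv",
    regressions = "regressions.tsv")
  paths_out <- file.path(out_dir, out)
  names(paths_out) <- names(out)

  spines_out <- if (inherits(segments, "study_dataset")) {
    classify_spines(segments$spines)
  } else classify_spines(spines)
  write_tsv(spines_out, paths_out["spines_classified"])
  write_tsv(fit$density, paths_out["density"])
  write_tsv(as.data.frame(fit$summary), paths_out["summary"])

  tabs <- report_tables(fit)
  write_tsv(tabs$kruskal_wallis, paths_out["kruskal_wallis"])
  write_tsv(tabs$dunn, paths_out["dunn"])
  reg <- fit$regressions
  if (is.null(reg))
    reg <- data.frame(metric = character(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      p_value = numeric(0), significant = logical(0))
  write_tsv(reg, paths_out["regressions"])

  manifest <- structure(list(
    mode = mode, seed = seed,
    config = if (!is.null(config)) config[setdiff(names(config), "biometrics")],
    adjust = adjust,
    input_hashes = input_hashes,
    package_version = as.character(utils::packageVersion("spinemorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(unname(vapply(paths_out, identity, character(1)))),
    output_hashes = as.list(tools::md5sum(unname(paths_out)))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  attr(manifest, "fit") <- fit
  invisible(manifest)
}

#' Format the inferential results as report tables
#'
#' Produces the two flat tables the pipeline writes: one row per
#' Kruskal-Wallis test (per-stage class comparisons, per-class stage
#' comparisons, and the total-density stage comparison) and one row per
#' Dunn pairwise comparison — all C(4,2) = 6 pairs per comparison — with p
#' values and significance codes.
#'
#' @param fit a `"spine_study"`.
#' @return List with data frames `kruskal_wallis` (comparison, group_set,
#'   H, df, p, code) and `dunn` (comparison, group_a, group_b, Z, p_raw,
#'   p_adjusted, code).
#' @export
report_tables <- function(fit) {
  if (!inherits(fit, "spine_study")) stop("fit must be a spine_study")
  blocks <- c(
    stats::setNames(
      fit$tests$by_stage,
      paste0("classes_within_", names(fit$tests$by_stage))),
    stats::setNames(
      fit$tests$by_class,
      paste0("stages_for_", names(fit$tests$by_class))),
    list(stages_for_total = fit$tests$total))
  kw_rows <- list(); dunn_rows <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b$kw)) {
      kw_rows[[nm]] <- data.frame(comparison = nm, H = NA_real_,
                                  df = NA_integer_, p = NA_real_,
                                  code = NA_character_, note = b$error,
                                  stringsAsFactors = FALSE)
      next
    }
    kw_rows[[nm]] <- data.frame(
      comparison = nm, H = b$kw$H, df = b$kw$df, p = b$kw$p,
      code = significance_code(b$kw$p), note = "",
      stringsAsFactors = FALSE)
    d <- b$dunn
    d <- cbind(comparison = nm, d, stringsAsFactors = FALSE)
    dunn_rows[[nm]] <- d
  }
  if (!length(kw_rows)) stop("no results to report")
  list(kruskal_wallis = do.call(rbind, c(kw_rows, make.row.names = FALSE)),
       dunn = do.call(rbind, c(dunn_rows, make.row.names = FALSE)))
}
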