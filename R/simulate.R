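#' Study configuration for the synthetic generator
#'
#' Bundles the design of a synthetic spine-density study: the life stages,
#' how many dendritic segments each stage contributes, the segment-length
#' distribution, the number of animals per stage, count dispersion, and
#' the per-stage biometric distributions. Defaults reproduce the published
#' study design: four continental life stages, 77 segments per stage (308
#' in total), segments of 10-14 um, and 19 animals (5 glass eels, 5
#' elvers, 5 yellow eels, 4 silver eels) with the published biometric
#' means and SDs.
#'
#' @param stages character vector of stage names.
#' @param segments_per_stage segments generated per stage (>= 2).
#' @param segment_length_range uniform range (um) for segment arc lengths;
#'   minimum must be >= 10 (the tracing rule).
#' @param animals_per_stage integer vector, animals per stage.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param phi dispersion multiplier for per-class counts (variance =
#'   `phi * mean`; 1 = Poisson, < 1 sub-Poisson via binomial, > 1 via
#'   gamma-mixed Poisson).
#' @param biometrics data frame with columns `stage`, `TL_mean`, `TL_sd`,
#'   `TW_mean`, `TW_sd`, `BW_mean`, `BW_sd` (cm / g / g); defaults to the
#'   published per-stage values.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(stages = c("glass", "elver", "yellow", "silver"),
                         segments_per_stage = 77L,
                         segment_length_range = c(10, 14),
                         animals_per_stage = c(5L, 5L, 5L, 4L),
                         seed,
                         phi = 1,
                         biometrics = default_biometrics()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a scalar integer seed is mandatory")
  if (segments_per_stage < 2L) stop("segments_per_stage must be >= 2")
  if (length(animals_per_stage) != length(stages))
    stop("animals_per_stage must have one entry per stage")
  if (any(animals_per_stage < 1L)) stop("each stage needs >= 1 animal")
  if (segment_length_range[1] < 10 ||
      segment_length_range[2] < segment_length_range[1])
    stop("segment lengths must span a valid range with minimum >= 10 um")
  if (phi <= 0) stop("phi must be positive")
  if (!all(stages %in% biometrics$stage))
    stop("biometrics must cover every stage")
  structure(
    list(stages = stages,
         segments_per_stage = as.integer(segments_per_stage),
         segment_length_range = segment_length_range,
         animals_per_stage = as.integer(animals_per_stage),
         seed = as.integer(seed), phi = phi, biometrics = biometrics),
    class = "study_config")
}

#' Published per-stage biometric means and SDs
#'
#' Total length (TL, cm), total weight (TW, g) and brain weight (BW, g)
#' of the sampled eels, per life stage (mean and SD).
#' @return Data frame with columns `stage`, `TL_mean`, `TL_sd`, `TW_mean`,
#'   `TW_sd`, `BW_mean`, `BW_sd`.
#' @export
default_biometrics <- function() {
  data.frame(
    stage = c("glass", "elver", "yellow", "silver"),
    TL_mean = c(6.53, 8.06, 30.56, 38.40),
    TL_sd   = c(0.43, 2.43, 3.41, 3.23),
    TW_mean = c(0.23, 0.77, 39.04, 105.75),
    TW_sd   = c(0.04, 0.94, 14.04, 52.22),
    BW_mean = c(0.004, 0.005, 0.058, 0.110),
    BW_sd   = c(0.001, 0.002, 0.026, 0.049),
    stringsAsFactors = FALSE)
}

#' Draw class-conditional spine geometries
#'
#' Samples spine geometry from ranges that satisfy the classifier for the
#' requested class by construction:
#' \itemize{
#'   \item M: headed; neck max diameter U(0.2, 0.5) um, neck length
#'     U(0.3, 0.95) x neck diameter (strictly shorter than thick), head
#'     diameter neck x U(1.3, 2.5);
#'   \item LT: headed; neck max diameter U(0.1, 0.3) um, neck length
#'     U(1.1 x neck, 4 x neck + 1) um, head diameter neck x U(1.3, 2.5);
#'   \item S: headless, total length U(0.3, 0.95) um;
#'   \item F: headless, total length U(10.5, 15) um.
#' }
#' For headed spines the total length is neck length plus head diameter
#' (the head is modelled as a terminal bulb). No geometry ever falls in
#' the headless 1-10 um gap, so generated studies classify back to their
#' requested classes exactly.
#'
#' @param class one of `"M"`, `"LT"`, `"S"`, `"F"`.
#' @param n number of spines to draw.
#' @return Data frame with columns `total_length_um`, `has_head`,
#'   `head_diameter_um`, `neck_max_diameter_um`, `neck_length_um`.
#' @export
sample_geometry <- function(class, n = 1L) {
  if (!class %in% SPINE_CLASSES) stop("unknown spine class: ", class)
  if (n == 0L)
    return(data.frame(total_length_um = numeric(0), has_head = logical(0),
                      head_diameter_um = numeric(0),
                      neck_max_diameter_um = numeric(0),
                      neck_length_um = numeric(0)))
  if (class %in% c("M", "LT")) {
    neck <- switch(class,
                   M = stats::runif(n, 0.2, 0.5),
                   LT = stats::runif(n, 0.1, 0.3))
    neck_len <- switch(class,
                       M = neck * stats::runif(n, 0.3, 0.95),
                       LT = stats::runif(n, 1.1 * neck, 4 * neck + 1))
    head <- neck * stats::runif(n, 1.3, 2.5)
    data.frame(total_length_um = neck_len + head, has_head = TRUE,
               head_diameter_um = head, neck_max_diameter_um = neck,
               neck_length_um = neck_len)
  } else {
    total <- switch(class,
                    S = stats::runif(n, 0.3, 0.95),
                    F = stats::runif(n, 10.5, 15))
    data.frame(total_length_um = total, has_head = FALSE,
               head_diameter_um = 0, neck_max_diameter_um = 0,
               neck_length_um = 0)
  }
}

# per-class spine counts with mean m and variance phi * m
sample_counts <- function(m, phi) {
  n <- length(m)
  if (phi == 1) return(stats::rpois(n, m))
  if (phi < 1) {
    # binomial: size chosen so that np = m and np(1-p) = phi * m
    p <- 1 - phi
    size <- pmax(round(m / p), ceiling(m))
    return(stats::rbinom(n, size = size, prob = ifelse(size > 0, m / size, 0)))
  }
  # gamma-mixed Poisson (negative binomial): var = m + m^2/size = phi * m
  out <- integer(n)
  pos <- m > 0
  out[pos] <- stats::rnbinom(sum(pos), size = m[pos] / (phi - 1), mu = m[pos])
  out
}

#' Simulate classified dendritic segments for one stage
#'
#' Draws `n` segments of the given stage: segment arc lengths from the
#' configured range, per-class spine counts with mean
#' `rate * length / 10` and variance `phi x mean`, and class-conditional
#' spine geometries ([sample_geometry()]). Uses the current RNG state;
#' seed upstream (e.g. via [generate_study()]) for reproducibility.
#'
#' @param stage stage name (must be a row of `rate_table$rates`).
#' @param rate_table a `"stage_rate_table"` ([calibrate_rate_table()]).
#' @param n number of segments.
#' @param lengths optional vector of segment arc lengths (um, all >= 10);
#'   default U(10, 14).
#' @param phi count dispersion; defaults to the table's `phi`.
#' @param segment_prefix prefix for generated segment ids.
#' @return List with `segments` (data frame: segment_id, stage,
#'   arc_length_um) and `spines` (geometry table with a `true_class`
#'   column recording the generating class).
#' @export
sample_segments <- function(stage, rate_table, n, lengths = NULL,
                            phi = rate_table$phi,
                            segment_prefix = stage) {
  stopifnot(inherits(rate_table, "stage_rate_table"))
  if (!stage %in% rownames(rate_table$rates))
    stop("unknown stage: ", stage)
  if (phi <= 0) stop("phi must be positive")
  if (is.null(lengths)) lengths <- stats::runif(n, 10, 14)
  if (length(lengths) != n) stop("lengths must have one entry per segment")
  if (any(lengths < 10)) stop("segment lengths must be >= 10 um")
  ids <- sprintf("%s_seg%04d", segment_prefix, seq_len(n))
  segments <- data.frame(segment_id = ids, stage = stage,
                         arc_length_um = lengths, stringsAsFactors = FALSE)
  spines <- list()
  for (cl in SPINE_CLASSES) {
    m <- rate_table$rates[stage, cl] * lengths / 10
    counts <- sample_counts(m, phi)
    total <- sum(counts)
    if (total == 0L) next
    geo <- sample_geometry(cl, total)
    geo <- cbind(segment_id = rep(ids, counts), stage = stage, geo,
                 true_class = cl, stringsAsFactors = FALSE)
    spines[[cl]] <- geo
  }
  spines <- if (length(spines)) do.call(rbind, spines) else
    data.frame(segment_id = character(0), stage = character(0),
               total_length_um = numeric(0), has_head = logical(0),
               head_diameter_um = numeric(0),
               neck_max_diameter_um = numeric(0),
               neck_length_um = numeric(0), true_class = character(0),
               stringsAsFactors = FALSE)
  rownames(spines) <- NULL
  list(segments = segments, spines = spines)
}

#' Simulate one dendritic segment
#'
#' Single-segment convenience wrapper around [sample_segments()], with an
#' optional smooth 3-D polyline of the requested arc length.
#'
#' @inheritParams sample_segments
#' @param length segment arc length (um, >= 10).
#' @param include_polyline attach a simulated 3-D polyline whose arc
#'   length equals `length`.
#' @return List with `segments` (one row), `spines`, and `polyline`
#'   (matrix or NULL).
#' @export
sample_segment <- function(stage, rate_table, length = 12,
                           phi = rate_table$phi, include_polyline = TRUE) {
  out <- sample_segments(stage, rate_table, 1L, lengths = length, phi = phi)
  out$polyline <- if (include_polyline) random_polyline(length) else NULL
  out
}

#' Smooth 3-D random-walk polyline of a given arc length
#'
#' Fixed-length steps (0.5 um) with slowly decorrelating direction, so the
#' polyline's arc length equals the requested length exactly (up to
#' floating point) while its shape meanders like a traced dendrite.
#'
#' @param length target arc length (um).
#' @param step step size (um).
#' @param wobble direction perturbation per step (0 = straight line).
#' @return Numeric matrix with columns x, y, z (um).
#' @export
random_polyline <- function(length, step = 0.5, wobble = 0.3) {
  if (length <= 0) stop("length must be positive")
  m <- max(2L, ceiling(length / step))
  s <- length / m
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  steps <- matrix(0, nrow = m, ncol = 3)
  for (i in seq_len(m)) {
    dir <- dir + wobble * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    steps[i, ] <- dir * s
  }
  rbind(0, apply(steps, 2, cumsum))
}

#' Generate a complete synthetic spine-density study
#'
#' Produces the full dataset the analysis pipeline consumes: classified
#' dendritic segments for every stage, per-animal biometrics drawn from
#' truncated-at-zero normals with the configured per-stage means/SDs, and
#' a provenance block. Segments are assigned round-robin to the stage's
#' animals. Biometrics are drawn independently of spine density (the
#' published study found no correlation between them). The whole dataset
#' is a pure function of the configuration, whose seed is mandatory.
#'
#' @param config a [study_config()].
#' @param rate_table a `"stage_rate_table"`; default
#'   [calibrate_rate_table()].
#' @param include_polylines also simulate a 3-D polyline per segment
#'   (listed in `$polylines`, named by segment id). Counts, geometries and
#'   densities do not depend on the polylines; disable for speed when only
#'   densities are needed.
#' @return An object of class `"study_dataset"`: list with `segments`
#'   (segment_id, stage, animal_id, arc_length_um), `spines` (geometry +
#'   `true_class`), `animals` (animal_id, stage, TL_cm, TW_g, BW_g),
#'   `polylines` (named list or NULL) and `provenance` (seed, config
#'   hash, package version).
#' @examples
#' ds <- generate_study(study_config(seed = 1, segments_per_stage = 5),
#'                      include_polylines = FALSE)
#' nrow(ds$segments)  # 20
#' @export
generate_study <- function(config, rate_table = calibrate_rate_table(),
                           include_polylines = TRUE) {
  stopifnot(inherits(config, "study_config"),
            inherits(rate_table, "stage_rate_table"))
  if (!all(config$stages %in% rownames(rate_table$rates)))
    stop("rate table does not cover every configured stage")
  set.seed(config$seed)
  seg_list <- list(); spine_list <- list(); animal_list <- list()
  polylines <- if (include_polylines) list() else NULL
  for (si in seq_along(config$stages)) {
    s <- config$stages[si]
    n <- config$segments_per_stage
    lengths <- stats::runif(n, config$segment_length_range[1],
                            config$segment_length_range[2])
    drawn <- sample_segments(s, rate_table, n, lengths, phi = config$phi)
    n_an <- config$animals_per_stage[si]
    an_ids <- sprintf("%s_animal%02d", s, seq_len(n_an))
    drawn$segments$animal_id <- an_ids[((seq_len(n) - 1L) %% n_an) + 1L]
    bm <- config$biometrics[config$biometrics$stage == s, ]
    animal_list[[s]] <- data.frame(
      animal_id = an_ids, stage = s,
      TL_cm = rnorm_pos(n_an, bm$TL_mean, bm$TL_sd),
      TW_g = rnorm_pos(n_an, bm$TW_mean, bm$TW_sd),
      BW_g = rnorm_pos(n_an, bm$BW_mean, bm$BW_sd),
      stringsAsFactors = FALSE)
    if (include_polylines) {
      pl <- lapply(lengths, random_polyline)
      names(pl) <- drawn$segments$segment_id
      polylines <- c(polylines, pl)
    }
    seg_list[[s]] <- drawn$segments
    spine_list[[s]] <- drawn$spines
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[, c("segment_id", "stage", "animal_id",
                           "arc_length_um")]
  rownames(segments) <- NULL
  spines <- do.call(rbind, spine_list)
  rownames(spines) <- NULL
  structure(
    list(segments = segments, spines = spines,
         animals = do.call(rbind, c(animal_list, make.row.names = FALSE)),
         polylines = polylines,
         provenance = list(seed = config$seed,
                           config_hash = config_hash(config),
                           phi = config$phi,
                           package_version =
                             as.character(utils::packageVersion("spinemorph")))),
    class = "study_dataset")
}

# truncated-at-zero normal draws (resample non-positive values)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

# stable md5 hash of a configuration (via its deparsed serialisation)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "study_dataset: %d segments, %d spines, %d animals, %d stage(s); seed %d\n",
    nrow(x$segments), nrow(x$spines), nrow(x$animals),
    length(unique(x$segments$stage)), x$provenance$seed))
  invisible(x)
}

#' Export a generated segment as a neuron morphology
#'
#' Encodes one simulated dendritic segment in the package's SWC dialect:
#' the polyline becomes a chain of dendrite nodes (structure tag 3) and
#' each spine a short child branch of spine-tagged nodes (tag 7) — a neck
#' node and, for headed spines, a head node whose radius is half the head
#' diameter. Stage and animal id go into the metadata header.
#'
#' @param dataset a `"study_dataset"` generated with polylines.
#' @param segment_id id of the segment to export.
#' @return A `"neuron_morphology"`.
#' @export
segment_morphology <- function(dataset, segment_id) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(dataset$polylines))
    stop("dataset was generated without polylines")
  pl <- dataset$polylines[[segment_id]]
  if (is.null(pl)) stop("unknown segment_id: ", segment_id)
  seg <- dataset$segments[dataset$segments$segment_id == segment_id, ]
  sp <- dataset$spines[dataset$spines$segment_id == segment_id, ,
                       drop = FALSE]
  n_d <- nrow(pl)
  dend_radius <- 0.4
  nodes <- data.frame(
    id = seq_len(n_d), type = SWC_DENDRITE_TAG,
    x = pl[, 1], y = pl[, 2], z = pl[, 3],
    radius = dend_radius, parent = c(-1L, seq_len(n_d - 1L)))
  next_id <- n_d
  if (nrow(sp)) {
    # spines attach to evenly spaced interior dendrite nodes
    att <- 1L + (seq_len(nrow(sp)) - 1L) %% (n_d - 1L)
    for (i in seq_len(nrow(sp))) {
      a <- att[i]
      base <- as.numeric(pl[a, ])
      u <- perpendicular_unit(pl[a + 1L, ] - pl[a, ])
      if (sp$has_head[i]) {
        neck_tip <- base + u * sp$neck_length_um[i]
        head_c <- base + u * sp$total_length_um[i]
        nodes <- rbind(nodes, data.frame(
          id = next_id + 1:2, type = SWC_SPINE_TAG,
          x = c(neck_tip[1], head_c[1]), y = c(neck_tip[2], head_c[2]),
          z = c(neck_tip[3], head_c[3]),
          radius = c(sp$neck_max_diameter_um[i] / 2,
                     sp$head_diameter_um[i] / 2),
          parent = c(a, next_id + 1L)))
        next_id <- next_id + 2L
      } else {
        tip <- base + u * sp$total_length_um[i]
        nodes <- rbind(nodes, data.frame(
          id = next_id + 1L, type = SWC_SPINE_TAG,
          x = tip[1], y = tip[2], z = tip[3],
          radius = 0.1, parent = a))
        next_id <- next_id + 1L
      }
    }
  }
  neuron_morphology(nodes, metadata = c(
    segment_id = segment_id, stage = seg$stage,
    animal_id = seg$animal_id,
    arc_length_um = sprintf("%.6f", seg$arc_length_um)))
}

perpendicular_unit <- function(v) {
  v <- as.numeric(v)
  ref <- if (abs(v[1]) < 0.9 * sqrt(sum(v^2))) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - v * sum(ref * v) / sum(v^2)
  p / sqrt(sum(p^2))
}
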