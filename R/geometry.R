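#' Arc length of a 3-D polyline
#'
#' Sum of Euclidean distances between consecutive points. This is the
#' length measure used everywhere densities are normalised: a traced
#' dendritic segment is a polyline and its "length" is its arc length in
#' micrometres.
#'
#' @param polyline numeric matrix or data frame with columns x, y, z (one
#'   row per point, in order along the trace), in micrometres.
#' @return Arc length in micrometres (non-negative scalar).
#' @examples
#' arc_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
arc_length <- function(polyline) {
  p <- as.matrix(polyline)
  if (!is.numeric(p) || ncol(p) < 3L)
    stop("polyline must be a numeric matrix with columns x, y, z")
  p <- p[, 1:3, drop = FALSE]
  if (nrow(p) < 2L)
    stop("polyline needs at least 2 points")
  if (!all(is.finite(p)))
    stop("polyline coordinates must be finite")
  d <- diff(p)
  sum(sqrt(rowSums(d * d)))
}

#' Construct a protrusion diameter profile
#'
#' A protrusion profile is the raw measurement of one candidate spine: the
#' diameter of the protrusion sampled along its own arc, from the
#' attachment point on the dendrite (arc position 0) to its tip.
#'
#' @param arc_position numeric vector of arc positions (um), strictly
#'   increasing, starting at 0.
#' @param diameter numeric vector of diameters (um), all positive, same
#'   length as `arc_position`.
#' @param attachment_id optional node id on the parent dendrite.
#' @return An object of class `"protrusion_profile"`.
#' @export
protrusion_profile <- function(arc_position, diameter, attachment_id = NA_integer_) {
  if (length(arc_position) != length(diameter))
    stop("arc_position and diameter must have the same length")
  if (length(arc_position) < 2L)
    stop("a protrusion profile needs at least 2 samples")
  if (arc_position[1L] != 0)
    stop("arc_position must start at 0")
  if (any(diff(arc_position) <= 0))
    stop("arc_position must be strictly increasing")
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("all diameters must be positive and finite")
  structure(
    list(arc_position = as.numeric(arc_position),
         diameter = as.numeric(diameter),
         attachment_id = attachment_id),
    class = "protrusion_profile"
  )
}

#' Measure spine metrics from a protrusion diameter profile
#'
#' Extracts the four geometric quantities the spine classifier consumes
#' (total length, head diameter, maximum neck diameter, neck length) from a
#' diameter profile, deciding first whether the protrusion carries a
#' distinguishable head.
#'
#' Head detection works on the diameter profile: let the neck candidate be
#' the global diameter minimum, and let `d_head` be the maximum diameter
#' distal to it. The protrusion has a head iff
#' \itemize{
#'   \item `d_head >= head_min_diameter` (the bulb is large enough to be a
#'     "well-formed" head), and
#'   \item `d_head >= head_prominence_ratio * d_min`, where `d_min` is the
#'     minimum diameter between the attachment point and the position of
#'     `d_head` (the bulb stands out from the neck), and
#'   \item `d_head` exceeds every diameter in the neck region (the head is
#'     the widest part of the protrusion; rules out bulbous-base artefacts).
#' }
#' When a head is present the neck region is `[0, position of d_min]`:
#' `neck_length` is that position, `neck_max_diameter` the maximum diameter
#' over the neck region (the literal maximum, not a mean), and
#' `head_diameter = d_head`. Headless protrusions get zeros for all three.
#'
#' @param profile a [protrusion_profile()].
#' @param head_min_diameter minimum head diameter (um) for a bulb to count
#'   as a well-formed head. Default 0.3 um.
#' @param head_prominence_ratio how much wider than the thinnest neck point
#'   the bulb must be (dimensionless, >= 1). Default 1.2.
#' @return An object of class `"spine_metrics"`: a list with
#'   `total_length`, `has_head`, `head_diameter`, `neck_max_diameter`,
#'   `neck_length` (um).
#' @examples
#' p <- protrusion_profile(seq(0, 1, by = 0.2),
#'                         c(0.40, 0.25, 0.20, 0.70, 0.80, 0.60))
#' measure_spine(p)
#' @export
measure_spine <- function(profile, head_min_diameter = 0.3,
                          head_prominence_ratio = 1.2) {
  stopifnot(inherits(profile, "protrusion_profile"))
  if (head_min_diameter <= 0) stop("head_min_diameter must be positive")
  if (head_prominence_ratio < 1) stop("head_prominence_ratio must be >= 1")
  arc <- profile$arc_position
  d <- profile$diameter
  n <- length(d)
  total <- arc[n]

  headless <- function() spine_metrics(total_length = total, has_head = FALSE)

  i_min <- which.min(d)              # first global minimum
  if (i_min == n) return(headless()) # nothing distal of the minimum
  distal <- (i_min + 1L):n
  j <- distal[which.max(d[distal])]  # position of the distal maximum
  d_head <- d[j]
  # thinnest point before the head; ties resolve distally so a cylindrical
  # neck ends where the head begins, not at the attachment
  k <- max(which(d[1:j] == min(d[1:j])))
  if (k == j) return(headless())     # no neck/head transition
  neck_max <- max(d[1:k])
  has_head <- d_head >= head_min_diameter &&
    d_head >= head_prominence_ratio * d[k] &&
    d_head > neck_max
  if (!has_head) return(headless())
  spine_metrics(
    total_length = total,
    has_head = TRUE,
    head_diameter = d_head,
    neck_max_diameter = neck_max,
    neck_length = arc[k]
  )
}

#' Construct validated spine metrics
#'
#' @param total_length total protrusion length (um), positive.
#' @param has_head logical: does the protrusion carry a distinguishable head?
#' @param head_diameter head diameter (um); 0 when headless.
#' @param neck_max_diameter maximum neck diameter (um); 0 when headless.
#' @param neck_length neck length (um); 0 when headless.
#' @return An object of class `"spine_metrics"`.
#' @export
spine_metrics <- function(total_length, has_head, head_diameter = 0,
                          neck_max_diameter = 0, neck_length = 0) {
  if (!is.finite(total_length) || total_length <= 0)
    stop("total_length must be positive")
  if (isTRUE(has_head)) {
    if (head_diameter <= neck_max_diameter)
      stop("a headed spine must have head_diameter > neck_max_diameter")
    if (neck_length >= total_length)
      stop("neck_length must be smaller than total_length")
    if (head_diameter <= 0 || neck_max_diameter <= 0 || neck_length < 0)
      stop("headed spine requires positive head and neck diameters")
  } else {
    if (head_diameter != 0 || neck_max_diameter != 0 || neck_length != 0)
      stop("headless spine must have zero head/neck fields")
  }
  structure(
    list(total_length = total_length, has_head = isTRUE(has_head),
         head_diameter = head_diameter,
         neck_max_diameter = neck_max_diameter,
         neck_length = neck_length),
    class = "spine_metrics"
  )
}

#' @export
print.spine_metrics <- function(x, ...) {
  cat(sprintf(
    "spine_metrics: total %.3g um, %s\n", x$total_length,
    if (x$has_head)
      sprintf("head %.3g um, neck max %.3g um, neck length %.3g um",
              x$head_diameter, x$neck_max_diameter, x$neck_length)
    else "headless"))
  invisible(x)
}
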