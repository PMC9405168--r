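#' Read a neuronal reconstruction in the SWC dialect
#'
#' Reads the whitespace-delimited 7-column SWC format (id, structure tag,
#' x, y, z, radius, parent id). Lines starting with `#` are comments;
#' comments of the form `# key: value` are collected into the morphology's
#' metadata (used here for life stage, animal id, cell subtype and soma
#' diameter). The dialect uses structure tag 7 for dendritic-spine branches
#' (standard SWC reserves no spine tag); radii are radii, so diameters are
#' `2 * radius`. Coordinates and radii are in micrometres.
#'
#' @param path path to an SWC file.
#' @return An object of class `"neuron_morphology"`: a list with `nodes`
#'   (data frame: id, type, x, y, z, radius, parent) and `metadata` (named
#'   character vector).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- character()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L) meta[m[2]] <- m[3]
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != 7L)
      stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("malformed SWC line %d: non-numeric field", i))
    rows[[i]] <- vals
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("SWC file contains no nodes")
  tab <- do.call(rbind, rows)
  nodes <- data.frame(
    id = as.integer(tab[, 1]), type = as.integer(tab[, 2]),
    x = tab[, 3], y = tab[, 4], z = tab[, 5],
    radius = tab[, 6], parent = as.integer(tab[, 7])
  )
  neuron_morphology(nodes, metadata = meta)
}

#' Construct and validate a neuron morphology
#'
#' @param nodes data frame with columns id, type, x, y, z, radius, parent.
#' @param metadata named character vector of free-form metadata
#'   (e.g. `stage`, `animal_id`, `cell_subtype`, `soma_diameter_um`).
#' @return An object of class `"neuron_morphology"`.
#' @export
neuron_morphology <- function(nodes, metadata = character()) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(need %in% names(nodes)))
    stop("nodes must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(nodes) == 0L) stop("morphology must contain at least one node")
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z)))
    stop("node coordinates must be finite")
  if (any(!is.finite(nodes$radius) | nodes$radius <= 0))
    stop("all radii must be positive")
  dangling <- nodes$parent != -1L & !(nodes$parent %in% nodes$id)
  if (any(dangling))
    stop("dangling parent id(s): ",
         paste(unique(nodes$parent[dangling]), collapse = ", "))
  if (any(nodes$parent == nodes$id))
    stop("a node cannot be its own parent")
  if (!any(nodes$parent == -1L)) stop("morphology must have at least one root")
  md <- as.character(metadata)
  names(md) <- names(metadata)
  structure(list(nodes = nodes[order(nodes$id), , drop = FALSE],
                 metadata = md),
            class = "neuron_morphology")
}

#' Write a neuron morphology to an SWC file
#'
#' Nodes are written in canonical id order; metadata is emitted as
#' `# key: value` header comments. Numeric columns are printed with full
#' double precision so a read/write round trip preserves the node table
#' exactly.
#'
#' @param morph a `"neuron_morphology"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "neuron_morphology"))
  n <- morph$nodes[order(morph$nodes$id), , drop = FALSE]
  header <- character()
  if (length(morph$metadata))
    header <- sprintf("# %s: %s", names(morph$metadata), morph$metadata)
  body <- sprintf("%d %d %s %s %s %s %d",
                  n$id, n$type,
                  sprintf("%.17g", n$x), sprintf("%.17g", n$y),
                  sprintf("%.17g", n$z), sprintf("%.17g", n$radius),
                  n$parent)
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SWC file: ", path)
  invisible(path)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat(sprintf("neuron_morphology: %d nodes, %d root(s)\n",
              nrow(x$nodes), sum(x$nodes$parent == -1L)))
  if (length(x$metadata))
    cat(paste0("  ", names(x$metadata), ": ", x$metadata, collapse = "\n"),
        "\n")
  invisible(x)
}

# structure tag used for spine branches in this SWC dialect
SWC_SPINE_TAG <- 7L
SWC_DENDRITE_TAG <- 3L

#' Extract protrusion profiles for the spine branches of a morphology
#'
#' Walks every maximal chain of spine-tagged nodes (structure tag 7)
#' hanging off a dendrite node and converts it into a
#' [protrusion_profile()]: arc position 0 at the attachment node on the
#' dendrite, diameters taken as `2 * radius` of the successive spine nodes.
#'
#' @param morph a `"neuron_morphology"`.
#' @return A list of [protrusion_profile()] objects (possibly empty).
#' @export
spine_profiles <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  n <- morph$nodes
  idx <- seq_len(nrow(n))
  names(idx) <- n$id
  children <- split(n$id, factor(n$parent, levels = n$id))
  is_spine <- n$type == SWC_SPINE_TAG
  # roots of spine branches: spine nodes whose parent is not a spine node
  parent_idx <- ifelse(n$parent == -1L, NA_integer_, idx[as.character(n$parent)])
  branch_root <- is_spine & (is.na(parent_idx) | !is_spine[parent_idx])
  out <- list()
  for (r in which(branch_root)) {
    att <- parent_idx[r]
    if (is.na(att)) next  # a spine branch must attach to the dendrite
    chain <- r
    repeat {
      kids <- children[[as.character(n$id[chain[length(chain)]])]]
      kids <- kids[is_spine[idx[as.character(kids)]]]
      if (length(kids) == 0L) break
      chain <- c(chain, idx[as.character(kids[1L])])  # follow first child
    }
    pts <- as.matrix(n[c(att, chain), c("x", "y", "z")])
    seg <- sqrt(rowSums(diff(pts)^2))
    # sample 0 sits at the attachment point; its diameter is the branch's
    # basal diameter (first spine node), not the dendrite's
    out[[length(out) + 1L]] <- protrusion_profile(
      arc_position = c(0, cumsum(seg)),
      diameter = 2 * n$radius[c(chain[1L], chain)],
      attachment_id = n$id[att]
    )
  }
  out
}
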