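#' Neuron morphologies from SWC samples
#'
#' A morphology is a rooted tree of 3D sample points with radii and
#' structure-type labels, the interchange representation used by
#' neuromorpho.org ("SWC": id, type, x, y, z, radius, parent per row).
#' `as_morphology()` validates a point table and attaches the class;
#' `read_swc()` / `write_swc()` move between files and morphologies.
#'
#' Structure codes 1, 3 and 4 map to soma, basal and apical dendrite; any
#' other code is kept, labelled `"other"`, and excluded from arbor-specific
#' analyses.
#'
#' @param points data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent_id` (or a bare 7-column SWC-like table in that order).
#' @param soma_area_override optional soma surface area in um^2, used by
#'   [soma_surface()] instead of the spherical-soma convention (reconstructed
#'   somata are often assigned their measured areas individually).
#' @return an object of class `morphology`: the validated, contiguously
#'   re-indexed point tibble plus attributes.
#' @examples
#' pts <- data.frame(id = 1:3, type = c(1, 3, 3), x = c(0, 10, 20),
#'                   y = 0, z = 0, radius = c(5, 1, 1), parent_id = c(-1, 1, 2))
#' m <- as_morphology(pts)
#' path_distance(m, 3)
#' @export
as_morphology <- function(points, soma_area_override = NULL) {
  cols <- c("id", "type", "x", "y", "z", "radius", "parent_id")
  if (!is.data.frame(points) || ncol(points) < 7) {
    abort("`points` must be a data frame with the seven SWC columns.")
  }
  if (!all(cols %in% names(points))) {
    points <- points[, 1:7]
    names(points) <- cols
  }
  pts <- as_tibble(points[, cols])
  pts$id <- as.integer(pts$id)
  pts$type <- as.integer(pts$type)
  pts$parent_id <- as.integer(pts$parent_id)

  if (nrow(pts) < 1) abort("morphology needs at least one point.")
  if (anyDuplicated(pts$id)) abort("duplicated point ids.", class = "dendrisig_structure_error")
  if (any(!is.finite(pts$x) | !is.finite(pts$y) | !is.finite(pts$z))) {
    abort("non-finite coordinates.")
  }
  if (any(!is.finite(pts$radius) | pts$radius <= 0)) {
    abort("every radius must be > 0.", class = "dendrisig_validation_error")
  }

  roots <- which(pts$parent_id == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("morphology must have exactly one root (found %d).", length(roots)),
          class = "dendrisig_structure_error")
  }

  # re-index contiguously in a parent-before-child (topological) order
  idx <- order_topologically(pts$id, pts$parent_id)
  pts <- pts[idx, ]
  new_id <- seq_len(nrow(pts))
  remap <- stats::setNames(new_id, pts$id)
  pts$id <- new_id
  pts$parent_id <- ifelse(pts$parent_id == -1L, -1L,
                          as.integer(remap[as.character(pts$parent_id)]))
  pts$structure <- structure_label(pts$type)

  m <- structure(list(points = pts, soma_area_override = soma_area_override),
                 class = "morphology")
  m
}

structure_label <- function(type) {
  out <- rep("other", length(type))
  out[type == 1L] <- "soma"
  out[type == 3L] <- "basal"
  out[type == 4L] <- "apical"
  out
}

# topological order of points; errors on orphans and cycles
order_topologically <- function(id, parent_id) {
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  parent_pos <- integer(n)
  for (i in seq_len(n)) {
    p <- parent_id[i]
    if (p == -1L) {
      parent_pos[i] <- 0L
    } else {
      pp <- pos[as.character(p)]
      if (is.na(pp)) {
        abort(sprintf("point %s refers to unknown parent %s.", id[i], p),
              class = "dendrisig_structure_error")
      }
      if (pp == i) abort("point is its own parent.", class = "dendrisig_structure_error")
      parent_pos[i] <- pp
    }
  }
  depth <- rep(NA_integer_, n)
  resolve <- function(i) {
    chain <- integer(0)
    while (is.na(depth[i])) {
      if (i %in% chain) {
        abort("cycle detected in parent links.", class = "dendrisig_structure_error")
      }
      chain <- c(chain, i)
      if (parent_pos[i] == 0L) {
        depth[i] <<- 0L
        break
      }
      if (!is.na(depth[parent_pos[i]])) {
        depth[i] <<- depth[parent_pos[i]] + 1L
        break
      }
      i <- parent_pos[i]
    }
    for (j in rev(chain)) {
      if (is.na(depth[j])) depth[j] <<- depth[parent_pos[j]] + 1L
    }
  }
  for (i in seq_len(n)) resolve(i)
  order(depth, seq_len(n))
}

#' @export
print.morphology <- function(x, ...) {
  pts <- x$points
  cat(sprintf("<morphology: %d points (%d soma, %d basal, %d apical, %d other)>\n",
              nrow(pts), sum(pts$structure == "soma"), sum(pts$structure == "basal"),
              sum(pts$structure == "apical"), sum(pts$structure == "other")))
  invisible(x)
}

#' @export
as_tibble.morphology <- function(x, ...) x$points

#' Read and write SWC morphology files
#'
#' Whitespace-delimited seven-column SWC with `#` comment lines.  Reading
#' validates the tree (single root, no orphans or cycles, positive radii) and
#' re-indexes ids contiguously; writing emits full-precision values so that a
#' write/read round trip reproduces the point table exactly.
#'
#' @param path file path.
#' @param soma_area_override passed to [as_morphology()].
#' @return `read_swc()` returns a `morphology`; `write_swc()` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path, soma_area_override = NULL) {
  if (!file.exists(path)) abort(sprintf("SWC file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) abort(sprintf("no data lines in %s", path))
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    abort(sprintf("malformed SWC line %d in %s (expected 7 fields, got %d).",
                  rows[bad[1]], path, lengths(fields)[bad[1]]),
          class = "dendrisig_parse_error")
  }
  num <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(num)) {
    bad <- rows[which(rowSums(is.na(num)) > 0)[1]]
    abort(sprintf("non-numeric field on SWC line %d in %s.", bad, path),
          class = "dendrisig_parse_error")
  }
  pts <- tibble(id = as.integer(num[, 1]), type = as.integer(num[, 2]),
                x = num[, 3], y = num[, 4], z = num[, 5],
                radius = num[, 6], parent_id = as.integer(num[, 7]))
  as_morphology(pts, soma_area_override = soma_area_override)
}

#' @param m a `morphology`.
#' @rdname read_swc
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  p <- m$points
  lines <- sprintf("%d %d %s %s %s %s %d", p$id, p$type,
                   fmt_num(p$x), fmt_num(p$y), fmt_num(p$z), fmt_num(p$radius),
                   p$parent_id)
  writeLines(c("# SWC written by dendrisig", lines), path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Path distance of points from the root
#'
#' Sum of Euclidean inter-point distances along the unique path from a point
#' to the soma root.  Signalling descriptors are graphed against this
#' distance of the PSP initiation site.
#'
#' @param m a `morphology`.
#' @param point_id point id (after re-indexing); if `NULL`, distances for all
#'   points are returned as a vector indexed by id.
#' @return distance(s) in micrometres.
#' @export
path_distance <- function(m, point_id = NULL) {
  stopifnot(inherits(m, "morphology"))
  p <- m$points
  d <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {     # parents precede children after reindexing
    par <- p$parent_id[i]
    if (par != -1L) {
      step <- sqrt((p$x[i] - p$x[par])^2 + (p$y[i] - p$y[par])^2 +
                     (p$z[i] - p$z[par])^2)
      d[i] <- d[par] + step
    }
  }
  if (is.null(point_id)) return(d)
  if (any(!point_id %in% p$id)) abort("unknown point id.")
  d[point_id]
}

#' Lateral surface area of a cylindrical dendrite segment
#'
#' Inter-sample segments are modelled as open cylinders, so the membrane area
#' is \eqn{\pi d l} (no end caps: the cable continues at both ends).
#'
#' @param d diameter (um).
#' @param l length (um).
#' @return area in um^2.
#' @export
segment_surface_area <- function(d, l) {
  if (any(d <= 0) || any(l <= 0)) {
    abort("segment_surface_area() needs d > 0 and l > 0.")
  }
  pi * d * l
}

#' Soma surface area
#'
#' Uses the override area when one is attached to the morphology (reconstructed
#' somata carry individually measured areas); otherwise collapses all soma
#' sample points to one sphere of the mean radius, area \eqn{4 \pi r^2}.
#'
#' @param m a `morphology`.
#' @return soma area in um^2.
#' @export
soma_surface <- function(m) {
  stopifnot(inherits(m, "morphology"))
  if (!is.null(m$soma_area_override)) return(m$soma_area_override)
  r <- m$points$radius[m$points$structure == "soma"]
  if (length(r) == 0) {
    abort("morphology has no soma points and no soma area override.")
  }
  4 * pi * mean(r)^2
}

# Segment table underlying all morphometry: one row per non-root point whose
# own structure is dendritic (segment from parent sample to this sample).
# Segments attached to a soma sample take the child diameter so the fat soma
# radius does not inflate proximal dendrite calibre.
morph_segments <- function(m) {
  p <- m$points
  pd <- path_distance(m)
  child <- which(p$parent_id != -1L & p$structure != "soma")
  if (length(child) == 0) {
    return(tibble(child = integer(), parent = integer(), length = numeric(),
                  diameter = numeric(), area = numeric(), arbor = character(),
                  mid_dist = numeric(), start_dist = numeric()))
  }
  par <- p$parent_id[child]
  len <- sqrt((p$x[child] - p$x[par])^2 + (p$y[child] - p$y[par])^2 +
                (p$z[child] - p$z[par])^2)
  diam <- ifelse(p$structure[par] == "soma",
                 2 * p$radius[child],
                 p$radius[par] + p$radius[child])
  keep <- len > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d zero-length segment(s).", sum(!keep)))
  }
  child <- child[keep]; par <- par[keep]; len <- len[keep]; diam <- diam[keep]
  tibble(child = child, parent = par, length = len, diameter = diam,
         area = pi * diam * len, arbor = p$structure[child],
         mid_dist = pd[par] + len / 2, start_dist = pd[par])
}

#' Distance-binned distribution of dendritic length or surface area
#'
#' Fraction of an arbor's total length (or lateral membrane area) whose
#' path-distance midpoint falls in each bin.  The two distributions coincide
#' bin-by-bin for a constant-diameter arbor (area is proportional to length)
#' and are compared with a Kolmogorov-Smirnov test in the group analysis.
#'
#' @param m a `morphology`.
#' @param quantity `"length"` or `"area"`.
#' @param bin_width bin width in um.
#' @param arbor `"apical"`, `"basal"` or `"all"` (all dendritic segments).
#' @return tibble with `bin_lo`, `bin_hi`, `bin_mid` and `fraction`
#'   (fractions sum to 1).
#' @export
distribution_by_distance <- function(m, quantity = c("length", "area"),
                                     bin_width = 50, arbor = c("apical", "basal", "all")) {
  quantity <- match.arg(quantity)
  arbor <- match.arg(arbor)
  seg <- morph_segments(m)
  if (arbor != "all") seg <- seg[seg$arbor == arbor, ] else {
    if (any(seg$arbor == "other")) {
      warn("segments with structure 'other' excluded from arbor analysis.")
    }
    seg <- seg[seg$arbor %in% c("apical", "basal"), ]
  }
  if (nrow(seg) == 0) abort(sprintf("empty %s arbor.", arbor))
  w <- if (quantity == "length") seg$length else seg$area
  edges <- seq(0, max(seg$mid_dist) + bin_width, by = bin_width)
  idx <- findInterval(seg$mid_dist, edges, rightmost.closed = TRUE)
  frac <- vapply(seq_len(length(edges) - 1L),
                 function(b) sum(w[idx == b]), numeric(1))
  tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
         bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
         fraction = frac / sum(frac))
}

#' Per-arbor morphometry summary
#'
#' One row per arbor with total dendritic length, total lateral surface area,
#' number of segments and maximal path distance; a compact per-neuron
#' morphometric record.
#'
#' @param m a `morphology`.
#' @return tibble with one row per arbor present.
#' @export
morphometry <- function(m) {
  seg <- morph_segments(m)
  if (nrow(seg) == 0) abort("morphology has no dendritic segments.")
  seg |>
    group_by(arbor = .data$arbor) |>
    summarise(total_length = sum(.data$length),
              total_area = sum(.data$area),
              n_segments = n(),
              max_path_distance = max(.data$start_dist + .data$length),
              .groups = "drop")
}
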