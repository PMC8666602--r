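# Racetrack geometry: a closed corridor bounded by an outer and an inner
# ring of line segments, with a spawn region between them.

.lf_rounded_rect <- function(width, height, radius, n_arc = 8L) {
  hw <- width / 2 - radius
  hh <- height / 2 - radius
  corners <- list(
    c(hw, hh, 0), c(-hw, hh, pi / 2), c(-hw, -hh, pi), c(hw, -hh, 3 * pi / 2)
  )
  pts <- NULL
  for (cn in corners) {
    th <- cn[3] + seq(0, pi / 2, length.out = n_arc + 1L)
    pts <- rbind(pts, cbind(cn[1] + radius * cos(th), cn[2] + radius * sin(th)))
  }
  pts
}

.lf_ring_to_walls <- function(poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  cbind(poly[, 1], poly[, 2], poly[nxt, 1], poly[nxt, 2])
}

#' Construct a racetrack
#'
#' A track is a closed corridor: an outer boundary ring and an inner boundary
#' ring, both polygonized into line segments. Agents live (and spawn) in the
#' annular corridor between the rings and die on touching either boundary.
#'
#' @param outer,inner Matrices of ring vertices (columns x, y), outer given
#'   counter-clockwise. The rings must be closed (last vertex joins the
#'   first implicitly).
#' @return An object of class `track` with fields `walls` (segment matrix
#'   with columns x1, y1, x2, y2), `outer`, `inner` and `bbox`.
#' @seealso [default_track()] for the standard corridor.
#' @export
make_track <- function(outer, inner) {
  outer <- as.matrix(outer)
  inner <- as.matrix(inner)
  walls <- rbind(.lf_ring_to_walls(outer), .lf_ring_to_walls(inner))
  structure(list(
    walls = walls, outer = outer, inner = inner,
    bbox = c(xmin = min(outer[, 1]), xmax = max(outer[, 1]),
             ymin = min(outer[, 2]), ymax = max(outer[, 2]))
  ), class = "track")
}

#' The default corridor racetrack
#'
#' A rounded-rectangle corridor: outer boundary 40 x 25 length units with
#' corner radius 8, inner boundary offset inward by 6 units (corner radius
#' 2), giving a corridor of width 6 with straights and curves. The absolute
#' dimensions are a package choice; any closed corridor can be substituted
#' via [make_track()] or [track_from_yaml()].
#'
#' @param width,height Outer dimensions in length units.
#' @param corridor Corridor width in length units.
#' @param radius Outer corner radius.
#' @param n_arc Segments per quarter arc.
#' @return A `track`.
#' @examples
#' tr <- default_track()
#' nrow(tr$walls)
#' @export
default_track <- function(width = 40, height = 25, corridor = 6, radius = 8,
                          n_arc = 8L) {
  if (corridor >= min(width, height) / 2) stop("corridor too wide for the track")
  outer <- .lf_rounded_rect(width, height, radius, n_arc)
  inner <- .lf_rounded_rect(width - 2 * corridor, height - 2 * corridor,
                            max(radius - corridor, 0.5), n_arc)
  make_track(outer, inner)
}

# TRUE for points strictly inside the corridor (inside outer, outside inner).
.lf_in_corridor <- function(px, py, track) {
  .lf_in_polygon(px, py, track$outer) & !.lf_in_polygon(px, py, track$inner)
}

#' Write a track to YAML
#' @param track A [make_track()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
track_to_yaml <- function(track, path) {
  yaml::write_yaml(list(
    outer = lapply(seq_len(nrow(track$outer)),
                   function(i) as.numeric(track$outer[i, ])),
    inner = lapply(seq_len(nrow(track$inner)),
                   function(i) as.numeric(track$inner[i, ]))
  ), path, precision = 15L)
  invisible(path)
}

#' Read a track from YAML
#' @param path File written by [track_to_yaml()] (or hand-authored with the
#'   same schema: `outer` and `inner` lists of `[x, y]` vertices).
#' @return A `track`.
#' @export
track_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  make_track(do.call(rbind, x$outer), do.call(rbind, x$inner))
}

#' @export
print.track <- function(x, ...) {
  cat("<track> ", nrow(x$walls), " wall segments, bbox [",
      paste(signif(x$bbox, 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Plot a track (and optionally a trajectory)
#'
#' @param object A `track`.
#' @param trajectory Optional data frame with columns `x`, `y` (e.g. from
#'   [simulate_trajectory()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.track <- function(object, trajectory = NULL, ...) {
  walls <- tibble::tibble(x = object$walls[, 1], y = object$walls[, 2],
                          xend = object$walls[, 3], yend = object$walls[, 4])
  p <- ggplot2::ggplot(walls) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(trajectory)) {
    p <- p + ggplot2::geom_path(
      data = trajectory,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$episode),
      colour = "steelblue", linewidth = 0.3)
  }
  p
}
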