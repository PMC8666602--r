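# Vectorized 2D geometry primitives used by the simulator: segment-segment
# intersection (sensors vs walls), point-segment distance (body circle vs
# walls) and point-in-polygon tests (spawn region).

# Cross product (b - a) x (c - a); all arguments vectors of equal length.
.lf_cross <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Do segments (a, b) intersect segments (c, d)? Vectorized elementwise;
# touching endpoints count as intersection. Collinear overlaps are resolved
# by bounding-box overlap.
.lf_seg_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- .lf_cross(cx, cy, dx, dy, ax, ay)
  d2 <- .lf_cross(cx, cy, dx, dy, bx, by)
  d3 <- .lf_cross(ax, ay, bx, by, cx, cy)
  d4 <- .lf_cross(ax, ay, bx, by, dx, dy)
  straddle <- (d1 * d2 <= 0) & (d3 * d4 <= 0)
  degen <- d1 == 0 & d2 == 0 & d3 == 0 & d4 == 0
  boxes <- pmin(ax, bx) <= pmax(cx, dx) & pmax(ax, bx) >= pmin(cx, dx) &
    pmin(ay, by) <= pmax(cy, dy) & pmax(ay, by) >= pmin(cy, dy)
  (straddle & !degen) | (degen & boxes)
}

# Distance from points (px, py) to the segment (ax, ay)-(bx, by) (scalars).
.lf_pt_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  dx <- px - (ax + t * vx)
  dy <- py - (ay + t * vy)
  sqrt(dx * dx + dy * dy)
}

# Minimum distance from each point to any wall segment, computed on the
# full point x wall grid. walls: matrix with columns x1, y1, x2, y2.
.lf_min_wall_dist <- function(px, py, walls) {
  n <- length(px)
  m <- nrow(walls)
  if (m == 0L) return(rep(Inf, n))
  ax <- matrix(walls[, 1], n, m, byrow = TRUE)
  ay <- matrix(walls[, 2], n, m, byrow = TRUE)
  vx <- matrix(walls[, 3] - walls[, 1], n, m, byrow = TRUE)
  vy <- matrix(walls[, 4] - walls[, 2], n, m, byrow = TRUE)
  wx <- px - ax
  wy <- py - ay
  len2 <- vx * vx + vy * vy
  t <- pmin(1, pmax(0, (wx * vx + wy * vy) / pmax(len2, .Machine$double.eps)))
  dx <- wx - t * vx
  dy <- wy - t * vy
  sqrt(.lf_row_min(dx * dx + dy * dy))
}

.lf_row_min <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

# Does each segment (x1,y1)-(x2,y2) hit any wall segment? Full grid.
.lf_hits_any_wall <- function(x1, y1, x2, y2, walls) {
  n <- length(x1)
  m <- nrow(walls)
  if (m == 0L) return(rep(FALSE, n))
  cx <- matrix(walls[, 1], n, m, byrow = TRUE)
  cy <- matrix(walls[, 2], n, m, byrow = TRUE)
  dx <- matrix(walls[, 3], n, m, byrow = TRUE)
  dy <- matrix(walls[, 4], n, m, byrow = TRUE)
  hit <- .lf_seg_intersect(x1, y1, x2, y2, cx, cy, dx, dy)
  rowSums(hit) > 0L
}

# Crossing-number point-in-polygon test; poly is a closed ring given as a
# matrix of vertices (x, y), last vertex joined back to the first.
.lf_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
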