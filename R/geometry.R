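# Internal planar geometry helpers (projected meters throughout).

# distance from points (px, py) to one segment (x1,y1)-(x2,y2)
.seg_point_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# min distance from each point to a polyline given as a 2-column matrix
.polyline_dist <- function(px, py, line) {
  n <- nrow(line)
  if (n == 1) return(sqrt((px - line[1, 1])^2 + (py - line[1, 2])^2))
  d <- rep(Inf, length(px))
  for (k in seq_len(n - 1)) {
    d <- pmin(d, .seg_point_dist(px, py, line[k, 1], line[k, 2],
                                 line[k + 1, 1], line[k + 1, 2]))
  }
  d
}

# distance from a point to an axis-aligned rectangle (0 inside)
.rect_point_dist <- function(px, py, xmin, ymin, xmax, ymax) {
  dx <- pmax(xmin - px, 0, px - xmax)
  dy <- pmax(ymin - py, 0, py - ymax)
  sqrt(dx * dx + dy * dy)
}

.seg_seg_intersects <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(px, py, qx, qy, rx, ry)
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry)
    orient(px, py, qx, qy, rx, ry) == 0 &&
      min(px, qx) <= rx && rx <= max(px, qx) &&
      min(py, qy) <= ry && ry <= max(py, qy)
  on_seg(ax, ay, bx, by, cx, cy) || on_seg(ax, ay, bx, by, dx, dy) ||
    on_seg(cx, cy, dx, dy, ax, ay) || on_seg(cx, cy, dx, dy, bx, by)
}

# exact min distance from an axis-aligned rectangle to a polyline
.rect_polyline_dist <- function(xmin, ymin, xmax, ymax, line) {
  n <- nrow(line)
  inside <- function(px, py) px >= xmin && px <= xmax && py >= ymin && py <= ymax
  if (n == 1) return(.rect_point_dist(line[1, 1], line[1, 2], xmin, ymin, xmax, ymax))
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  edges <- cbind(corners, corners[c(2, 3, 4, 1), ])
  # lower bound per segment (endpoint distance minus segment length) lets
  # far segments be skipped once a nearby one has been measured
  d1 <- .rect_point_dist(line[-n, 1], line[-n, 2], xmin, ymin, xmax, ymax)
  d2 <- .rect_point_dist(line[-1, 1], line[-1, 2], xmin, ymin, xmax, ymax)
  seg_len <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  lb <- pmax(pmin(d1, d2) - seg_len, 0)
  best <- Inf
  for (k in order(lb)) {
    if (lb[k] >= best) break
    x1 <- line[k, 1]; y1 <- line[k, 2]; x2 <- line[k + 1, 1]; y2 <- line[k + 1, 2]
    if (inside(x1, y1) || inside(x2, y2)) return(0)
    hit <- FALSE
    for (e in 1:4) {
      if (.seg_seg_intersects(x1, y1, x2, y2,
                              edges[e, 1], edges[e, 2], edges[e, 3], edges[e, 4])) {
        hit <- TRUE; break
      }
    }
    if (hit) return(0)
    best <- min(best,
                min(.seg_point_dist(corners[, 1], corners[, 2], x1, y1, x2, y2)),
                .rect_point_dist(x1, y1, xmin, ymin, xmax, ymax),
                .rect_point_dist(x2, y2, xmin, ymin, xmax, ymax))
  }
  best
}

# points strictly inside / on boundary of a closed polygon (2-col matrix)
.in_polygon <- function(px, py, poly) {
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
}

.bbox_of <- function(xy) c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
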