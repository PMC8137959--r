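# Convex geometry on pixel-center point sets: hull, minimum-area enclosing
# rectangle (rotating calipers), and Feret diameters.

#' Convex hull of a point set
#'
#' @param points Two-column matrix of (x, y) coordinates.
#' @return List with `hull` (two-column matrix of hull vertices, ordered
#'   counter-clockwise in image coordinates, i.e. positive shoelace area
#'   with y pointing down) and `hull_area` (shoelace area, pixels^2).
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("convex hull needs at least 3 points")
  i <- grDevices::chull(points[, 1], points[, 2])
  hull <- points[i, , drop = FALSE]
  if (nrow(hull) < 3L) stop("collinear point set: hull is degenerate")
  a <- shoelace_area(hull)
  if (a < 0) { hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]; a <- -a }
  if (a <= 0) stop("collinear point set: hull is degenerate")
  colnames(hull) <- c("x", "y")
  list(hull = hull, hull_area = a)
}

# Directed extents of points along unit vector u and its left normal.
.extents <- function(pts, ux, uy) {
  pu <- pts[, 1] * ux + pts[, 2] * uy
  pn <- -pts[, 1] * uy + pts[, 2] * ux
  c(min(pu), max(pu), min(pn), max(pn))
}

#' Minimum-area enclosing rectangle
#'
#' Computes the smallest-area (possibly rotated) rectangle enclosing a
#' convex hull via rotating calipers: the optimum has one side collinear
#' with a hull edge, so only hull-edge orientations are examined. Ties in
#' area are broken by the smallest rotation angle.
#'
#' The reported `rotate_angle` lies in \[-90, 0): -90 degrees means an
#' axis-aligned rectangle and the angle increases toward 0 as the rectangle
#' is rotated clockwise (image coordinates, y down).
#'
#' @param hull Two-column matrix of convex polygon vertices (e.g. from
#'   [convex_hull()]).
#' @return List of class `min_area_rect`: `center` (x, y), `top_left`
#'   (corner with smallest y, then smallest x), `width` and `height`
#'   (width along the supporting edge), `rotate_angle` (degrees),
#'   `area`, and `corners` (4 x 2 matrix).
#' @export
min_area_rect <- function(hull) {
  hull <- as.matrix(hull)
  n <- nrow(hull)
  if (n < 3L) stop("degenerate hull: fewer than 3 vertices")
  best <- NULL
  for (k in seq_len(n)) {
    p1 <- as.numeric(hull[k, ]); p2 <- as.numeric(hull[k %% n + 1L, ])
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    ux <- ex / len; uy <- ey / len
    e <- .extents(hull, ux, uy)
    w <- e[2] - e[1]; h <- e[4] - e[3]
    area <- w * h
    ang <- rect_angle_from_direction(ux, uy)
    if (is.null(best) || area < best$area * (1 - 1e-12) ||
        (abs(area - best$area) <= best$area * 1e-12 && ang < best$rotate_angle)) {
      cu <- (e[1] + e[2]) / 2; cn <- (e[3] + e[4]) / 2
      center <- c(cu * ux - cn * uy, cu * uy + cn * ux)
      corners <- rbind(
        c(e[1], e[3]), c(e[2], e[3]), c(e[2], e[4]), c(e[1], e[4]))
      corners <- cbind(corners[, 1] * ux - corners[, 2] * uy,
                       corners[, 1] * uy + corners[, 2] * ux)
      best <- list(center = unname(center), width = w, height = h,
                   rotate_angle = ang, area = area, corners = unname(corners))
    }
  }
  if (is.null(best)) stop("degenerate hull: no valid edge")
  tl <- order(best$corners[, 2], best$corners[, 1])[1]
  best$top_left <- best$corners[tl, ]
  class(best) <- "min_area_rect"
  best
}

# Map an edge direction to the [-90, 0) rectangle-angle convention.
rect_angle_from_direction <- function(ux, uy) {
  phi <- atan2(uy, ux) * 180 / pi
  (phi %% 90) - 90
}

#' Feret diameters of a convex hull
#'
#' The Feret diameter along a direction is the distance between the two
#' parallel supporting tangents perpendicular to that direction. The
#' maximum over directions equals the largest pairwise vertex distance;
#' the minimum is attained measuring perpendicular to some hull edge, so
#' both are computed from the hull's vertices and edges alone.
#'
#' Angles are degrees in \[-180, 180\], measured from the +x axis in image
#' coordinates: `max_angle` is the direction of the maximizing chord,
#' `min_angle` the direction along which the minimum caliper distance is
#' measured (perpendicular to the supporting edge).
#'
#' @param hull Two-column matrix of convex polygon vertices.
#' @return List of class `feret_result`: `max_diameter`, `max_angle`,
#'   `min_diameter`, `min_angle`.
#' @export
feret <- function(hull) {
  hull <- as.matrix(hull)
  n <- nrow(hull)
  if (n < 3L) stop("degenerate hull: fewer than 3 vertices")
  # maximum: largest pairwise distance between hull vertices
  dx <- outer(hull[, 1], hull[, 1], "-")
  dy <- outer(hull[, 2], hull[, 2], "-")
  d2 <- dx^2 + dy^2
  i <- which.max(d2)
  r <- (i - 1L) %% n + 1L; c <- (i - 1L) %/% n + 1L
  max_d <- sqrt(d2[i])
  max_ang <- unname(atan2(hull[c, 2] - hull[r, 2],
                          hull[c, 1] - hull[r, 1]) * 180 / pi)
  # minimum: smallest caliper width perpendicular to a hull edge
  min_d <- Inf; min_ang <- NA_real_
  for (k in seq_len(n)) {
    p1 <- as.numeric(hull[k, ]); p2 <- as.numeric(hull[k %% n + 1L, ])
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    ux <- ex / len; uy <- ey / len
    pn <- -hull[, 1] * uy + hull[, 2] * ux
    w <- max(pn) - min(pn)
    if (w < min_d) {
      min_d <- w
      min_ang <- atan2(ux, -uy) * 180 / pi   # left normal of the edge
    }
  }
  if (!is.finite(min_d) || min_d <= 0) stop("degenerate hull: zero width")
  structure(list(max_diameter = max_d, max_angle = max_ang,
                 min_diameter = min_d, min_angle = min_ang),
            class = "feret_result")
}
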