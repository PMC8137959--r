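# Least-squares ellipse fitting and ellipse perimeter.

#' Fit an ellipse to contour points
#'
#' Direct least-squares conic fit constrained to an ellipse
#' (Fitzgibbon-type algebraic fit in the numerically stable partitioned
#' form), minimizing the algebraic residual of
#' \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F} over the contour points subject
#' to \eqn{4AC - B^2 = 1}. Coordinates are centered internally for
#' conditioning. A moments-based fit (from the region's second central
#' moments, exact for a uniformly filled ellipse) is available as a
#' fallback or by request.
#'
#' @param contour Two-column matrix of (x, y) boundary points (>= 5).
#' @param method `"direct"` (algebraic least squares, default) or
#'   `"moments"` (second central moments of the supplied points).
#' @return Object of class `fitted_ellipse`: `center` (x, y),
#'   `long_axis` and `short_axis` (full axis lengths, pixels),
#'   `angle` (major-axis direction, degrees), `area` (\eqn{\pi a b}),
#'   and `perimeter` (Ramanujan approximation, see [ellipse_perimeter()]).
#' @export
fit_ellipse <- function(contour, method = c("direct", "moments")) {
  method <- match.arg(method)
  xy <- as.matrix(contour)
  if (nrow(xy) < 5L) stop("ellipse fit needs at least 5 contour points")
  if (method == "direct") fit_ellipse_direct(xy) else fit_ellipse_moments(xy)
}

fit_ellipse_direct <- function(xy) {
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  x <- xy[, 1] - mx; y <- xy[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit degenerated: singular scatter matrix"))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1) where C1 encodes 4AC - B^2
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("ellipse fit degenerated to a non-ellipse conic")
  a1 <- vecs[, ok[1]]
  a1 <- a1 / sqrt(cond[ok[1]])          # enforce 4AC - B^2 = 1
  a2 <- as.vector(Tm %*% a1)
  conic_to_ellipse(c(a1, a2), mx, my)
}

fit_ellipse_moments <- function(xy) {
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  x <- xy[, 1] - mx; y <- xy[, 2] - my
  cxx <- mean(x^2); cyy <- mean(y^2); cxy <- mean(x * y)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2))
  if (any(ev$values <= 0)) stop("ellipse fit degenerated: collapsed moments")
  # boundary-ring moments: for points on an ellipse, the covariance
  # eigenvalue is about (semi-axis)^2 / 2 (exact for a circle)
  semi <- sqrt(2 * ev$values)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  make_fitted_ellipse(c(mx, my), semi[1], semi[2], ang)
}

# conic (A,B,C,D,E,F) in coordinates centered at (mx, my) -> geometric form
conic_to_ellipse <- function(p, mx, my) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  ctr <- tryCatch(solve(2 * Mq, -c(D, E)), error = function(e)
    stop("ellipse fit degenerated: singular conic"))
  Fc <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F
  ev <- eigen(Mq, symmetric = TRUE)
  s2 <- -Fc / ev$values
  if (any(s2 <= 0)) stop("ellipse fit degenerated to a non-ellipse conic")
  semi <- sqrt(s2)
  major <- which.max(semi)
  ang <- atan2(ev$vectors[2, major], ev$vectors[1, major]) * 180 / pi
  make_fitted_ellipse(c(ctr[1] + mx, ctr[2] + my),
                      max(semi), min(semi), ang)
}

make_fitted_ellipse <- function(center, semi_major, semi_minor, angle) {
  long_axis <- 2 * semi_major; short_axis <- 2 * semi_minor
  structure(list(
    center = unname(center),
    long_axis = long_axis,
    short_axis = short_axis,
    angle = ((angle + 90) %% 180) - 90,
    area = pi * semi_major * semi_minor,
    perimeter = ellipse_perimeter(long_axis, short_axis)),
    class = "fitted_ellipse")
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' \deqn{P = \pi (a + b) \left(1 + \frac{3h}{10 + \sqrt{4 - 3h}}\right),
#'   \quad h = \left(\frac{a - b}{a + b}\right)^2}
#' with semi-axes \eqn{a, b}. Exact in the circle limit (h = 0); relative
#' error below 1e-6 for axis ratios down to about 0.2.
#'
#' @param long_axis,short_axis Full axis lengths in pixels
#'   (`0 < short_axis <= long_axis`).
#' @return Perimeter in pixels.
#' @export
ellipse_perimeter <- function(long_axis, short_axis) {
  if (any(short_axis <= 0) || any(long_axis <= 0))
    stop("non-positive ellipse axis")
  if (any(short_axis > long_axis * (1 + 1e-12)))
    stop("short_axis exceeds long_axis")
  a <- long_axis / 2; b <- short_axis / 2
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
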