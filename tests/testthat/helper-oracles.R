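# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Feret diameter along direction phi (radians): extent of projections.
proj_width <- function(pts, phi) {
  p <- pts[, 1] * cos(phi) + pts[, 2] * sin(phi)
  max(p) - min(p)
}

# Brute-force max/min Feret: 0.1-degree sweep plus golden-section
# refinement of the projection-width function around the grid optimum
# (the bare grid has O(step) error at kinked minima).
oracle_feret <- function(pts, step_deg = 0.1) {
  phis <- seq(0, pi, by = step_deg * pi / 180)
  w <- vapply(phis, function(p) proj_width(pts, p), numeric(1))
  refine <- function(center, what) {
    stats::optimize(function(p) proj_width(pts, p),
                    interval = center + c(-2, 2) * step_deg * pi / 180,
                    maximum = (what == "max"), tol = 1e-12)
  }
  mx <- refine(phis[which.max(w)], "max")
  mn <- refine(phis[which.min(w)], "min")
  list(max_diameter = mx$objective, min_diameter = mn$objective)
}

# Brute-force minimum-area enclosing rectangle over orientations.
oracle_minrect_area <- function(pts, step_deg = 0.1) {
  area_at <- function(phi) proj_width(pts, phi) * proj_width(pts, phi + pi / 2)
  phis <- seq(0, pi / 2, by = step_deg * pi / 180)
  a <- vapply(phis, area_at, numeric(1))
  stats::optimize(area_at,
                  interval = phis[which.min(a)] + c(-2, 2) * step_deg * pi / 180,
                  tol = 1e-12)$objective
}

# O(n^2) pair-enumeration concordance, explicit loops.
oracle_harrell <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; npairs <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[j] > time[i] ||
        (time[j] == time[i] && event[j] == 0)
      if (!comparable) next
      npairs <- npairs + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / npairs
}

# Exact ellipse perimeter by arc-length quadrature (full axis lengths).
oracle_ellipse_perimeter <- function(long_axis, short_axis) {
  a <- long_axis / 2; b <- short_axis / 2
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# Winding-free point-in-convex-polygon check (all cross products one sign).
inside_convex <- function(px, py, hull, tol = 1e-9) {
  n <- nrow(hull)
  s <- 0
  for (k in seq_len(n)) {
    p1 <- hull[k, ]; p2 <- hull[k %% n + 1, ]
    cr <- (p2[1] - p1[1]) * (py - p1[2]) - (p2[2] - p1[2]) * (px - p1[1])
    if (abs(cr) < tol) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Hand-written Cox log partial likelihood, continuous time (no ties).
cox_loglik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Random blob point set fixture (polygon vertices, not a mask).
random_blob_points <- function(seed, n_vertices = 24) {
  set.seed(seed)
  a <- runif(1, 8, 25)
  b <- runif(1, 0.4, 1) * a
  th <- runif(1, 0, pi)
  ol <- gen_blob_outline(seed + 1000, mean_radius = 1,
                         irregularity = runif(1, 0, 0.4),
                         n_vertices = n_vertices)
  x <- ol[, 1] * a; y <- ol[, 2] * b
  cbind(x * cos(th) - y * sin(th), x * sin(th) + y * cos(th))
}

# Random valid blob mask fixture.
random_blob_mask <- function(seed) {
  set.seed(seed)
  for (attempt in 0:19) {
    a <- runif(1, 6, 18)
    b <- runif(1, 0.4, 1) * a
    m <- tryCatch(
      gen_mask(shape_spec("blob", a = a, b = max(b, 3),
                          theta = runif(1, -180, 179),
                          irregularity = runif(1, 0, 0.35),
                          seed = seed * 31L + attempt)),
      error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  stop("no valid blob mask for seed ", seed)
}

# Foreground pixel centers (x, y) of a mask.
mask_px <- function(mask) {
  g <- if (inherits(mask, "nucleus_mask")) mask$grid else mask
  fg <- which(g == 1L, arr.ind = TRUE)
  cbind(fg[, 2] - 1, fg[, 1] - 1)
}

# Censored survival instance with score/time ties for concordance tests.
random_survival_instance <- function(seed, n = 60) {
  set.seed(seed)
  time <- sample(1:20, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
  event <- rbinom(n, 1, 0.7)
  scores <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)
  list(scores = scores, time = time, event = event)
}
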