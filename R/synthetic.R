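# Synthetic data generation: masks with known analytic geometry, irregular
# blob outlines, survival cohorts drawn from a Cox model, and slide/ROI
# fixtures. Everything is deterministic given the seed arguments.

#' Analytic shape specification
#'
#' Describes one shape to rasterize into a binary mask. `a` and `b` are
#' half-extents in pixels (`a >= b > 0`); for blobs they are the mean
#' radii along the shape's own x and y axes before rotation. `theta` is
#' the orientation in degrees, counter-clockwise in image coordinates
#' (y down), in \[-180, 180).
#'
#' @param kind One of `"disk"`, `"ellipse"`, `"rectangle"`, `"blob"`.
#' @param a,b Half-axes / half-extents (pixels). For a disk `b` defaults
#'   to `a`.
#' @param theta Orientation (degrees).
#' @param center (x, y) center in 0-based pixel coordinates; defaults to
#'   the grid center.
#' @param grid (height, width) of the target grid in pixels.
#' @param irregularity,n_vertices,seed Blob-only parameters, passed to
#'   [gen_blob_outline()].
#' @return Object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("disk", "ellipse", "rectangle", "blob"),
                       a, b = if (kind == "disk") a else NULL,
                       theta = 0, center = NULL, grid = NULL,
                       irregularity = 0.3, n_vertices = 24, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(b)) stop("b is required for kind = ", kind)
  if (!(a >= b && b > 0)) stop("shape_spec requires a >= b > 0")
  if (theta < -180 || theta >= 180) stop("theta must lie in [-180, 180)")
  if (is.null(grid)) {
    side <- 2 * ceiling(a * (1 + irregularity)) + 7
    grid <- c(side, side)
  }
  if (is.null(center)) center <- c((grid[2] - 1) / 2, (grid[1] - 1) / 2)
  if (kind == "blob" && is.null(seed)) stop("blob shapes require a seed")
  structure(list(kind = kind, a = a, b = b, theta = theta,
                 center = center, grid = grid,
                 irregularity = irregularity, n_vertices = n_vertices,
                 seed = seed),
            class = "shape_spec")
}

#' Irregular star-convex blob outline
#'
#' Generates a closed star-convex polygon around the origin: `n_vertices`
#' equally spaced angles with radii drawn uniformly in
#' `mean_radius * [1 - irregularity, 1 + irregularity]`. With
#' `irregularity = 0` this is a regular n-gon.
#'
#' @param seed RNG seed (integer).
#' @param mean_radius Mean radius (pixels, or 1 for a unit blob).
#' @param irregularity Radial jitter fraction in \[0, 1).
#' @param n_vertices Number of polygon vertices (>= 8).
#' @return Two-column matrix of (x, y) vertices, counter-clockwise.
#' @export
gen_blob_outline <- function(seed, mean_radius = 10, irregularity = 0.3,
                             n_vertices = 24) {
  if (n_vertices < 8L) stop("n_vertices must be >= 8")
  if (irregularity < 0 || irregularity >= 1)
    stop("irregularity must lie in [0, 1)")
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  radii <- mean_radius * (1 + irregularity * stats::runif(n_vertices, -1, 1))
  cbind(x = radii * cos(ang), y = radii * sin(ang))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Rasterize a shape specification into a nucleus mask
#'
#' A pixel is foreground iff its center lies inside (or on the boundary
#' of) the analytic shape — the pixel-center rule, which makes analytic
#' areas and extents directly checkable. The shape must fit in the grid
#' with a 2-pixel margin.
#'
#' @param spec A [shape_spec()].
#' @param ... Passed to [nucleus_mask()] (identifiers).
#' @return A `nucleus_mask`.
#' @export
gen_mask <- function(spec, ...) {
  stopifnot(inherits(spec, "shape_spec"))
  h <- spec$grid[1]; w <- spec$grid[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  th <- spec$theta * pi / 180
  # rotate pixel centers into the shape's own frame
  dx <- px - spec$center[1]; dy <- py - spec$center[2]
  rx <- dx * cos(th) + dy * sin(th)
  ry <- -dx * sin(th) + dy * cos(th)
  inside <- switch(spec$kind,
    disk = ,
    ellipse = (rx / spec$a)^2 + (ry / spec$b)^2 <= 1,
    rectangle = abs(rx) <= spec$a & abs(ry) <= spec$b,
    blob = {
      outline <- gen_blob_outline(spec$seed, mean_radius = 1,
                                  irregularity = spec$irregularity,
                                  n_vertices = spec$n_vertices)
      poly <- cbind(outline[, 1] * spec$a, outline[, 2] * spec$b)
      point_in_polygon(rx, ry, poly)
    })
  g <- matrix(0L, h, w)
  g[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <- 1L
  if (any(g[1:2, ] == 1L) || any(g[(h - 1):h, ] == 1L) ||
      any(g[, 1:2] == 1L) || any(g[, (w - 1):w] == 1L))
    stop("shape does not fit in grid with a 2-pixel margin")
  nucleus_mask(g, ...)
}

# even-odd rule point-in-polygon test, vectorized over query points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Synthetic cohort configuration
#'
#' Study conditions for [gen_cohort()]: cohort size, per-patient nucleus
#' counts, true Cox coefficients, exponential baseline hazard and
#' independent exponential censoring, and the coupling from patient risk
#' to nucleus shape.
#'
#' Defaults emulate a diffuse large B-cell lymphoma cohort: 170 patients,
#' overall survival in years from an exponential baseline with rate
#' 0.2/year (median about 3.5 years), censoring rate 0.086/year (about
#' 30% censored), nucleus diameters 10–60 px at 0.25 um/px, and the first
#' covariate driving both hazard and nuclear elongation so geometric
#' features carry prognostic signal.
#'
#' @param n_patients Number of patients (>= 2).
#' @param nuclei_per_patient Scalar count or length-2 range; `0` skips
#'   mask generation (clinical table only).
#' @param beta True Cox coefficients per (standard-normal) covariate.
#' @param baseline_rate Exponential baseline hazard (1/years, > 0).
#' @param censor_rate Independent exponential censoring rate (1/years,
#'   >= 0; `0` disables censoring).
#' @param shape_effect Function `(lp, covariates) -> list(mean_radius,
#'   axis_ratio, irregularity)` mapping a patient's linear predictor to
#'   nucleus shape-distribution parameters; may use the RNG.
#' @param radius_range Range of mean nucleus radii (pixels).
#' @param seed RNG seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 170, nuclei_per_patient = 30,
                          beta = c(0.8, 0.3), baseline_rate = 0.2,
                          censor_rate = 0.086,
                          shape_effect = default_shape_effect,
                          radius_range = c(5, 30), seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  if (length(nuclei_per_patient) == 1L)
    nuclei_per_patient <- rep(nuclei_per_patient, 2L)
  structure(list(n_patients = as.integer(n_patients),
                 nuclei_per_patient = as.integer(nuclei_per_patient),
                 beta = beta, baseline_rate = baseline_rate,
                 censor_rate = censor_rate, shape_effect = shape_effect,
                 radius_range = radius_range, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default risk-to-shape coupling
#'
#' High-risk patients (large linear predictor) get more elongated nuclei:
#' the axis ratio b/a shrinks from ~0.95 toward ~0.3 as risk grows.
#'
#' @param lp Patient linear predictor (x . beta).
#' @param covariates Named covariate vector (unused by the default).
#' @return List with `axis_ratio` and `irregularity`.
#' @export
default_shape_effect <- function(lp, covariates) {
  list(axis_ratio = 0.3 + 0.65 * stats::plogis(-1.5 * lp),
       irregularity = 0.15)
}

#' Generate a synthetic cohort
#'
#' Covariates are independent standard normals. Survival time follows the
#' Cox model with exponential baseline via inverse-CDF sampling,
#' \eqn{T = -\log(U) / (\lambda_0 \exp(x \beta))}; censoring time is an
#' independent exponential; `OS = min(T, C)` and `FUS = 1` iff the event
#' was observed. Per-patient nucleus masks are irregular blobs whose
#' shape-distribution parameters come from `shape_effect` applied to the
#' patient's linear predictor, so geometric features carry signal about
#' risk whenever `beta` loads on the coupled covariate.
#'
#' @param config A [cohort_config()].
#' @return List with `clinical` (data.frame: patient_id, cov_1..cov_p,
#'   OS, FUS), `masks` (named list per patient of `nucleus_mask` lists;
#'   empty when `nuclei_per_patient` is 0), and `true_lp` (the latent
#'   linear predictors, for validation).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n <- config$n_patients
  p <- length(config$beta)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("cov_", seq_len(p))))
  lp <- as.vector(X %*% config$beta)
  Tt <- -log(stats::runif(n)) / (config$baseline_rate * exp(lp))
  Ct <- if (config$censor_rate > 0)
    stats::rexp(n, rate = config$censor_rate) else rep(Inf, n)
  OS <- pmin(Tt, Ct)
  FUS <- as.integer(Tt <= Ct)
  ids <- sprintf("synth_%04d", seq_len(n))
  clinical <- data.frame(patient_id = ids, X, OS = OS, FUS = FUS,
                         stringsAsFactors = FALSE)
  masks <- list()
  if (config$nuclei_per_patient[2] > 0L) {
    blob_seeds <- sample.int(.Machine$integer.max - 1L, n)
    masks <- lapply(seq_len(n), function(i) {
      k <- if (config$nuclei_per_patient[1] == config$nuclei_per_patient[2])
        config$nuclei_per_patient[1]
      else sample(config$nuclei_per_patient[1]:config$nuclei_per_patient[2], 1L)
      se <- config$shape_effect(lp[i], X[i, ])
      radii <- stats::runif(k, config$radius_range[1], config$radius_range[2])
      cell_seeds <- blob_seeds[i] %% 1000003L + seq_len(k)
      lapply(seq_len(k), function(j) {
        a <- radii[j]
        b <- min(a, max(2.5, a * se$axis_ratio))
        theta <- stats::runif(1, -180, 180 - 1e-9)
        # a very thin irregular tip can rasterize to a disconnected
        # sliver; retry with a perturbed blob seed (deterministic)
        for (attempt in 0:19) {
          m <- tryCatch(
            gen_mask(shape_spec("blob", a = a, b = b, theta = theta,
                                irregularity = se$irregularity,
                                seed = (cell_seeds[j] + 7919L * attempt) %%
                                  .Machine$integer.max),
                     patient_id = ids[i],
                     patch_id = sprintf("%s_HE_0_0", ids[i]),
                     cell_number = j * 2L),  # non-consecutive, like the dataset
            error = function(e) NULL)
          if (!is.null(m)) return(m)
        }
        stop("could not rasterize a valid nucleus for patient ", ids[i])
      })
    })
    names(masks) <- ids
  }
  list(clinical = clinical, masks = masks, true_lp = lp)
}

#' Generate a synthetic slide with ROI annotations
#'
#' Produces an RGB raster (integer array height x width x 3, values
#' 0–255): near-white background (all channels >= 245) with textured
#' non-white tissue inside the given rectangles, plus an ROI annotation
#' table in the upper-left/lower-right corner schema (0-based, half-open
#' rectangles).
#'
#' @param width,height Slide size in pixels.
#' @param tissue_regions List of `c(x0, y0, x1, y1)` rectangles.
#' @param seed RNG seed.
#' @param stain Stain label recorded in the annotations.
#' @return List with `image` (integer array) and `annotations`
#'   (data.frame: patient_id, tma_id, stain, x0, y0, x1, y1).
#' @export
gen_slide <- function(width, height, tissue_regions = list(), seed = 1L,
                      stain = "HE") {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  img <- array(sample(245:255, height * width * 3, replace = TRUE),
               dim = c(height, width, 3))
  ann <- list()
  for (i in seq_along(tissue_regions)) {
    r <- tissue_regions[[i]]
    if (r[1] < 0 || r[2] < 0 || r[3] > width || r[4] > height ||
        r[3] <= r[1] || r[4] <= r[2])
      stop("tissue region ", i, " outside slide bounds or inverted")
    rows <- (r[2] + 1):r[4]; cols <- (r[1] + 1):r[3]
    tex <- array(sample(80:200, length(rows) * length(cols) * 3,
                        replace = TRUE),
                 dim = c(length(rows), length(cols), 3))
    img[rows, cols, ] <- tex
    ann[[i]] <- data.frame(
      patient_id = sprintf("synth_%04d", i), tma_id = "TMA001",
      stain = stain, x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4],
      stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(patient_id = character(), tma_id = character(),
               stain = character(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), stringsAsFactors = FALSE)
  storage.mode(img) <- "integer"
  list(image = img, annotations = annotations)
}
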