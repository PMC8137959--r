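# Per-nucleus feature orchestration and the cell_shapes table dialect.

#' Derived shape factors
#'
#' Six unitless descriptors combining the fitted ellipse, Feret diameters
#' and convex-hull area:
#' \itemize{
#'   \item `esf = short_axis / long_axis` (elliptical shape factor)
#'   \item `csf = 4 pi * ellip_area / ellip_perimt^2` (circularity)
#'   \item `sf1 = short_axis / max_diameter`
#'   \item `sf2 = min_diameter / max_diameter`
#'   \item `elongation = max_diameter / min_diameter`
#'   \item `convexity = sqrt(ellip_area / hull_area)`
#' }
#' All of esf, csf, sf1, sf2 and elongation equal 1 for a perfect circle;
#' csf decreases toward 0 with increasing ellipticity.
#'
#' @param ellipse A `fitted_ellipse` (see [fit_ellipse()]).
#' @param feret_res A `feret_result` (see [feret()]).
#' @param hull_area Convex-hull area in pixels^2.
#' @return Named list with the six factors.
#' @export
shape_factors <- function(ellipse, feret_res, hull_area) {
  stopifnot(inherits(ellipse, "fitted_ellipse"),
            inherits(feret_res, "feret_result"))
  if (ellipse$long_axis <= 0 || ellipse$perimeter <= 0 ||
      feret_res$max_diameter <= 0 || feret_res$min_diameter <= 0 ||
      hull_area <= 0)
    stop("zero or negative denominator in shape factors")
  list(
    esf = ellipse$short_axis / ellipse$long_axis,
    csf = 4 * pi * ellipse$area / ellipse$perimeter^2,
    sf1 = ellipse$short_axis / feret_res$max_diameter,
    sf2 = feret_res$min_diameter / feret_res$max_diameter,
    elongation = feret_res$max_diameter / feret_res$min_diameter,
    convexity = sqrt(ellipse$area / hull_area)
  )
}

#' Compute all geometric features of one nucleus mask
#'
#' Runs the full per-nucleus chain: boundary tracing, convex hull,
#' minimum-area rotated rectangle, least-squares ellipse fit, Feret
#' diameters, and the six derived shape factors. The convex hull (and
#' everything downstream of it) is computed from all foreground pixel
#' centers, which is exact for point sets; the traced contour feeds the
#' ellipse fit.
#'
#' @param mask A `nucleus_mask` or binary matrix.
#' @param ellipse_method Passed to [fit_ellipse()]; with the default
#'   `"direct"`, a degenerate algebraic fit falls back to the
#'   moments-based fit when `ellipse_fallback = TRUE`.
#' @param ellipse_fallback Allow moments fallback on degenerate direct
#'   fits (default `TRUE`).
#' @return Object of class `nucleus_features`: a named list with the
#'   rectangle, ellipse and Feret results, `hull_area`, the six shape
#'   factors, and the mask identifiers.
#' @export
compute_features <- function(mask, ellipse_method = "direct",
                             ellipse_fallback = TRUE) {
  if (is.matrix(mask)) mask <- nucleus_mask(mask, validate = FALSE)
  validate_mask(mask)
  id <- mask_id_string(mask)
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, " failed for mask ", id, ": ", conditionMessage(e),
           call. = FALSE))
  }
  contour <- step("contour tracing", mask_to_contour(mask))
  fg <- which(mask$grid == 1L, arr.ind = TRUE)
  pts <- cbind(x = fg[, 2] - 1, y = fg[, 1] - 1)
  ch <- step("convex hull", convex_hull(pts))
  rect <- step("minimum-area rectangle", min_area_rect(ch$hull))
  fer <- step("Feret diameters", feret(ch$hull))
  ell <- tryCatch(
    fit_ellipse(contour, method = ellipse_method),
    error = function(e) {
      if (ellipse_fallback && !identical(ellipse_method, "moments"))
        fit_ellipse(contour, method = "moments")
      else stop("ellipse fit failed for mask ", id, ": ",
                conditionMessage(e), call. = FALSE)
    })
  sf <- step("shape factors", shape_factors(ell, fer, ch$hull_area))
  structure(c(
    list(patient_id = mask$patient_id, patch_id = mask$patch_id,
         cell_number = mask$cell_number,
         rect = rect, ellipse = ell, feret = fer,
         hull_area = ch$hull_area),
    sf), class = "nucleus_features")
}

# scalar numeric feature columns of the cell_shapes table
CELL_SHAPE_FEATURES <- c(
  "shortAxis", "longAxis", "ellip_perimt", "ellip_area",
  "maxDiameter", "minDiameter", "hull_area",
  "esf", "csf", "sf1", "sf2", "elongation", "convexity")

fmt_tuple <- function(v) sprintf("(%.6g, %.6g)", v[1], v[2])

#' Flatten nucleus features to a one-row data frame
#'
#' Produces a row in the cell_shapes dialect: tuple-valued columns
#' (`rectCenter`, `rectDimension`, `ellip_centroid`) serialized as
#' `"(x, y)"` strings. `rectCenter` holds the rectangle's center; the
#' top-left corner is additionally exposed as `rect_topleft` because the
#' two conventions coexist in the wild.
#'
#' @param feat A `nucleus_features` object.
#' @return One-row `data.frame`.
#' @export
features_row <- function(feat) {
  stopifnot(inherits(feat, "nucleus_features"))
  data.frame(
    patient_id = feat$patient_id,
    patch_id = feat$patch_id,
    cell_number = feat$cell_number,
    rectCenter = fmt_tuple(feat$rect$center),
    rectDimension = fmt_tuple(c(feat$rect$width, feat$rect$height)),
    rotate_angle = feat$rect$rotate_angle,
    ellip_centroid = fmt_tuple(feat$ellipse$center),
    shortAxis = feat$ellipse$short_axis,
    longAxis = feat$ellipse$long_axis,
    ellip_perimt = feat$ellipse$perimeter,
    ellip_area = feat$ellipse$area,
    maxDiameter = feat$feret$max_diameter,
    maxAngle = feat$feret$max_angle,
    minDiameter = feat$feret$min_diameter,
    minAngle = feat$feret$min_angle,
    hull_area = feat$hull_area,
    esf = feat$esf, csf = feat$csf, sf1 = feat$sf1, sf2 = feat$sf2,
    elongation = feat$elongation, convexity = feat$convexity,
    rect_topleft = fmt_tuple(feat$rect$top_left),
    stringsAsFactors = FALSE)
}

#' Compute features for a list of masks
#'
#' @param masks List of `nucleus_mask` objects.
#' @param microns_per_px Optional physical pixel size; when given, extra
#'   `*_um` columns with lengths in micrometers are appended (never
#'   applied silently to the pixel-valued columns).
#' @return `data.frame` with one row per mask (cell_shapes dialect).
#' @export
compute_features_table <- function(masks, microns_per_px = NULL) {
  rows <- lapply(masks, function(m) features_row(compute_features(m)))
  out <- do.call(rbind, rows)
  if (!is.null(microns_per_px)) {
    for (col in c("shortAxis", "longAxis", "ellip_perimt",
                  "maxDiameter", "minDiameter"))
      out[[paste0(col, "_um")]] <- out[[col]] * microns_per_px
  }
  out
}

#' Parse a "(x, y)" tuple column
#'
#' Lenient about whitespace and surrounding parentheses.
#'
#' @param s Character vector of `"(x, y)"` strings.
#' @return Two-column numeric matrix.
#' @export
parse_tuple <- function(s) {
  parts <- strsplit(gsub("[()]", "", s), ",")
  t(vapply(parts, function(p) as.numeric(trimws(p)), numeric(2)))
}
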