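# ROI annotation parsing and fixed-size patch extraction from raster
# slides. Rectangles are 0-based and half-open: [x0, x1) x [y0, y1).

VALID_STAINS <- c("HE", "CD10", "BCL6", "MUM1", "BCL2", "MYC")

#' Load ROI annotations from a CSV table
#'
#' Expects per-row: patient id, TMA id, stain, and the upper-left /
#' lower-right corner coordinates of the ROI rectangle at full
#' magnification. Column names are configurable because released
#' annotation tables vary.
#'
#' @param table Path to a CSV file, or a data.frame.
#' @param columns Named character vector mapping the canonical names
#'   (`patient_id`, `tma_id`, `stain`, `x0`, `y0`, `x1`, `y1`) to the
#'   table's column names.
#' @return `data.frame` of validated annotations with canonical columns.
#' @export
load_annotations <- function(table,
                             columns = c(patient_id = "patient_id",
                                         tma_id = "tma_id", stain = "stain",
                                         x0 = "x0", y0 = "y0",
                                         x1 = "x1", y1 = "y1")) {
  df <- if (is.character(table)) {
    if (!file.exists(table)) stop("annotation file not found: ", table)
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else as.data.frame(table)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols))
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(df[[columns["patient_id"]]]),
    tma_id = as.character(df[[columns["tma_id"]]]),
    stain = as.character(df[[columns["stain"]]]),
    x0 = as.numeric(df[[columns["x0"]]]),
    y0 = as.numeric(df[[columns["y0"]]]),
    x1 = as.numeric(df[[columns["x1"]]]),
    y1 = as.numeric(df[[columns["y1"]]]),
    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  bad_rect <- which(out$x1 <= out$x0 | out$y1 <= out$y0)
  if (length(bad_rect))
    stop("inverted ROI rectangle in annotation row(s): ",
         paste(bad_rect, collapse = ", "))
  bad_stain <- which(!(out$stain %in% VALID_STAINS))
  if (length(bad_stain))
    stop("unknown stain in annotation row(s) ",
         paste(bad_stain, collapse = ", "), ": ",
         paste(unique(out$stain[bad_stain]), collapse = ", "))
  out
}

#' Extract fixed-size patches from an ROI
#'
#' Tiles the ROI with size x size windows starting at its upper-left
#' corner, advancing by `stride` pixels, row-major (top-left toward
#' bottom-right). Windows that do not fit entirely inside the ROI are
#' dropped, never padded, so every returned patch has exactly the
#' requested side length; with `stride >= size` patches are disjoint.
#'
#' @param image Integer array height x width x 3 (values 0–255), e.g.
#'   from [gen_slide()] or [read_patch_png()].
#' @param roi One-row annotation (data.frame or list with `x0`, `y0`,
#'   `x1`, `y1`, and optionally `patient_id`, `stain`).
#' @param size,stride Patch side length and tiling step (pixels).
#' @return List of patches; each is a list with `pixels` (size x size x 3
#'   integer array), `patch_id` (`{patient}_{stain}_{row}_{col}`),
#'   `origin` (x, y of the top-left corner in slide coordinates),
#'   `patient_id`, `stain`.
#' @export
extract_patches <- function(image, roi, size = 224, stride = 224) {
  stopifnot(length(dim(image)) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  roi <- as.list(roi)
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > w || roi$y1 > h)
    stop("ROI extends outside the image bounds")
  pid <- if (!is.null(roi$patient_id)) roi$patient_id else "unknown"
  stain <- if (!is.null(roi$stain)) roi$stain else "HE"
  xs <- seq(roi$x0, by = stride, length.out =
              max(0, floor((roi$x1 - roi$x0 - size) / stride) + 1))
  ys <- seq(roi$y0, by = stride, length.out =
              max(0, floor((roi$y1 - roi$y0 - size) / stride) + 1))
  if (length(xs) == 0L || length(ys) == 0L) return(list())
  out <- vector("list", length(xs) * length(ys))
  n <- 0L
  for (j in seq_along(ys)) {        # rows outer: row-major order
    for (i in seq_along(xs)) {
      n <- n + 1L
      out[[n]] <- list(
        pixels = image[(ys[j] + 1):(ys[j] + size),
                       (xs[i] + 1):(xs[i] + size), , drop = FALSE],
        patch_id = sprintf("%s_%s_%d_%d", pid, stain, j - 1L, i - 1L),
        origin = c(x = xs[i], y = ys[j]),
        patient_id = pid, stain = stain)
    }
  }
  out
}

#' Is a patch informative (not mostly white)?
#'
#' A pixel is "white" when all three channels exceed `white_level`. The
#' patch is discarded (returns `FALSE`) iff the white fraction strictly
#' exceeds `max_white_fraction`; exactly at the threshold it is kept.
#'
#' @param patch A patch (list with `pixels`) or a bare H x W x 3 array.
#' @param white_level Channel intensity above which a pixel counts as
#'   white (default 220).
#' @param max_white_fraction Maximum tolerated white fraction (default
#'   0.5).
#' @return `TRUE` if the patch contains enough tissue to keep.
#' @export
is_informative <- function(patch, white_level = 220,
                           max_white_fraction = 0.5) {
  px <- if (is.list(patch)) patch$pixels else patch
  stopifnot(length(dim(px)) == 3)
  if (min(px) < 0 || max(px) > 255) stop("pixel values must lie in [0, 255]")
  white <- px[, , 1] > white_level & px[, , 2] > white_level &
    px[, , 3] > white_level
  mean(white) <= max_white_fraction
}

#' Extract and filter patches for a whole annotation table
#'
#' @param image Slide raster (see [extract_patches()]).
#' @param annotations Annotation table from [load_annotations()].
#' @param size,stride,white_level,max_white_fraction See
#'   [extract_patches()] and [is_informative()].
#' @return List of retained (informative) patches across all ROIs.
#' @export
extract_all_patches <- function(image, annotations, size = 224,
                                stride = 224, white_level = 220,
                                max_white_fraction = 0.5) {
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    ps <- extract_patches(image, annotations[i, ], size = size,
                          stride = stride)
    keep <- vapply(ps, is_informative, logical(1),
                   white_level = white_level,
                   max_white_fraction = max_white_fraction)
    out <- c(out, ps[keep])
  }
  out
}

#' Write patches as PNG files in the dataset layout
#'
#' Files go to `Patches/{stain}/{patient_id}/{patch_id}.png`.
#'
#' @param patches List of patches.
#' @param out_dir Root output directory.
#' @return Invisibly, the written file paths.
#' @export
write_patches <- function(patches, out_dir) {
  paths <- character(length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    d <- file.path(out_dir, "Patches", p$stain, p$patient_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, paste0(p$patch_id, ".png"))
    png::writePNG(p$pixels / 255, paths[i])
  }
  invisible(paths)
}

#' Read a patch PNG back as a 0–255 integer array
#'
#' @param path PNG file path.
#' @return Integer array H x W x 3.
#' @export
read_patch_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  storage.mode(a) <- "double"
  out <- round(a * 255)
  storage.mode(out) <- "integer"
  out
}
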