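# Pixel coordinate convention used throughout the package:
# origin at the top-left pixel center, x = column index, y = row index,
# both 0-based, y increasing downward. A mask matrix m[row, col] therefore
# holds the pixel whose center is (x = col - 1, y = row - 1).

#' Construct a nucleus mask object
#'
#' Wraps a binary matrix as a `nucleus_mask`, the unit consumed by the
#' morphometry functions. The foreground must form a single 8-connected
#' component of at least 5 pixels.
#'
#' @param grid Integer/logical matrix with values in \{0, 1\}.
#' @param patient_id,patch_id Identifiers carried through to feature rows.
#' @param cell_number Integer cell identifier (need not be consecutive).
#' @param validate If `TRUE` (default), enforce the mask invariants.
#' @return An object of class `nucleus_mask`.
#' @export
nucleus_mask <- function(grid, patient_id = NA_character_, patch_id = NA_character_,
                         cell_number = NA_integer_, validate = TRUE) {
  if (!is.matrix(grid)) stop("mask grid must be a matrix")
  storage.mode(grid) <- "integer"
  if (!all(grid %in% c(0L, 1L))) stop("non-binary mask: values outside {0, 1}")
  m <- structure(list(grid = grid, patient_id = patient_id,
                      patch_id = patch_id, cell_number = cell_number),
                 class = "nucleus_mask")
  if (validate) validate_mask(m)
  m
}

mask_id_string <- function(mask) {
  sprintf("(patient_id=%s, patch_id=%s, cell_number=%s)",
          mask$patient_id, mask$patch_id, mask$cell_number)
}

#' Validate nucleus mask invariants
#'
#' Checks that the foreground has at least 5 pixels, forms a single
#' 8-connected component, and does not touch the grid border.
#'
#' @param mask A `nucleus_mask`.
#' @param require_margin If `TRUE`, reject foreground on the outermost
#'   pixel rows/columns (generated masks always keep a margin; masks read
#'   from disk may legitimately touch the border, so readers pass `FALSE`).
#' @return The mask, invisibly; errors on violation.
#' @export
validate_mask <- function(mask, require_margin = FALSE) {
  g <- mask$grid
  nfg <- sum(g)
  if (nfg < 5L)
    stop("mask ", mask_id_string(mask), ": fewer than 5 foreground pixels")
  if (n_components8(g) != 1L)
    stop("mask ", mask_id_string(mask),
         ": foreground is not a single 8-connected component")
  if (require_margin) {
    if (any(g[1, ] == 1L) || any(g[nrow(g), ] == 1L) ||
        any(g[, 1] == 1L) || any(g[, ncol(g)] == 1L))
      stop("mask ", mask_id_string(mask), ": foreground touches the grid border")
  }
  invisible(mask)
}

# Number of 8-connected foreground components. Adjacent foreground pixel
# pairs are enumerated with vectorized shifts (E, S, SE, SW) and the
# component count comes from the resulting pixel-adjacency graph.
n_components8 <- function(g) {
  fg <- which(g == 1L)
  if (length(fg) == 0L) return(0L)
  nr <- nrow(g); nc <- ncol(g)
  idx <- matrix(seq_along(g), nr, nc)
  edge_pairs <- function(a, b) {
    keep <- g[a] == 1L & g[b] == 1L
    cbind(a[keep], b[keep])
  }
  e <- rbind(
    edge_pairs(as.vector(idx[, -nc]),      as.vector(idx[, -1])),        # E
    edge_pairs(as.vector(idx[-nr, ]),      as.vector(idx[-1, ])),        # S
    edge_pairs(as.vector(idx[-nr, -nc]),   as.vector(idx[-1, -1])),      # SE
    edge_pairs(as.vector(idx[-nr, -1]),    as.vector(idx[-1, -nc]))      # SW
  )
  # map pixel linear indices to 1..n vertex ids
  vid <- integer(length(g)); vid[fg] <- seq_along(fg)
  gr <- igraph::graph_from_edgelist(cbind(vid[e[, 1]], vid[e[, 2]]), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, length(fg) - igraph::vcount(gr)))
  igraph::components(gr)$no
}

#' Trace the outer boundary of a mask
#'
#' Follows the outer boundary of the (single) foreground component with
#' Moore-neighbor tracing, returning a closed simple polygon through the
#' centers of the boundary pixels. A shape w pixels wide therefore has a
#' contour extent of w - 1. Orientation is counter-clockwise in image
#' coordinates (positive shoelace area with y pointing down).
#'
#' @param mask A `nucleus_mask` (or bare binary matrix).
#' @param prune_collinear Drop vertices lying on straight runs, keeping
#'   only direction changes (e.g. a filled rectangle reduces to its 4
#'   corners). Default `FALSE`: ellipse fitting wants the dense contour.
#' @return Two-column matrix of (x, y) vertices; the polygon is implicitly
#'   closed (last vertex connects back to the first).
#' @export
mask_to_contour <- function(mask, prune_collinear = FALSE) {
  if (is.matrix(mask)) mask <- nucleus_mask(mask, validate = FALSE)
  g <- mask$grid
  if (sum(g) == 0L) stop("mask ", mask_id_string(mask), ": empty mask")
  if (n_components8(g) != 1L)
    stop("mask ", mask_id_string(mask), ": multi-component mask")
  path <- moore_trace(g)
  if (nrow(path) < 4L)
    stop("mask ", mask_id_string(mask), ": too few boundary points")
  xy <- cbind(x = path[, 2] - 1, y = path[, 1] - 1)
  if (shoelace_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  if (prune_collinear) xy <- prune_collinear_points(xy)
  xy
}

# Moore-neighbor boundary tracing (background-tracking radial sweep with
# Jacob's stopping criterion). Returns (row, col) pixels in visit order.
moore_trace <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  # pad so neighbor lookups never leave the array
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- g
  # clockwise Moore neighborhood starting at W (visual orientation, y down)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_index <- function(drr, dcc) which(dr == drr & dc == dcc)
  # start: first foreground pixel in raster order; its W neighbor is background
  rc <- which(p == 1L, arr.ind = TRUE)
  ord <- order(rc[, 1], rc[, 2])
  s_r <- rc[ord[1], 1]; s_c <- rc[ord[1], 2]
  if (nrow(rc) == 1L) return(cbind(s_r - 1L, s_c - 1L))
  path_r <- s_r; path_c <- s_c
  cur_r <- s_r; cur_c <- s_c
  cdir <- 1L                      # direction of current background pixel (W)
  first_move <- NULL
  max_steps <- 8L * (nrow(rc) + 4L)
  for (step in seq_len(max_steps)) {
    found_k <- 0L
    for (j in 0:7) {
      k <- (cdir - 1L + j) %% 8L + 1L     # clockwise scan from background
      rr <- cur_r + dr[k]; cc <- cur_c + dc[k]
      if (p[rr, cc] == 1L) { found_k <- k; break }
    }
    if (found_k == 0L) break              # isolated pixel, cannot reach here
    prev_k <- (found_k - 2L) %% 8L + 1L   # last background examined
    nxt_r <- cur_r + dr[found_k]; nxt_c <- cur_c + dc[found_k]
    # Jacob: stop when the start pixel is re-entered toward the same successor
    if (!is.null(first_move) &&
        cur_r == s_r && cur_c == s_c &&
        nxt_r == first_move[1] && nxt_c == first_move[2]) break
    if (is.null(first_move)) first_move <- c(nxt_r, nxt_c)
    # background pixel position, re-expressed relative to the next pixel
    b_r <- cur_r + dr[prev_k]; b_c <- cur_c + dc[prev_k]
    cdir <- dir_index(b_r - nxt_r, b_c - nxt_c)
    cur_r <- nxt_r; cur_c <- nxt_c
    if (!(cur_r == s_r && cur_c == s_c)) {
      path_r <- c(path_r, cur_r); path_c <- c(path_c, cur_c)
    }
  }
  keep <- !duplicated(cbind(path_r, path_c))
  cbind(path_r[keep], path_c[keep]) - 1L  # un-pad
}

prune_collinear_points <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(xy)
  prev <- xy[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- xy[c(2:n, 1L), , drop = FALSE]
  cross <- (xy[, 1] - prev[, 1]) * (nxt[, 2] - xy[, 2]) -
           (xy[, 2] - prev[, 2]) * (nxt[, 1] - xy[, 1])
  xy[abs(cross) > 1e-12, , drop = FALSE]
}

#' Shoelace (signed) polygon area
#'
#' Positive for counter-clockwise orientation in image coordinates
#' (y increasing downward).
#'
#' @param xy Two-column matrix of polygon vertices, implicitly closed.
#' @return Signed area in pixels squared.
#' @export
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}
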