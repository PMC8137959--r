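# Minimal NPY reader/writer for 2-D arrays (the per-nucleus mask format).
# Writes format version 1.0; reads 1.0 and 2.0, C or Fortran order, for
# the integer/boolean/float dtypes that can hold a binary mask.

#' Write a nucleus mask as an NPY file
#'
#' NPY version 1.0, dtype `|u1`, C (row-major) order. Round-trips
#' bit-exactly through [read_mask()].
#'
#' @param mask A `nucleus_mask` or binary integer matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  g <- if (inherits(mask, "nucleus_mask")) mask$grid else mask
  if (!is.matrix(g)) stop("mask must be a matrix")
  if (!all(g %in% c(0L, 1L))) stop("non-binary mask: values outside {0, 1}")
  header <- sprintf("{'descr': '|u1', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(g), ncol(g))
  # total header block (magic 6 + version 2 + len 2 + dict) padded to 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.raw(t(g)), con)          # C order: rows contiguous
  invisible(path)
}

# parse the python dict literal in an NPY header (regex; fields only)
parse_npy_header <- function(hdr) {
  descr <- regmatches(hdr, regexpr("'descr':\\s*'[^']+'", hdr))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shape_str <- regmatches(hdr, regexpr("'shape':\\s*\\(([^)]*)\\)", hdr))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shape_str), ",")[[1]])
  list(descr = descr, fortran = fortran, shape = shape)
}

#' Read an NPY file as a matrix
#'
#' Supports format versions 1.0 and 2.0, C or Fortran order, and the
#' dtypes `|u1`, `|i1`, `|b1`, `<i2`, `<i4`, `<i8`, `<u2`, `<u4`,
#' `<f4`, `<f8`.
#'
#' @param path NPY file path.
#' @return Numeric or integer matrix.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) stop("NPY file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("corrupt NPY header (bad magic) in ", path)
  ver <- as.integer(readBin(con, "raw", 2))
  hlen <- if (ver[1] == 1L)
    readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  else readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- rawToChar(readBin(con, "raw", hlen))
  info <- parse_npy_header(hdr)
  if (length(info$shape) != 2L)
    stop("expected 2-dimensional mask, got ",
         length(info$shape), "-dimensional array in ", path)
  n <- prod(info$shape)
  vals <- switch(info$descr,
    "|u1" = , "|b1" = as.integer(readBin(con, "raw", n)),
    "|i1" = readBin(con, "integer", n, size = 1),
    "<i2" = readBin(con, "integer", n, size = 2, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2, endian = "little",
                    signed = FALSE),
    "<i4" = , "<u4" = readBin(con, "integer", n, size = 4,
                              endian = "little"),
    "<i8" = , "<u8" = {
      # read as int32 pairs; the low word carries small values like 0/1
      w <- readBin(con, "integer", 2 * n, size = 4, endian = "little")
      lo <- w[seq(1, 2 * n, by = 2)]; hi <- w[seq(2, 2 * n, by = 2)]
      if (any(hi != 0 & !(hi == -1L & lo < 0)))
        stop("64-bit integer values exceed 32-bit range in ", path)
      lo
    },
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NPY dtype '", info$descr, "' in ", path))
  if (length(vals) != n) stop("truncated NPY data in ", path)
  if (info$fortran) matrix(vals, info$shape[1], info$shape[2])
  else t(matrix(vals, info$shape[2], info$shape[1]))
}

#' Read a nucleus mask from an NPY file
#'
#' Validates that the array is 2-D with values restricted to \{0, 1\}.
#' Identifiers default to the `Cells/{patient}/{patch}/{cell}.npy` path
#' components when the file lives in that layout.
#'
#' @param path NPY file path.
#' @param patient_id,patch_id,cell_number Optional identifier overrides.
#' @return A `nucleus_mask`.
#' @export
read_mask <- function(path, patient_id = NULL, patch_id = NULL,
                      cell_number = NULL) {
  g <- read_npy(path)
  if (!all(g %in% c(0, 1)))
    stop("non-binary mask in ", path, ": values outside {0, 1}")
  storage.mode(g) <- "integer"
  parts <- rev(strsplit(normalizePath(path, mustWork = FALSE),
                        .Platform$file.sep)[[1]])
  if (is.null(cell_number))
    cell_number <- suppressWarnings(as.integer(sub("\\.npy$", "", parts[1])))
  if (is.null(patch_id)) patch_id <- parts[2]
  if (is.null(patient_id)) patient_id <- parts[3]
  nucleus_mask(g, patient_id = patient_id, patch_id = patch_id,
               cell_number = cell_number, validate = FALSE)
}

#' Write a cohort's masks in the Cells/ directory layout
#'
#' Files go to `Cells/{patient_id}/{patch_id}/{cell_number}.npy`.
#'
#' @param masks Named list (per patient) of `nucleus_mask` lists, as
#'   produced by [gen_cohort()].
#' @param out_dir Root output directory.
#' @return Invisibly, the written file paths.
#' @export
write_cells <- function(masks, out_dir) {
  paths <- character(0)
  for (pid in names(masks)) {
    for (m in masks[[pid]]) {
      d <- file.path(out_dir, "Cells", m$patient_id, m$patch_id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(d, paste0(m$cell_number, ".npy"))
      write_mask(m, f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Read all masks under a Cells/ directory
#'
#' Cell numbers may be non-consecutive; no contiguity is assumed.
#'
#' @param cells_dir Path to a `Cells/` root.
#' @return List of `nucleus_mask` objects.
#' @export
read_cells <- function(cells_dir) {
  files <- list.files(cells_dir, pattern = "\\.npy$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no NPY masks found under ", cells_dir)
  lapply(files, read_mask)
}
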