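#' Voxel volume in Hounsfield units
#'
#' A `voxel_volume` is the package's CT-scan proxy: a 3D numeric array of
#' Hounsfield-unit (HU) values together with its world geometry. Voxel
#' indices are 0-based and a voxel's world coordinate refers to its
#' *center* (the dominant medical-imaging convention, and the one that
#' keeps distance computations symmetric).
#'
#' @param data 3D numeric array of finite HU values.
#' @param spacing Per-axis voxel size in mm (length 1 or 3, all > 0).
#' @param origin World position (mm) of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix (default
#'   identity).
#' @return An object of class `voxel_volume` with fields `data`,
#'   `spacing`, `origin`, `direction`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(data)) != 3L) {
    stop("volume data must have exactly 3 dimensions", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("each extent must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  stopifnot_finite(data, "HU values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L) stop("origin must be length 3", call. = FALSE)
  stopifnot_finite(origin, "origin")
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction must be a 3x3 orthonormal matrix", call. = FALSE)
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Integer label mask paired with a voxel volume
#'
#' Identifies anatomical bodies (e.g. ilium, sacrum, calibration inserts)
#' on the same grid as a [voxel_volume()]. Label 0 is background; every
#' nonzero label present in `labels` must appear in `table`.
#'
#' @param labels 3D integer array; 0 = background.
#' @param table Named integer vector mapping body name -> label value.
#' @param spacing,origin,direction Grid geometry, as for [voxel_volume()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, table, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  if (length(dim(labels)) != 3L) {
    stop("label data must have exactly 3 dimensions", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  table <- vapply(table, as.integer, integer(1))
  if (is.null(names(table)) || any(!nzchar(names(table)))) {
    stop("label table must be a named integer vector", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, table)
  if (length(missing) > 0L) {
    stop(sprintf("labels present in mask but absent from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(labels = labels, table = table,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 direction = as.matrix(direction)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, bodies: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s=%d", names(x$table), x$table),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the boolean mask of one body
#'
#' @param m A [label_mask()].
#' @param body Body name present in the label table.
#' @return Logical 3D array.
#' @export
body_mask <- function(m, body) {
  stopifnot(inherits(m, "label_mask"))
  if (!body %in% names(m$table)) {
    stop(sprintf("unknown body '%s'; known: %s", body,
                 paste(names(m$table), collapse = ", ")), call. = FALSE)
  }
  m$labels == m$table[[body]]
}

geometry_of <- function(x) {
  list(spacing = x$spacing, origin = x$origin, direction = x$direction,
       dim = dim(if (inherits(x, "label_mask")) x$labels else x$data))
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$direction - gb$direction)) <= tol
}

#' Voxel/world coordinate transforms
#'
#' Maps continuous 0-based voxel indices to world coordinates (mm) and
#' back. The two maps are exact inverses; out-of-grid points map to
#' indices outside `[0, extent - 1]` without error.
#'
#' @param v A [voxel_volume()] or [label_mask()].
#' @param idx Numeric vector of length 3 or an n x 3 matrix of
#'   (continuous, 0-based) voxel indices.
#' @param p Numeric vector of length 3 or an n x 3 matrix of world
#'   points (mm).
#' @return An object of the same shape as the input, transformed.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind_points(idx)
  w <- idx %*% (t(v$direction) * v$spacing)
  sweep(w, 2L, v$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, p) {
  p <- rbind_points(p)
  d <- sweep(p, 2L, v$origin, "-") %*% v$direction
  sweep(d, 2L, v$spacing, "/")
}

rbind_points <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  stopifnot(ncol(p) == 3L)
  p
}

# World coordinates of every voxel center along each axis (length = extent).
axis_coords <- function(v) {
  d <- geometry_of(v)$dim
  lapply(1:3, function(k) (seq_len(d[k]) - 1) * v$spacing[k])
}

## ---- file I/O --------------------------------------------------------

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.(mha|mhd)$", lp)) "metaimage"
  else stop(sprintf("unsupported volume format: '%s' (use .nii, .nii.gz, .mha or .mhd)",
                    basename(path)), call. = FALSE)
}

#' Read and write voxel volumes
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) is handled by the RNifti library; the
#' uncompressed MetaImage format (`.mha`, `.mhd` + `.raw`) by a minimal
#' built-in reader. Spacing and origin are taken from the file header.
#'
#' @param path File path.
#' @param v A [voxel_volume()] to write.
#' @return `read_volume()` returns a [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  g <- switch(fmt,
              nifti = read_nifti_raw(path),
              metaimage = read_metaimage_raw(path))
  voxel_volume(g$data, g$spacing, g$origin, g$direction)
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "voxel_volume"))
  switch(volume_format(path),
         nifti = write_nifti_raw(v$data, v$spacing, v$origin, v$direction,
                                 path, datatype = "double"),
         metaimage = write_metaimage_raw(v$data, v$spacing, v$origin,
                                         v$direction, path,
                                         type = "MET_DOUBLE"))
  invisible(path)
}

#' Read and write label masks
#'
#' The integer label grid is stored in the same formats as volumes; the
#' label table travels in a JSON sidecar (`<stem>.labels.json`, mapping
#' body name -> integer label).
#'
#' @param path File path of the label image.
#' @param m A [label_mask()] to write.
#' @param table_path Path of the JSON label table; defaults to the image
#'   path with its image extension replaced by `.labels.json`.
#' @return `read_label_mask()` returns a [label_mask()].
#' @export
read_label_mask <- function(path, table_path = default_table_path(path)) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!file.exists(table_path)) {
    stop(sprintf("label table not found: %s", table_path), call. = FALSE)
  }
  g <- switch(fmt,
              nifti = read_nifti_raw(path),
              metaimage = read_metaimage_raw(path))
  tab <- jsonlite::read_json(table_path, simplifyVector = TRUE)
  tab <- vapply(tab, as.integer, integer(1))
  label_mask(g$data, tab, g$spacing, g$origin, g$direction)
}

#' @rdname read_label_mask
#' @export
write_label_mask <- function(m, path, table_path = default_table_path(path)) {
  stopifnot(inherits(m, "label_mask"))
  switch(volume_format(path),
         nifti = write_nifti_raw(m$labels, m$spacing, m$origin, m$direction,
                                 path, datatype = "int32"),
         metaimage = write_metaimage_raw(m$labels, m$spacing, m$origin,
                                         m$direction, path, type = "MET_INT"))
  jsonlite::write_json(as.list(m$table), table_path, auto_unbox = TRUE)
  invisible(path)
}

default_table_path <- function(path) {
  sub("\\.(nii\\.gz|nii|mha|mhd)$", ".labels.json", path, ignore.case = TRUE)
}

read_nifti_raw <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop header attributes
  if (length(dim(arr)) != 3L) {
    stop(sprintf("expected a 3D image, got %dD", length(dim(arr))),
         call. = FALSE)
  }
  x <- RNifti::xform(im)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  direction <- sweep(x[1:3, 1:3], 2L, spacing, "/")
  list(data = arr, spacing = spacing, origin = x[1:3, 4],
       direction = direction)
}

write_nifti_raw <- function(arr, spacing, origin, direction, path, datatype) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing
  m <- diag(4)
  m[1:3, 1:3] <- direction %*% diag(spacing)
  m[1:3, 4] <- origin
  RNifti::sform(im) <- structure(m, code = 2L)
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

## Minimal MetaImage (ITK .mha/.mhd) support, uncompressed only.

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                     MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line", call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (is.null(ndims) || ndims != 3L) {
    stop(sprintf("expected a 3D image, got %sD", hdr[["NDims"]]), call. = FALSE)
  }
  if (!is.null(hdr[["CompressedData"]]) &&
      toupper(hdr[["CompressedData"]]) == "TRUE") {
    stop("compressed MetaImage data is not supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  if (!type %in% names(metaimage_types)) {
    stop(sprintf("unsupported ElementType: %s", type), call. = FALSE)
  }
  spacing <- if (!is.null(hdr[["ElementSpacing"]])) {
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  } else rep(1, 3)
  origin <- if (!is.null(hdr[["Offset"]])) {
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  } else rep(0, 3)
  direction <- if (!is.null(hdr[["TransformMatrix"]])) {
    matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]),
           nrow = 3L, byrow = TRUE)
  } else diag(3)
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (toupper(datafile) == "LOCAL") {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw_con, what = metaimage_types[[type]], n = n,
                  size = metaimage_sizes[[type]], signed = signed,
                  endian = "little")
  if (length(vals) != n) stop("truncated MetaImage data block", call. = FALSE)
  list(data = array(vals, dim = dims), spacing = spacing, origin = origin,
       direction = direction)
}

write_metaimage_raw <- function(arr, spacing, origin, direction, path, type) {
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(format(t(direction), digits = 17, trim = TRUE),
                  collapse = " ")),
    sprintf("Offset = %s",
            paste(format(origin, digits = 17, trim = TRUE), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(spacing, digits = 17, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", datafile))
  size <- metaimage_sizes[[type]]
  vals <- as.vector(arr)
  if (metaimage_types[[type]] == "integer") storage.mode(vals) <- "integer"
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local_data) {
    writeBin(vals, con, size = size, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(vals, rcon, size = size, endian = "little")
    close(rcon)
  }
  invisible(path)
}
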