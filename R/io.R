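#' Read a CT volume or label mask from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mha`,
#' `.mhd` + `.raw`). Integer-encoded HU values are preserved bit-exact.
#' Spacing and origin are taken from the header; a file without 3 spatial
#' dimensions or without spacing information is a header error. Orientation
#' matrices beyond spacing + translation are not interpreted: the package
#' works in voxel index order (x, y, z) mapped to physical mm via spacing
#' and origin.
#'
#' @param path Path to the file.
#' @return `read_volume()` returns a [ct_volume()]; `read_mask()` returns a
#'   [label_mask()].
#' @export
read_volume <- function(path) {
  raw <- read_any_volume(path)
  ct_volume(raw$data, spacing = raw$spacing, origin = raw$origin)
}

#' @rdname read_volume
#' @param schema Label schema for the mask, see [lung_label_schema()].
#' @export
read_mask <- function(path, schema = lung_label_schema()) {
  raw <- read_any_volume(path)
  if (any(abs(raw$data - round(raw$data)) > 1e-6))
    stop("mask file contains non-integer values")
  label_mask(array(as.integer(round(raw$data)), dim = dim(raw$data)),
             spacing = raw$spacing, origin = raw$origin, schema = schema)
}

#' Write a CT volume or label mask to disk
#'
#' Format is chosen by extension: `.nii`/`.nii.gz` (NIfTI) or `.mha`/`.mhd`
#' (MetaImage). Integer-valued data is stored as 16-bit integers so HU
#' round-trips bit-exact; anything else as 64-bit float (NIfTI: 32-bit).
#'
#' @param volume A [ct_volume()] or [label_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  g <- grid_of(volume)
  arr <- if (inherits(volume, "label_mask")) volume$labels else volume$voxels
  ext <- volume_format(path)
  if (ext %in% c("nii", "nii.gz")) {
    write_nifti_file(arr, g$spacing, g$origin, path)
  } else {
    write_meta_file(arr, g$spacing, g$origin, path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii\\.gz$", lp)) return("nii.gz")
  if (grepl("\\.nii$", lp)) return("nii")
  if (grepl("\\.mha$", lp)) return("mha")
  if (grepl("\\.mhd$", lp)) return("mhd")
  stop("unrecognized volume format (expected .nii, .nii.gz, .mha or .mhd): ",
       path)
}

read_any_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(fmt,
         nii = , nii.gz = read_nifti_file(path),
         mha = , mhd = read_meta_file(path))
}

# ---- NIfTI via RNifti ------------------------------------------------------

read_nifti_file <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("header error: expected 3 spatial dimensions, found ", length(d))
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) ||
      any(spacing[1:3] <= 0))
    stop("header error: missing or invalid voxel spacing")
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (is.null(xf)) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  list(data = array(as.numeric(img), dim = d), spacing = spacing[1:3],
       origin = origin)
}

write_nifti_file <- function(arr, spacing, origin, path) {
  integerish <- all(abs(arr - round(arr)) < 1e-9) &&
    min(arr) >= -32768 && max(arr) <= 32767
  img <- RNifti::asNifti(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path,
                     datatype = if (integerish) "int16" else "float")
  invisible(path)
}

# ---- MetaImage (.mha / .mhd) ----------------------------------------------
# Minimal MetaImage implementation: uncompressed, little-endian, identity
# transform. No installed R package reads this format.

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE))

read_meta_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header is "Key = Value" text lines; binary data may follow ElementDataFile
  end <- grepRaw("ElementDataFile", bytes)
  if (length(end) == 0L) stop("header error: no ElementDataFile key")
  nl <- grepRaw("\n", bytes, offset = end[1])
  if (length(nl) == 0L) nl <- length(bytes)
  header_txt <- rawToChar(bytes[seq_len(nl[1])])
  lines <- strsplit(header_txt, "\n", fixed = TRUE)[[1]]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  h <- setNames(as.list(vals[!is.na(keys)]), keys[!is.na(keys)])

  if (is.null(h$NDims) || as.integer(h$NDims) != 3L)
    stop("header error: expected NDims = 3")
  if (is.null(h$DimSize)) stop("header error: missing DimSize")
  if (is.null(h$ElementSpacing)) stop("header error: missing ElementSpacing")
  dims <- as.integer(strsplit(trimws(h$DimSize), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(h$ElementSpacing), "\\s+")[[1]])
  if (length(dims) != 3L || any(dims < 1L)) stop("header error: bad DimSize")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("header error: bad ElementSpacing")
  origin <- if (!is.null(h$Offset))
    as.numeric(strsplit(trimws(h$Offset), "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(h$CompressedData) && tolower(h$CompressedData) == "true")
    stop("header error: compressed MetaImage data is not supported")
  type <- meta_types[[h$ElementType %||% "MET_SHORT"]]
  if (is.null(type)) stop("header error: unsupported ElementType ",
                          h$ElementType)
  n <- prod(dims)
  if (identical(toupper(trimws(h$ElementDataFile)), "LOCAL")) {
    data_raw <- bytes[seq.int(nl[1] + 1L, length(bytes))]
  } else {
    rawpath <- file.path(dirname(path), trimws(h$ElementDataFile))
    if (!file.exists(rawpath)) stop("missing raw data file: ", rawpath)
    data_raw <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  if (length(data_raw) < n * type$size)
    stop("format error: truncated MetaImage data")
  vals <- readBin(data_raw, what = type$what, n = n, size = type$size,
                  signed = type$signed, endian = "little")
  list(data = array(as.numeric(vals), dim = dims), spacing = spacing,
       origin = origin)
}

write_meta_file <- function(arr, spacing, origin, path) {
  integerish <- all(abs(arr - round(arr)) < 1e-9) &&
    min(arr) >= -32768 && max(arr) <= 32767
  type <- if (integerish) "MET_SHORT" else "MET_DOUBLE"
  local_data <- grepl("\\.mha$", tolower(path))
  dims <- dim(arr)
  datafile <- if (local_data) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  header <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    sprintf("Offset = %.9g %.9g %.9g\n", origin[1], origin[2], origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n",
            spacing[1], spacing[2], spacing[3]),
    sprintf("DimSize = %d %d %d\n", dims[1], dims[2], dims[3]),
    sprintf("ElementType = %s\n", type),
    sprintf("ElementDataFile = %s\n", datafile))
  vals <- as.vector(arr)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  if (local_data) {
    write_meta_data(vals, con, type)
  } else {
    close(con)
    on.exit()
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    write_meta_data(vals, rawcon, type)
  }
  invisible(path)
}

write_meta_data <- function(vals, con, type) {
  if (type == "MET_SHORT") {
    writeBin(as.integer(round(vals)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
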