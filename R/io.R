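#' Read a medical-image volume
#'
#' Reads a 3D scalar volume from NIfTI (`.nii`, `.nii.gz`) or MetaImage
#' (`.mha`, uncompressed, local data). Spacing and origin metadata are taken
#' from the file header; a file without spacing metadata, or a non-3D image,
#' is a hard error. Masks (`kind = "mask"`) are binarized at 0.5 so files
#' stored as 0/255 read as 0/1.
#'
#' @param path path to an existing image file.
#' @param kind one of `"ct"`, `"ventilation"`, `"mask"`; masks return an
#'   `sv_mask`, other kinds an `sv_volume`.
#' @return [volume()] or [binary_mask()].
#' @export
read_volume <- function(path, kind = c("ct", "ventilation", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    v <- read_nifti_volume(path)
  } else if (grepl("\\.mha$", lp)) {
    v <- read_mha_volume(path)
  } else {
    stop(sprintf("unrecognized image format: %s (expected .nii/.nii.gz/.mha)",
                 path))
  }
  if (kind == "mask") {
    binary_mask(v$data, v$spacing, v$origin)
  } else {
    v
  }
}

read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  a <- array(as.numeric(a), dim(a))  # strip RNifti attributes
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop(sprintf("volume must be 3D: %s", path))
  sp <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("missing or invalid spacing metadata: %s", path))
  xf <- try(RNifti::xform(im), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error")) org <- as.numeric(xf[1:3, 4])
  volume(a, spacing = sp, origin = org)
}

#' Write a volume to disk
#'
#' Writes NIfTI (`.nii`/`.nii.gz`) or uncompressed local MetaImage (`.mha`).
#' Masks are written as unsigned 8-bit; other volumes as 32-bit float
#' (MetaImage) or double (NIfTI). The geometry (spacing, origin) is stored in
#' the header so that `read_volume(write_volume(v))` reproduces the grid.
#'
#' @param v an `sv_volume` or `sv_mask`.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    im <- RNifti::asNifti(v$data)
    RNifti::pixdim(im) <- v$spacing
    m <- diag(c(v$spacing, 1))
    m[1:3, 4] <- v$origin
    im <- RNifti::`sform<-`(im, structure(m, code = 2L))
    RNifti::writeNifti(im, path,
                       datatype = if (is_mask(v)) "uint8" else "double")
  } else if (grepl("\\.mha$", lp)) {
    write_mha_volume(v, path)
  } else {
    stop(sprintf("unrecognized output format: %s", path))
  }
  invisible(path)
}

# -- minimal MetaImage (.mha, local, uncompressed) codec ---------------------
# Supports MET_UCHAR/MET_SHORT/MET_FLOAT/MET_DOUBLE scalar volumes with
# little-endian data, which covers mask and CT interchange with ITK tools.

read_mha_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop(sprintf("unexpected end of header: %s", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop(sprintf("malformed MetaImage header line: %s", line))
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop(sprintf("only local-data MetaImage supported: %s", path))
  ndims <- as.integer(hdr[["NDims"]])
  if (!identical(ndims, 3L)) stop(sprintf("volume must be 3D: %s", path))
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- hdr[["ElementSpacing"]]
  if (is.null(sp)) sp <- hdr[["ElementSize"]]
  if (is.null(sp)) stop(sprintf("missing spacing metadata: %s", path))
  sp <- as.numeric(strsplit(sp, "\\s+")[[1]])
  org <- hdr[["Offset"]]
  org <- if (is.null(org)) c(0, 0, 0) else as.numeric(strsplit(org, "\\s+")[[1]])
  comp <- hdr[["CompressedData"]]
  if (!is.null(comp) && toupper(comp) == "TRUE")
    stop(sprintf("compressed MetaImage not supported: %s", path))
  type <- hdr[["ElementType"]]
  n <- prod(dm)
  dat <- switch(type,
    MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                   endian = "little")),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop(sprintf("unsupported ElementType %s: %s", type, path)))
  if (length(dat) != n) stop(sprintf("truncated MetaImage data: %s", path))
  volume(array(dat, dm), spacing = sp, origin = org)
}

write_mha_volume <- function(v, path) {
  dm <- dim(v$data)
  type <- if (is_mask(v)) "MET_UCHAR" else "MET_FLOAT"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", dm[1], dm[2], dm[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g",
                   v$spacing[1], v$spacing[2], v$spacing[3]),
           sprintf("Offset = %.9g %.9g %.9g",
                   v$origin[1], v$origin[2], v$origin[3]),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (is_mask(v)) {
    writeBin(as.integer(v$data), con, size = 1)
  } else {
    writeBin(as.numeric(v$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a deformation field
#'
#' Reads a per-voxel displacement field (mm) stored as a 4D NIfTI with the
#' three displacement components in the fourth dimension. The displacement
#' convention is `x' = x + u(x)` in world mm on the exhale grid.
#'
#' @param path path to a 4D NIfTI file with last dimension 3.
#' @return a [deformation_field()].
#' @export
read_dvf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  a <- array(as.numeric(a), dim(a))
  if (length(dim(a)) == 5L && dim(a)[4] == 1L) a <- a[, , , 1, ]
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop(sprintf("deformation field must be 4D with 3 components: %s", path))
  sp <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("missing or invalid spacing metadata: %s", path))
  xf <- try(RNifti::xform(im), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error")) org <- as.numeric(xf[1:3, 4])
  deformation_field(a, spacing = sp, origin = org)
}

#' Write a deformation field
#'
#' @param dvf a [deformation_field()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_dvf <- function(dvf, path) {
  im <- RNifti::asNifti(dvf$u)
  RNifti::pixdim(im) <- c(dvf$spacing, 1)
  m <- diag(c(dvf$spacing, 1))
  m[1:3, 4] <- dvf$origin
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}
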