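# Volume I/O: MetaImage (.mha/.mhd) and NIfTI (.nii/.nii.gz).
#
# MetaImage is a plain text header (key = value lines) followed by (or
# pointing at) raw voxel data; no package in the R ecosystem reads it, so a
# minimal reader/writer for the axis-aligned case is provided here. Spacing
# and origin are written in full double precision, so a MetaImage round trip
# is bit-exact. NIfTI goes through RNifti; its header stores geometry as
# float32, so round trips are exact to single precision (~1e-7 relative).

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_meta_path <- function(path) grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)

met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_USHORT = "integer",
               MET_SHORT = "integer", MET_UINT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
               MET_UINT = 4L, MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_meta_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    key <- kv[2]; val <- trimws(kv[3])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L) stop("only 3D MetaImage volumes are supported (NDims = ", ndims, ")")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_UCHAR"
  if (!type %in% names(met_types)) stop("unsupported MetaImage ElementType: ", type)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE") {
    stop("compressed MetaImage data is not supported")
  }
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) && toupper(hdr$BinaryDataByteOrderMSB) == "TRUE"
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw_con <- con
  } else {
    close(con); on.exit(NULL)
    raw_path <- file.path(dirname(path), data_file)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con))
  }
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw_con, what = met_types[[type]], n = n, size = met_sizes[[type]],
                  signed = if (met_sizes[[type]] <= 2) signed else TRUE,
                  endian = if (msb) "big" else "little")
  list(values = array(as.numeric(vals), dims), spacing = spacing, origin = origin)
}

write_meta_volume <- function(values, spacing, origin, path, type = NULL) {
  dims <- dim(values)
  if (is.null(type)) {
    integral <- all(values == round(values)) && min(values) >= 0 && max(values) <= 255
    type <- if (integral) "MET_UCHAR" else "MET_DOUBLE"
  }
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", num(origin)),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", num(spacing)),
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", if (mhd) basename(sub("\\.mhd$", ".raw", path)) else "LOCAL")
  )
  write_raw <- function(con) {
    if (type == "MET_UCHAR") {
      writeBin(as.raw(as.integer(values)), con)
    } else if (type == "MET_DOUBLE") {
      writeBin(as.numeric(values), con, size = 8)
    } else if (type == "MET_FLOAT") {
      writeBin(as.numeric(values), con, size = 4)
    } else stop("unsupported write type ", type)
  }
  if (mhd) {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), basename(sub("\\.mhd$", ".raw", path))), "wb")
    on.exit(close(con))
    write_raw(con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    write_raw(con)
  }
  invisible(path)
}

read_volume <- function(path) {
  if (is_meta_path(path)) {
    read_meta_volume(path)
  } else if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) stop("expected a 3D volume in ", path, " (got ", length(d), "D)")
    xf <- RNifti::xform(img)
    list(values = array(as.numeric(img), d),
         spacing = abs(RNifti::pixdim(img))[1:3],
         origin = as.numeric(xf[1:3, 4]))
  } else {
    stop("unrecognised volume format: ", path, " (use .mha, .mhd, .nii or .nii.gz)")
  }
}

write_volume <- function(values, spacing, origin, path) {
  if (is_meta_path(path)) {
    write_meta_volume(values, spacing, origin, path)
  } else if (is_nifti_path(path)) {
    img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
    m <- diag(c(spacing, 1)); m[1:3, 4] <- origin
    RNifti::pixdim(img) <- spacing
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    stop("unrecognised volume format: ", path)
  }
  invisible(path)
}

#' Read and write masked images
#'
#' A masked image is stored as two volumes: the grey/binary values and the
#' whole-bone label mask. Formats are chosen from the file extension:
#' MetaImage (`.mha` single file, `.mhd` + `.raw`) or NIfTI
#' (`.nii`/`.nii.gz`). Geometry (spacing, origin) is taken from the headers;
#' the two volumes must agree in dimensions and, to within 1e-6 mm, in
#' spacing and origin.
#'
#' @param grey_path,mask_path paths to the value and mask volumes.
#' @param side anatomical side flag to attach (`"left"`, `"right"`,
#'   `"unknown"`).
#' @return `load_masked_image()` returns a [masked_image].
#' @export
load_masked_image <- function(grey_path, mask_path, side = "unknown") {
  g <- read_volume(grey_path)
  m <- read_volume(mask_path)
  if (!identical(dim(g$values), dim(m$values))) {
    stop("dimension mismatch: grey ", paste(dim(g$values), collapse = "x"),
         " vs mask ", paste(dim(m$values), collapse = "x"))
  }
  if (max(abs(g$spacing - m$spacing)) > 1e-6 || max(abs(g$origin - m$origin)) > 1e-6) {
    stop("grey and mask volumes disagree in spacing/origin beyond 1e-6 mm")
  }
  masked_image(g$values, m$values, spacing = g$spacing, origin = g$origin, side = side)
}

#' @rdname load_masked_image
#' @param img a [masked_image] to write.
#' @export
write_masked_image <- function(img, grey_path, mask_path) {
  stopifnot(inherits(img, "masked_image"))
  write_volume(img$values, img$spacing, img$origin, grey_path)
  write_volume(img$mask, img$spacing, img$origin, mask_path)
  invisible(c(grey_path, mask_path))
}
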