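## Volume file I/O. Internal frame is always LPS, voxel-center convention.
## NIfTI stores RAS world coordinates: converted on read/write by negating
## the first two world components (x, y). NRRD and MetaImage are written in
## LPS directly.

RAS_TO_LPS <- diag(c(-1, -1, 1))

volume_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.nrrd$", p)) return("nrrd")
  if (grepl("\\.(mha|mhd)$", p)) return("metaimage")
  stop("unsupported volume format: ", basename(path),
       " (supported: .nii/.nii.gz, .nrrd, .mha/.mhd)")
}

#' Read a 3D volume (NIfTI, NRRD or MetaImage)
#'
#' Geometry is converted to the package's internal frame: LPS world
#' coordinates, 0-based voxel indices, voxel-center convention. Intensities
#' are stored as double regardless of the on-disk type and are not rescaled.
#'
#' @param path path to a `.nii`/`.nii.gz`, `.nrrd`, `.mha` or `.mhd` file.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  switch(volume_format(path),
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         metaimage = read_meta_volume(path))
}

#' Write a 3D volume (format chosen by file extension)
#'
#' @param volume a [volume3d()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.nrrd`, `.mha` or
#'   `.mhd`.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  switch(volume_format(path),
         nifti = write_nifti_volume(volume, path),
         nrrd = write_nrrd_volume(volume, path),
         metaimage = write_meta_volume(volume, path))
  invisible(path)
}

## ---- NIfTI ------------------------------------------------------------

read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- array(a, dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop("expected a 3D image, got ", length(dim(a)), "D: ", path)
  x <- structure(RNifti::xform(im), code = NULL) # voxel -> RAS, 4x4
  m <- RAS_TO_LPS %*% x[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  direction <- sweep(m, 2, spacing, "/")
  origin <- as.numeric(RAS_TO_LPS %*% x[1:3, 4])
  volume3d(a, spacing, origin, direction)
}

write_nifti_volume <- function(volume, path) {
  m <- RAS_TO_LPS %*% (volume$direction %*% diag(volume$spacing))
  x <- rbind(cbind(m, RAS_TO_LPS %*% volume$origin), c(0, 0, 0, 1))
  im <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(im) <- volume$spacing
  im <- RNifti::`sform<-`(im, structure(x, code = 2L))
  im <- RNifti::`qform<-`(im, structure(x, code = 2L))
  RNifti::writeNifti(im, path)
}

## ---- NRRD -------------------------------------------------------------

nrrd_vec <- function(v) paste0("(", paste(format(v, digits = 17), collapse = ","), ")")

parse_nrrd_vec <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):[ =]?(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "[ ]+")[[1]])
  if (is.null(ndim) || ndim != 3L)
    stop("expected a 3D NRRD, got dimension ", ndim, ": ", path)
  type <- tolower(fields[["type"]])
  rtype <- switch(type,
                  "double" = list(what = "double", size = 8),
                  "float" = list(what = "double", size = 4),
                  "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
                  "unsigned short" = , "ushort" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
                  "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
                  "uchar" = , "unsigned char" = , "uint8" = list(what = "integer", size = 1, signed = FALSE),
                  stop("unsupported NRRD type: ", type))
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (enc %in% c("gzip", "gz")) {
    raw_rest <- readBin(con, "raw", n = file.info(path)$size)
    zcon <- gzcon(rawConnection(raw_rest))
    on.exit(close(zcon), add = TRUE)
    vals <- readBin(zcon, rtype$what, n = n, size = rtype$size, endian = endian,
                    signed = if (is.null(rtype$signed)) TRUE else rtype$signed)
  } else if (enc == "raw") {
    vals <- readBin(con, rtype$what, n = n, size = rtype$size, endian = endian,
                    signed = if (is.null(rtype$signed)) TRUE else rtype$signed)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data: ", path)
  space <- tolower(fields[["space"]] %||% "left-posterior-superior")
  dirs <- fields[["space directions"]]
  if (is.null(dirs)) {
    m <- diag(3)
  } else {
    parts <- regmatches(dirs, gregexpr("\\([^)]*\\)", dirs))[[1]]
    m <- vapply(parts, parse_nrrd_vec, numeric(3))
  }
  origin <- if (is.null(fields[["space origin"]])) c(0, 0, 0)
            else parse_nrrd_vec(fields[["space origin"]])
  if (space %in% c("right-anterior-superior", "ras")) {
    m <- RAS_TO_LPS %*% m; origin <- as.numeric(RAS_TO_LPS %*% origin)
  } else if (!space %in% c("left-posterior-superior", "lps")) {
    stop("unsupported NRRD space: ", space)
  }
  spacing <- sqrt(colSums(m^2))
  direction <- sweep(m, 2, spacing, "/")
  volume3d(array(as.double(vals), sizes), spacing, origin, direction)
}

write_nrrd_volume <- function(volume, path, encoding = "gzip") {
  m <- volume$direction %*% diag(volume$spacing)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(dim(volume$voxels), collapse = " ")),
           paste("space directions:", nrrd_vec(m[, 1]), nrrd_vec(m[, 2]), nrrd_vec(m[, 3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           paste("space origin:", nrrd_vec(volume$origin)),
           "")
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (encoding == "gzip") {
    zcon <- gzcon(con)
    writeBin(as.double(volume$voxels), zcon, size = 8, endian = "little")
    close(zcon) # closes underlying con too
  } else {
    writeBin(as.double(volume$voxels), con, size = 8, endian = "little")
    close(con)
  }
}

## ---- MetaImage --------------------------------------------------------

read_meta_volume <- function(path) {
  hdr_lines <- character(); data_offset <- NULL
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("no ElementDataFile field in ", path)
    hdr_lines <- c(hdr_lines, line)
    if (grepl("^\\s*ElementDataFile", line)) break
  }
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  fields <- stats::setNames(vapply(kv, function(x) trimws(x[2]), ""),
                            vapply(kv, function(x) trimws(x[1]), ""))
  if (!identical(fields[["ObjectType"]], "Image")) stop("not a MetaImage image: ", path)
  ndims <- as.integer(fields[["NDims"]])
  if (ndims != 3L) stop("expected a 3D image, got NDims=", ndims, ": ", path)
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if ("Offset" %in% names(fields))
    as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if ("TransformMatrix" %in% names(fields))
    matrix(as.numeric(strsplit(fields[["TransformMatrix"]], "\\s+")[[1]]), 3, 3)
  else diag(3) # stored column-by-column: each group of 3 is one axis direction
  etype <- fields[["ElementType"]]
  rtype <- switch(etype,
                  MET_DOUBLE = list(what = "double", size = 8),
                  MET_FLOAT = list(what = "double", size = 4),
                  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                  MET_INT = list(what = "integer", size = 4, signed = TRUE),
                  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                  stop("unsupported ElementType: ", etype))
  msb <- identical(fields["BinaryDataByteOrderMSB"][[1]], "True")
  n <- prod(sizes)
  datafile <- fields[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(con, rtype$what, n = n, size = rtype$size,
                    endian = if (msb) "big" else "little",
                    signed = if (is.null(rtype$signed)) TRUE else rtype$signed)
  } else {
    dcon <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(dcon), add = TRUE)
    vals <- readBin(dcon, rtype$what, n = n, size = rtype$size,
                    endian = if (msb) "big" else "little",
                    signed = if (is.null(rtype$signed)) TRUE else rtype$signed)
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  volume3d(array(as.double(vals), sizes), spacing, origin, direction)
}

write_meta_volume <- function(volume, path) {
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", paste(format(as.numeric(volume$direction), digits = 17), collapse = " ")),
           paste("Offset =", paste(format(volume$origin, digits = 17), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           "AnatomicalOrientation = LPS",
           paste("ElementSpacing =", paste(format(volume$spacing, digits = 17), collapse = " ")),
           paste("DimSize =", paste(dim(volume$voxels), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.double(volume$voxels), con, size = 8, endian = "little")
    close(con)
  } else {
    close(con)
    dcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.double(volume$voxels), dcon, size = 8, endian = "little")
    close(dcon)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
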