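#' Named fiducial points in world coordinates
#'
#' A set of labeled 3D landmarks in LPS world millimetres. The A-value
#' computation requires the labels `round_window` and `basal_turn`;
#' registration initialization uses `apex`, `modiolus`, `round_window` and
#' `oval_window`. Arbitrary additional labels are allowed.
#'
#' @param points named list of length-3 numeric vectors, or an N x 3 matrix
#'   with unique rownames.
#' @param laterality `"left"`, `"right"` or `NA` if unknown.
#' @return an object of class `fiducial_set`.
#' @examples
#' fiducial_set(list(round_window = c(0, 0, 0), basal_turn = c(3, 4, 0)))
#' @export
fiducial_set <- function(points, laterality = NA_character_) {
  if (is.list(points)) {
    labs <- names(points)
    pts <- do.call(rbind, lapply(points, function(p) {
      if (length(p) != 3L) stop("each fiducial must have 3 coordinates")
      as.numeric(p)
    }))
    rownames(pts) <- labs
  } else {
    pts <- as.matrix(points)
    storage.mode(pts) <- "double"
  }
  if (is.null(rownames(pts)) || any(rownames(pts) == ""))
    stop("fiducials must be labeled")
  if (anyDuplicated(rownames(pts)))
    stop("duplicate fiducial label: ",
         paste(unique(rownames(pts)[duplicated(rownames(pts))]), collapse = ", "))
  if (ncol(pts) != 3L || any(!is.finite(pts)))
    stop("fiducial coordinates must be finite 3-vectors (mm)")
  if (!is.na(laterality) && !laterality %in% c("left", "right"))
    stop('`laterality` must be "left", "right" or NA')
  structure(list(points = pts, laterality = laterality), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d points (laterality: %s)\n",
              nrow(x$points), x$laterality))
  print(round(x$points, 4))
  invisible(x)
}

#' @export
length.fiducial_set <- function(x) nrow(x$points)

fiducial_labels <- function(set) rownames(set$points)

#' Extract a fiducial's world coordinates by label
#'
#' @param set a [fiducial_set()].
#' @param label fiducial label.
#' @return length-3 numeric world coordinate (mm).
#' @export
fiducial_point <- function(set, label) {
  stopifnot(inherits(set, "fiducial_set"))
  if (!label %in% rownames(set$points))
    stop("fiducial set is missing label '", label, "' (has: ",
         paste(rownames(set$points), collapse = ", "), ")")
  as.numeric(set$points[label, ])
}

#' Keep a subset of fiducials by label
#' @param set a [fiducial_set()].
#' @param labels labels to retain (all must be present).
#' @return a [fiducial_set()].
#' @export
subset_fiducials <- function(set, labels) {
  missing <- setdiff(labels, rownames(set$points))
  if (length(missing))
    stop("fiducial set is missing label(s): ", paste(missing, collapse = ", "))
  fiducial_set(set$points[labels, , drop = FALSE], set$laterality)
}

#' Read fiducials from CSV or 3D Slicer FCSV
#'
#' Two dialects are auto-detected. Plain CSV has a header `label,x,y,z`
#' (optionally a `laterality` column) with coordinates in LPS mm. Slicer
#' FCSV (detected by the `# Markups fiducial file` header or `.fcsv`
#' extension) stores RAS coordinates, converted to LPS by negating x and y.
#'
#' @param path file path.
#' @param laterality optional override; otherwise read from the file when a
#'   laterality column exists.
#' @return a [fiducial_set()].
#' @export
read_fiducials <- function(path, laterality = NULL) {
  if (!file.exists(path)) stop("fiducial file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_fcsv <- grepl("\\.fcsv$", tolower(path)) ||
    any(grepl("Markups fiducial file", lines[seq_len(min(3, length(lines)))]))
  if (is_fcsv) read_fcsv(lines, path, laterality)
  else read_fiducial_csv(lines, path, laterality)
}

read_fiducial_csv <- function(lines, path, laterality) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- tolower(strsplit(lines[1], ",")[[1]])
  need <- c("label", "x", "y", "z")
  if (!all(need %in% trimws(hdr)))
    stop("fiducial CSV must have header label,x,y,z: ", path)
  cols <- match(need, trimws(hdr))
  lat_col <- match("laterality", trimws(hdr))
  pts <- list(); lats <- character()
  for (i in seq_along(lines)[-1]) {
    f <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(f) < max(cols, na.rm = TRUE))
      stop("malformed fiducial row at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(f[cols[2:4]]))
    if (any(is.na(xyz)))
      stop("non-numeric coordinate at line ", i, " of ", path)
    lab <- f[cols[1]]
    if (lab %in% names(pts)) stop("duplicate fiducial label '", lab,
                                  "' at line ", i, " of ", path)
    pts[[lab]] <- xyz
    if (!is.na(lat_col) && length(f) >= lat_col) lats <- c(lats, f[lat_col])
  }
  lat <- laterality %||% (if (length(lats) && nzchar(lats[1])) lats[1] else NA_character_)
  fiducial_set(pts, lat)
}

read_fcsv <- function(lines, path, laterality) {
  data <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  pts <- list()
  for (i in seq_along(data)) {
    f <- strsplit(data[i], ",")[[1]]
    # Slicer markups: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,node
    if (length(f) < 12) stop("malformed FCSV row at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz))) stop("non-numeric coordinate at FCSV row ", i, " of ", path)
    lab <- trimws(f[12])
    if (lab %in% names(pts)) stop("duplicate fiducial label '", lab, "' in ", path)
    pts[[lab]] <- c(-xyz[1], -xyz[2], xyz[3]) # RAS -> LPS
  }
  fiducial_set(pts, laterality %||% NA_character_)
}

#' Write fiducials as CSV (`label,x,y,z,laterality`, LPS mm)
#'
#' @param set a [fiducial_set()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fiducials <- function(set, path) {
  stopifnot(inherits(set, "fiducial_set"))
  rows <- c("label,x,y,z,laterality",
            sprintf("%s,%s,%s,%s,%s", rownames(set$points),
                    format(set$points[, 1], digits = 17, trim = TRUE),
                    format(set$points[, 2], digits = 17, trim = TRUE),
                    format(set$points[, 3], digits = 17, trim = TRUE),
                    ifelse(is.na(set$laterality), "", set$laterality)))
  writeLines(rows, path)
  invisible(path)
}

#' Mirror a fiducial set consistently with its volume
#'
#' @param set a [fiducial_set()].
#' @param volume the (unmirrored) [volume3d()] whose center plane defines the
#'   reflection, as in [mirror_volume()].
#' @param plane_axis grid axis in 1..3.
#' @return mirrored [fiducial_set()] with flipped laterality.
#' @export
mirror_fiducials <- function(set, volume, plane_axis = 1) {
  pts <- mirror_point(set$points, volume, plane_axis)
  rownames(pts) <- rownames(set$points)
  lat <- switch(set$laterality, left = "right", right = "left", set$laterality)
  fiducial_set(pts, lat)
}
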