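#' Read a point cloud from PLY, OBJ or XYZ
#'
#' Reads vertex coordinates in file order. Faces in OBJ/PLY files are
#' discarded: the measurement pipeline operates purely on points, so meshes
#' are treated as their vertex sets.
#'
#' @param path Path to the file.
#' @param format One of \code{"ply"}, \code{"obj"}, \code{"xyz"} or
#'   \code{"auto"} (dispatch on file extension).
#' @return A \code{point_cloud}; \code{name} is the file stem.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "obj", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "xyz", "txt", "pts"))
      stop("cannot infer format from extension '", ext, "'; pass format=")
    format <- if (ext %in% c("txt", "pts")) "xyz" else ext
  }
  pts <- switch(format,
    ply = .read_ply_vertices(path),
    obj = .read_obj_vertices(path),
    xyz = .read_xyz(path))
  if (nrow(pts) == 0L) stop("file contains no vertices: ", path)
  point_cloud(pts, name = sub("\\.[^.]*$", "", basename(path)))
}

.parse_num_tokens <- function(tokens, path, lineno) {
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals))
    stop(sprintf("malformed numeric token in %s at line %d: '%s'",
                 path, lineno, paste(tokens[is.na(vals)], collapse = " ")))
  vals
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) return(matrix(numeric(0), 0, 3))
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop(sprintf("malformed coordinate line in %s at line %d", path, i))
    .parse_num_tokens(tok[1:3], path, i)
  })
  do.call(rbind, rows)
}

.read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- which(startsWith(lines, "v "))
  rows <- lapply(vidx, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop(sprintf("malformed vertex line in %s at line %d", path, i))
    .parse_num_tokens(tok[2:4], path, i)
  })
  if (length(rows) == 0L) return(matrix(numeric(0), 0, 3))
  do.call(rbind, rows)
}

# ASCII PLY only; x/y/z vertex properties must be the first three. Faces and
# extra elements after the vertex block are ignored.
.read_ply_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end_hdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(end_hdr)) stop("PLY header not terminated in ", path)
  hdr <- lines[seq_len(end_hdr)]
  fmt <- grep("^format", trimws(hdr), value = TRUE)
  if (length(fmt) && !grepl("ascii", fmt[1]))
    stop("only ascii PLY is supported: ", path)
  vline <- grep("^element vertex", trimws(hdr), value = TRUE)
  if (length(vline) == 0L) stop("PLY file has no vertex element: ", path)
  nvert <- as.integer(strsplit(vline[1], "[[:space:]]+")[[1]][3])
  if (is.na(nvert)) stop("malformed vertex count in PLY header: ", path)
  if (nvert == 0L) return(matrix(numeric(0), 0, 3))
  if (end_hdr + nvert > length(lines))
    stop("PLY file truncated: fewer vertex lines than declared in ", path)
  rows <- lapply(seq_len(nvert), function(j) {
    i <- end_hdr + j
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop(sprintf("malformed vertex line in %s at line %d", path, i))
    .parse_num_tokens(tok[1:3], path, i)
  })
  do.call(rbind, rows)
}

#' Write a point cloud to PLY, OBJ or XYZ
#'
#' Coordinates are written with enough precision (\code{\%.9g}) that a
#' read-back reproduces them to well under 1e-6.
#'
#' @param cloud A \code{point_cloud}.
#' @param path Output path; parent directory must exist.
#' @param format One of \code{"ply"}, \code{"obj"}, \code{"xyz"} or
#'   \code{"auto"} (from extension).
#' @return Invisibly, \code{path}.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "obj", "xyz")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "xyz"))
      stop("cannot infer format from extension '", ext, "'; pass format=")
    format <- ext
  }
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  p <- cloud$points
  coord_lines <- sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  out <- switch(format,
    xyz = coord_lines,
    obj = paste("v", coord_lines),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(p)),
            "property float x", "property float y", "property float z",
            "end_header", coord_lines))
  writeLines(out, path)
  invisible(path)
}

#' Read per-point labels (one integer per line)
#'
#' @param path Path to a label file.
#' @return Integer vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read labels: no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || any(vals != round(vals)))
    stop("non-integer label token in ", path)
  as.integer(vals)
}

#' Write per-point labels (one integer per line)
#'
#' @param labels Integer vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_labels <- function(labels, path) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers")
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Read a subjects-by-raters measurement matrix from CSV
#'
#' The CSV layout is: header row of rater/method identifiers, first column of
#' subject identifiers, cells in degrees. This is the table shape produced by
#' agreement studies in which several observers (and an automatic method) each
#' measure the same set of vertebrae.
#'
#' @param path CSV path.
#' @return A numeric S x R matrix with rownames = subject ids and
#'   colnames = rater ids.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("cannot read measurements: no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("measurement table needs >= 2 rater columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("measurement table has missing cells")
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a measurement matrix to CSV
#'
#' @param values Numeric S x R matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_measurements <- function(values, path) {
  df <- data.frame(subject = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged manual-vs-automatic measurement table
#'
#' The published 10-subject comparison study table: three human observers and
#' the automatic method each measured the axial rotation angle (degrees) of
#' ten vertebral models; cells are per-subject means over ten repeats.
#'
#' @return 10 x 4 numeric matrix (columns Observe1, Observe2, Observe3,
#'   Automatic).
#' @export
rotation_study_table <- function() {
  path <- system.file("extdata", "rotation_agreement_study.csv",
                      package = "vertrot", mustWork = TRUE)
  read_measurements(path)
}
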