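#' Construct a point cloud
#'
#' A point cloud is the universal currency of the measurement pipeline: an
#' ordered N x 3 matrix of Cartesian coordinates, conventionally in
#' millimetres. Point order is significant (labels and sampling indices refer
#' to it) and is preserved by all IO round trips.
#'
#' @param points Numeric N x 3 matrix (or coercible) of coordinates.
#' @param name Optional character identifier.
#' @return An object of class \code{point_cloud} with elements \code{points}
#'   and \code{name}.
#' @export
point_cloud <- function(points, name = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("'points' must be a numeric N x 3 matrix")
  if (nrow(points) < 1L)
    stop("point cloud must contain at least one point")
  if (!all(is.finite(points)))
    stop("all coordinates must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, name = name), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud%s: %d points>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$points)))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A \code{point_cloud} or \code{labeled_cloud}.
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  if (inherits(cloud, "labeled_cloud")) cloud <- cloud$cloud
  nrow(cloud$points)
}

#' Attach per-point labels to a cloud
#'
#' Binds a length-N integer label vector (0 = background, 1 = structure for
#' the two binary segmentation tasks) to a point cloud.
#'
#' @param cloud A \code{point_cloud}.
#' @param labels Integer vector, one label per point.
#' @return A \code{labeled_cloud} with elements \code{cloud} and
#'   \code{labels}.
#' @export
labeled_cloud <- function(cloud, labels) {
  stopifnot(inherits(cloud, "point_cloud"))
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers without missing values")
  if (length(labels) != nrow(cloud$points))
    stop(sprintf("label length (%d) does not match point count (%d)",
                 length(labels), nrow(cloud$points)))
  structure(list(cloud = cloud, labels = labels), class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud: %d points, %d labelled 1>\n",
              length(x$labels), sum(x$labels == 1L)))
  invisible(x)
}

#' Centre and scale a cloud to the unit ball
#'
#' Network input conditioning: translates the cloud so its centroid is at the
#' origin and scales it so the farthest point lies at distance 1. The returned
#' transform record inverts the mapping exactly.
#'
#' @param cloud A \code{point_cloud}.
#' @return List with \code{cloud} (the normalized \code{point_cloud}) and
#'   \code{transform}, a list holding \code{centroid} (length-3) and
#'   \code{scale} (positive scalar) such that
#'   \code{original = normalized * scale + centroid}.
#' @export
normalize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  centroid <- colMeans(p)
  centered <- sweep(p, 2L, centroid)
  scale <- sqrt(max(rowSums(centered^2)))
  if (scale <= 0)
    stop("degenerate cloud: all points coincide, scale is zero")
  list(cloud = point_cloud(centered / scale, name = cloud$name),
       transform = list(centroid = centroid, scale = scale))
}

#' Invert a normalization transform
#'
#' @param cloud A normalized \code{point_cloud}.
#' @param transform Transform record from \code{\link{normalize_cloud}}.
#' @return The \code{point_cloud} mapped back to original coordinates.
#' @export
denormalize_cloud <- function(cloud, transform) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- sweep(cloud$points * transform$scale, 2L, transform$centroid, "+")
  point_cloud(p, name = cloud$name)
}

#' Apply a rigid (or affine) transform to a cloud
#'
#' @param cloud A \code{point_cloud}.
#' @param rotation 3 x 3 matrix applied on the right as \code{p \%*\% t(R)}.
#' @param translation Length-3 offset added after rotation.
#' @return Transformed \code{point_cloud}.
#' @export
transform_cloud <- function(cloud, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points %*% t(rotation)
  p <- sweep(p, 2L, translation, "+")
  point_cloud(p, name = cloud$name)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues construction; used throughout the phantom generator and tests.
#'
#' @param axis Length-3 axis (normalized internally).
#' @param degrees Rotation angle in degrees (right-handed about \code{axis}).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, degrees) {
  a <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
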