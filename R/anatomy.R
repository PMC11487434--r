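#' Split a predicted endplate cloud into upper and lower plates
#'
#' The network's endplate prediction is one cloud containing both the superior
#' and inferior plate; they are separated by their spatial distribution with
#' 2-means clustering. "Upper" is the cluster whose centre has the greater
#' projection onto the inter-centre axis oriented toward positive global Z.
#'
#' @param endplate_points A \code{point_cloud} of predicted endplate points.
#' @param seed Integer seed for the K-means initialization.
#' @param nstart Number of K-means restarts (default 10, best inertia kept).
#' @param tol Minimum centre separation, as a fraction of the cloud diameter,
#'   below which the split is declared degenerate (default 1e-6).
#' @return List with \code{upper} and \code{lower} (\code{point_cloud}s) and
#'   \code{centers}, a list with \code{upper} and \code{lower} 3-vectors
#'   (cluster means, mm).
#' @export
split_endplates <- function(endplate_points, seed = 1L, nstart = 10L,
                            tol = 1e-6) {
  stopifnot(inherits(endplate_points, "point_cloud"))
  p <- endplate_points$points
  if (nrow(p) < 2L) stop("need at least 2 endplate points to split")
  km <- .seeded_kmeans(p, 2L, seed, nstart)
  c1 <- km$centers[1, ]
  c2 <- km$centers[2, ]
  diam <- sqrt(max(rowSums(sweep(p, 2L, colMeans(p))^2))) * 2
  if (sqrt(sum((c1 - c2)^2)) < tol * max(diam, 1))
    stop("degenerate endplate split: cluster centres coincide")
  axis <- c1 - c2
  if (axis[3] < 0) axis <- -axis  # orient the inter-centre axis toward +Z
  upper_first <- sum(c1 * axis) >= sum(c2 * axis)
  up_cl <- if (upper_first) 1L else 2L
  upper_idx <- km$cluster == up_cl
  list(
    upper = point_cloud(p[upper_idx, , drop = FALSE]),
    lower = point_cloud(p[!upper_idx, , drop = FALSE]),
    centers = list(upper = if (upper_first) c1 else c2,
                   lower = if (upper_first) c2 else c1)
  )
}

#' Locate the two pedicle centres
#'
#' Partitions the predicted pedicle cloud into two clusters with seeded
#' K-means and returns the cluster means in a deterministic order:
#' \code{left} is the centre with the smaller global X coordinate (ties broken
#' on Y, then Z).
#'
#' @param pedicle_points A \code{point_cloud} of predicted pedicle points.
#' @inheritParams split_endplates
#' @return List of class \code{pedicle_centers}: \code{left}, \code{right}
#'   3-vectors (mm) and \code{rule} recording the naming convention.
#' @export
pedicle_centers <- function(pedicle_points, seed = 1L, nstart = 10L) {
  stopifnot(inherits(pedicle_points, "point_cloud"))
  p <- pedicle_points$points
  if (nrow(p) < 2L) stop("need at least 2 pedicle points")
  if (max(apply(p, 2L, function(v) diff(range(v)))) == 0)
    stop("degenerate pedicle cloud: all points coincide")
  km <- .seeded_kmeans(p, 2L, seed, nstart)
  cs <- km$centers
  ord <- order(cs[, 1], cs[, 2], cs[, 3])
  structure(list(left = cs[ord[1], ], right = cs[ord[2], ],
                 rule = "left = smaller global X (ties: Y, then Z)"),
            class = "pedicle_centers")
}

.seeded_kmeans <- function(p, k, seed, nstart) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (nrow(unique(p)) < k) stop("fewer than ", k, " distinct points")
  if (nrow(p) == k) {
    # one point per cluster; stats::kmeans rejects this degenerate case
    return(list(cluster = seq_len(k), centers = p, tot.withinss = 0))
  }
  stats::kmeans(p, centers = k, nstart = nstart, iter.max = 100L)
}

#' Vertebral centroid from endplate centres
#'
#' The centroid sits at the midpoint of the segment joining the upper and
#' lower endplate centres; it is the origin of the local frame and the centre
#' of the transverse plane.
#'
#' @param centers List with \code{upper} and \code{lower} 3-vectors.
#' @return Length-3 midpoint.
#' @export
vertebral_centroid <- function(centers) {
  (centers$upper + centers$lower) / 2
}

#' Transverse plane of a vertebra
#'
#' The plane through the vertebral centroid whose normal is the line joining
#' the upper and lower endplate centres (the cranio-caudal axis).
#'
#' @param centers List with \code{upper} and \code{lower} 3-vectors.
#' @param tol Minimum axis length (mm) before the plane is degenerate.
#' @return List with \code{point} (the centroid) and unit \code{normal}.
#' @export
transverse_plane <- function(centers, tol = 1e-9) {
  axis <- centers$upper - centers$lower
  len <- sqrt(sum(axis^2))
  if (len < tol) stop("endplate centres coincide: transverse plane undefined")
  list(point = vertebral_centroid(centers), normal = axis / len)
}

#' Construct the vertebral local coordinate frame
#'
#' Origin at the vertebral centroid; z along the endplate axis (lower to
#' upper); y along the line from the pedicle midpoint to the centroid
#' (pointing anterior, away from the posterior pedicles); x = y cross z,
#' normalized. y and z are not forced orthogonal: the rotation angle uses only
#' in-plane projections, so a small non-orthogonality between the anatomical
#' axes is harmless and the anatomy is reported as found.
#'
#' @param ep_centers List with \code{upper}/\code{lower} endplate centres.
#' @param pd_centers A \code{pedicle_centers} object (or list with
#'   \code{left}/\code{right}).
#' @param tol Degeneracy tolerance relative to the axis lengths.
#' @return List of class \code{local_frame}: \code{origin}, unit
#'   \code{x_axis}, \code{y_axis}, \code{z_axis}.
#' @export
local_frame <- function(ep_centers, pd_centers, tol = 1e-6) {
  origin <- vertebral_centroid(ep_centers)
  pd_mid <- (pd_centers$left + pd_centers$right) / 2
  y <- origin - pd_mid
  z <- ep_centers$upper - ep_centers$lower
  ylen <- sqrt(sum(y^2)); zlen <- sqrt(sum(z^2))
  scale <- max(ylen, zlen, 1e-12)
  if (ylen < tol * scale)
    stop("pedicle midpoint coincides with the centroid: y-axis undefined")
  if (zlen < tol * scale)
    stop("endplate centres coincide: z-axis undefined")
  y <- y / ylen; z <- z / zlen
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  xlen <- sqrt(sum(x^2))
  if (xlen < tol) stop("y-axis parallel to z-axis: frame degenerate")
  structure(list(origin = origin, x_axis = x / xlen, y_axis = y, z_axis = z),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame>\n")
  cat(sprintf("  origin: (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n",
                ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Vertebral rotation angle
#'
#' The axial rotation angle is measured in the vertebra's transverse plane:
#' both the local y-axis and the global reference y-axis are projected onto
#' the plane, and the angle between the projections is reported in degrees.
#' The unsigned angle in [0, 180] is the headline output; the signed variant
#' takes its sign from the orientation of (global projection x local
#' projection) relative to the plane normal.
#'
#' @param frame A \code{local_frame}.
#' @param global_y Global reference axis (default \code{c(0, 1, 0)}, the
#'   anterior direction of the scanner frame).
#' @param normal Unit normal of the transverse plane; defaults to the frame's
#'   z-axis.
#' @param tol Minimum in-plane projection length before the angle is
#'   undefined.
#' @return List with \code{angle} (unsigned degrees) and \code{signed}
#'   (degrees in (-180, 180]).
#' @export
rotation_angle <- function(frame, global_y = c(0, 1, 0), normal = NULL,
                           tol = 1e-9) {
  if (is.null(normal)) normal <- frame$z_axis
  normal <- normal / sqrt(sum(normal^2))
  proj <- function(v) v - sum(v * normal) * normal
  pg <- proj(global_y / sqrt(sum(global_y^2)))
  pl <- proj(frame$y_axis)
  lg <- sqrt(sum(pg^2)); ll <- sqrt(sum(pl^2))
  if (lg < tol || ll < tol)
    stop("axis is (nearly) parallel to the plane normal: angle undefined")
  pg <- pg / lg; pl <- pl / ll
  cosang <- max(-1, min(1, sum(pg * pl)))
  cross <- c(pg[2] * pl[3] - pg[3] * pl[2],
             pg[3] * pl[1] - pg[1] * pl[3],
             pg[1] * pl[2] - pg[2] * pl[1])
  sinang <- sum(cross * normal)
  unsigned <- acos(cosang) * 180 / pi
  signed <- atan2(sinang, cosang) * 180 / pi
  list(angle = unsigned, signed = signed)
}

#' Full single-vertebra measurement pipeline
#'
#' Runs the complete measurement on one vertebral cloud: (optionally) sample,
#' obtain endplate and pedicle structure points (from a trained model or from
#' given label vectors), split the endplates, cluster the pedicles, build the
#' local frame and report the rotation angle. All intermediate artifacts are
#' returned for audit.
#'
#' @param cloud A \code{point_cloud} of the whole vertebra.
#' @param endplate Either an integer 0/1 label vector of length N or a trained
#'   \code{vertrot_model} for the endplate task.
#' @param pedicle As \code{endplate}, for the pedicle task.
#' @param sample_m Optional subset size; when given, the cloud is first
#'   downsampled with entropy-FPS and labels/predictions refer to the subset.
#' @param global_y Global reference axis for the angle.
#' @param seed Seed for K-means (and sampling start policy).
#' @param lambda Entropy weight for the optional sampling step.
#' @return List of class \code{vertebra_measurement}: \code{angle} (unsigned
#'   degrees), \code{signed}, \code{frame}, \code{plane},
#'   \code{endplate_centers}, \code{pedicle_centers}, \code{n_endplate},
#'   \code{n_pedicle}, \code{n_points}.
#' @export
measure_vertebra <- function(cloud, endplate, pedicle, sample_m = NULL,
                             global_y = c(0, 1, 0), seed = 1L, lambda = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.null(sample_m)) {
    res <- entropy_fps(cloud, sample_m, lambda = lambda, start = 1L)
    if (is.numeric(endplate)) endplate <- endplate[res$indices]
    if (is.numeric(pedicle)) pedicle <- pedicle[res$indices]
    cloud <- take_sample(cloud, res)
  }
  get_mask <- function(spec, task) {
    if (inherits(spec, "vertrot_model")) {
      pred <- predict(spec, cloud)
      mask <- pred == 1L
    } else {
      if (length(spec) != nrow(cloud$points))
        stop(task, " labels do not match the cloud size")
      mask <- as.integer(spec) == 1L
    }
    if (!any(mask)) stop("no points predicted for the ", task, " structure")
    mask
  }
  ep_mask <- get_mask(endplate, "endplate")
  pd_mask <- get_mask(pedicle, "pedicle")
  ep_cloud <- point_cloud(cloud$points[ep_mask, , drop = FALSE])
  pd_cloud <- point_cloud(cloud$points[pd_mask, , drop = FALSE])
  split <- split_endplates(ep_cloud, seed = seed)
  pdc <- pedicle_centers(pd_cloud, seed = seed)
  frame <- local_frame(split$centers, pdc)
  plane <- transverse_plane(split$centers)
  ang <- rotation_angle(frame, global_y = global_y, normal = plane$normal)
  structure(list(angle = ang$angle, signed = ang$signed, frame = frame,
                 plane = plane, endplate_centers = split$centers,
                 pedicle_centers = pdc,
                 n_endplate = sum(ep_mask), n_pedicle = sum(pd_mask),
                 n_points = nrow(cloud$points)),
            class = "vertebra_measurement")
}

#' @export
print.vertebra_measurement <- function(x, ...) {
  cat(sprintf("<vertebra_measurement: %.2f deg (signed %.2f)>\n",
              x$angle, x$signed))
  cat(sprintf("  points: %d total, %d endplate, %d pedicle\n",
              x$n_points, x$n_endplate, x$n_pedicle))
  invisible(x)
}

#' Pedicle-centre offset between two measurements
#'
#' Euclidean displacement (mm) of each predicted pedicle centre from a
#' reference (e.g. manually segmented) centre, the landmark-accuracy metric
#' for pedicle recognition.
#'
#' @param pred,ref \code{pedicle_centers} objects sharing the left/right
#'   naming convention.
#' @return Named numeric vector \code{c(left=, right=)} in mm.
#' @export
center_offset <- function(pred, ref) {
  c(left = sqrt(sum((pred$left - ref$left)^2)),
    right = sqrt(sum((pred$right - ref$right)^2)))
}
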