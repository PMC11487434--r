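#' Phantom vertebra configuration
#'
#' Geometry of the synthetic single-vertebra surface phantom, sized after a
#' typical lumbar vertebra: an elliptical-cylinder body wall, two parallel
#' endplate caps, and two posterior pedicle blobs symmetric about the
#' mid-sagittal plane. Surfaces (not volumes) are sampled, mimicking
#' reconstructed surface meshes. The anterior direction is +Y, the
#' cranio-caudal axis +Z, and the pedicles sit posteriorly at -Y.
#'
#' @param body_radius_x,body_radius_y Semi-axes of the elliptical body (mm;
#'   defaults 20 and 15).
#' @param body_height Body height between the endplates (mm; default 25).
#' @param endplate_thickness Vertical extent of the cap point band (mm;
#'   default 0 = flat caps).
#' @param pedicle_offset Lateral/posterior placement of the pedicle centres:
#'   \code{c(lateral, posterior)} in mm (default \code{c(15, 20)}, i.e.
#'   centres at (+-15, -20, 0)).
#' @param pedicle_radius Pedicle blob radius (mm; default 4).
#' @param n_body,n_endplate,n_pedicle Points sampled on the body wall, each
#'   endplate cap, and each pedicle blob (defaults 1200 / 350 / 250).
#' @param density_skew Factor by which the posterior elements are denser than
#'   the body: the body count is divided by it (default 2, emulating the
#'   uneven density of reconstructed vertebral clouds).
#' @param noise_sd Isotropic Gaussian surface noise (mm; default 0). Noise is
#'   applied after labelling, so labels remain exact.
#' @param theta Applied axial rotation about the endplate axis (degrees,
#'   default 0).
#' @param tilt Additional tilt about the global X axis applied after the
#'   axial rotation (degrees, default 0).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class \code{phantom_config}.
#' @export
phantom_config <- function(body_radius_x = 20, body_radius_y = 15,
                           body_height = 25, endplate_thickness = 0,
                           pedicle_offset = c(15, 20), pedicle_radius = 4,
                           n_body = 1200L, n_endplate = 350L,
                           n_pedicle = 250L, density_skew = 2,
                           noise_sd = 0, theta = 0, tilt = 0, seed = 1L) {
  cfg <- list(body_radius_x = body_radius_x, body_radius_y = body_radius_y,
              body_height = body_height,
              endplate_thickness = endplate_thickness,
              pedicle_offset = pedicle_offset,
              pedicle_radius = pedicle_radius,
              n_body = as.integer(n_body), n_endplate = as.integer(n_endplate),
              n_pedicle = as.integer(n_pedicle), density_skew = density_skew,
              noise_sd = noise_sd, theta = theta, tilt = tilt,
              seed = as.integer(seed))
  if (any(c(body_radius_x, body_radius_y, body_height, pedicle_radius) <= 0))
    stop("all phantom dimensions must be positive")
  if (density_skew <= 0) stop("density_skew must be positive")
  if (pedicle_offset[2] - pedicle_radius < body_radius_y * 0.5)
    stop("pedicles overlap the vertebral body at this geometry")
  structure(cfg, class = "phantom_config")
}

# n/2 random points on an elliptical disk plus their antipodes, so the
# empirical centroid is exactly (0, 0)
.symmetric_disk <- function(n, a, b) {
  half <- ceiling(n / 2)
  u <- stats::runif(half)
  phi <- stats::runif(half, 0, 2 * pi)
  x <- a * sqrt(u) * cos(phi)
  y <- b * sqrt(u) * sin(phi)
  cbind(c(x, -x), c(y, -y))
}

# n/2 random points on a sphere surface plus their antipodes about the centre
.symmetric_sphere <- function(n, r) {
  half <- ceiling(n / 2)
  v <- matrix(stats::rnorm(half * 3), half, 3)
  v <- v / sqrt(rowSums(v^2)) * r
  rbind(v, -v)
}

#' Generate a labelled synthetic vertebra
#'
#' Builds the phantom in canonical pose (endplate axis = global Z, anterior =
#' +Y), labels the endplate caps (task A) and pedicle blobs (task B), applies
#' the configured axial rotation and tilt, and finally adds surface noise.
#' Caps and blobs are antipodally symmetrized so their empirical centroids
#' equal the exact landmark positions; the recorded ground-truth angle is the
#' angle implied by the true landmarks, which before noise the measurement
#' pipeline recovers exactly (and, with zero tilt, equals the applied
#' \code{theta}).
#'
#' @param config A \code{\link{phantom_config}}.
#' @return List with \code{endplate_task} and \code{pedicle_task}
#'   (\code{labeled_cloud}s sharing the same points) and \code{truth}, a list
#'   with \code{theta_true} (signed degrees), \code{theta_applied},
#'   \code{endplate_centers}, \code{pedicle_centers} (exact post-transform
#'   landmarks), \code{rotation} (the applied 3 x 3 matrix) and the label
#'   masks.
#' @export
generate_vertebra <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  a <- config$body_radius_x; b <- config$body_radius_y
  h2 <- config$body_height / 2
  nb <- max(8L, as.integer(round(config$n_body / config$density_skew)))
  # body wall: uniform angle x height on the elliptical cylinder surface
  phi <- stats::runif(nb, 0, 2 * pi)
  z <- stats::runif(nb, -h2, h2)
  body <- cbind(a * cos(phi), b * sin(phi), z)
  # endplate caps, antipodally symmetric: centroids exactly (0, 0, +-h2)
  up_xy <- .symmetric_disk(config$n_endplate, a, b)
  lo_xy <- .symmetric_disk(config$n_endplate, a, b)
  thick <- config$endplate_thickness
  up_dz <- if (thick > 0) stats::runif(nrow(up_xy) / 2, 0, thick) else NULL
  # mirrored z-offsets keep the cap centroid z exact even with thickness
  up_z <- h2 - if (thick > 0) c(up_dz, up_dz) else 0
  lo_dz <- if (thick > 0) stats::runif(nrow(lo_xy) / 2, 0, thick) else NULL
  lo_z <- -h2 + if (thick > 0) c(lo_dz, lo_dz) else 0
  upper <- cbind(up_xy, up_z)
  lower <- cbind(lo_xy, lo_z)
  up_center <- c(0, 0, mean(up_z))
  lo_center <- c(0, 0, mean(lo_z))
  # pedicle blobs: left generated, right mirrored across the mid-sagittal
  # plane, so the combined centroid has x = 0 exactly
  pc_left <- c(-config$pedicle_offset[1], -config$pedicle_offset[2], 0)
  left <- sweep(.symmetric_sphere(config$n_pedicle, config$pedicle_radius),
                2L, pc_left, "+")
  right <- left
  right[, 1] <- -right[, 1]
  pc_right <- pc_left; pc_right[1] <- -pc_right[1]
  pts <- rbind(body, upper, lower, left, right)
  ep_labels <- c(rep(0L, nrow(body)), rep(1L, nrow(upper) + nrow(lower)),
                 rep(0L, nrow(left) + nrow(right)))
  pd_labels <- c(rep(0L, nrow(body) + nrow(upper) + nrow(lower)),
                 rep(1L, nrow(left) + nrow(right)))
  R <- rotation_matrix(c(0, 0, 1), config$theta)
  if (config$tilt != 0)
    R <- rotation_matrix(c(1, 0, 0), config$tilt) %*% R
  pts <- pts %*% t(R)
  landmarks <- list(upper = as.numeric(R %*% up_center),
                    lower = as.numeric(R %*% lo_center),
                    left = as.numeric(R %*% pc_left),
                    right = as.numeric(R %*% pc_right))
  # ground-truth angle: run the frame construction on the exact landmarks
  frame <- local_frame(list(upper = landmarks$upper, lower = landmarks$lower),
                       list(left = landmarks$left, right = landmarks$right))
  ang <- rotation_angle(frame)
  if (config$noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = config$noise_sd),
                        nrow(pts), 3)
  cloud <- point_cloud(pts, name = sprintf("phantom_seed%d", config$seed))
  list(endplate_task = labeled_cloud(cloud, ep_labels),
       pedicle_task = labeled_cloud(cloud, pd_labels),
       truth = list(theta_true = ang$signed,
                    theta_applied = config$theta,
                    endplate_centers = landmarks[c("upper", "lower")],
                    pedicle_centers = landmarks[c("left", "right")],
                    rotation = R,
                    endplate_mask = ep_labels,
                    pedicle_mask = pd_labels,
                    config = config))
}

#' Generate a phantom dataset with a manifest
#'
#' @param n Number of phantoms.
#' @param theta_range Axial angles drawn uniformly from this range (degrees;
#'   default \code{c(0, 25)}).
#' @param template A \code{\link{phantom_config}} supplying all other
#'   parameters; each phantom gets its own derived seed and drawn theta.
#' @param seed Base seed for the dataset.
#' @return List with \code{phantoms} (list of \code{\link{generate_vertebra}}
#'   outputs) and \code{manifest}, a data frame with \code{id},
#'   \code{theta_applied}, \code{theta_true}, \code{noise_sd}, \code{seed}.
#' @export
generate_dataset <- function(n, theta_range = c(0, 25),
                             template = phantom_config(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  thetas <- stats::runif(n, theta_range[1], theta_range[2])
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- template
    cfg$theta <- thetas[i]
    cfg$seed <- seeds[i]
    phantoms[[i]] <- generate_vertebra(cfg)
    rows[[i]] <- data.frame(id = i, theta_applied = thetas[i],
                            theta_true = phantoms[[i]]$truth$theta_true,
                            noise_sd = cfg$noise_sd, seed = seeds[i])
  }
  list(phantoms = phantoms, manifest = do.call(rbind, rows))
}
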