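make_disk_pair <- function(n = 120, z = 10, seed = 1) {
  set.seed(seed)
  one <- function(zc) {
    u <- runif(n); phi <- runif(n, 0, 2 * pi)
    cbind(8 * sqrt(u) * cos(phi), 8 * sqrt(u) * sin(phi), zc)
  }
  point_cloud(rbind(one(z), one(-z)))
}

test_that("endplate splitting recovers two parallel disks", {
  cl <- make_disk_pair()
  sp <- split_endplates(cl, seed = 2)
  # cluster centres are the sampled-disk centroids ...
  expect_equal(sp$centers$upper, colMeans(cl$points[1:120, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sp$centers$lower, colMeans(cl$points[121:240, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # ... which sit near the analytic disk centres, within sampling error
  expect_lt(sqrt(sum((sp$centers$upper - c(0, 0, 10))^2)), 8 / sqrt(120) * 3)
  expect_equal(sp$centers$upper[3], 10, tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(sp$centers$lower[3], -10, tolerance = 0.1, ignore_attr = TRUE)
  expect_identical(split_endplates(cl, seed = 2)$centers, sp$centers)

  two <- point_cloud(rbind(c(0, 0, 3), c(0, 0, -3)))
  sp2 <- split_endplates(two)
  expect_equal(sp2$centers$upper, c(0, 0, 3), ignore_attr = TRUE)
  expect_equal(sp2$centers$lower, c(0, 0, -3), ignore_attr = TRUE)
})

test_that("pedicle clustering matches blob means and the exact 2-partition", {
  set.seed(3)
  blob <- function(c0) sweep(matrix(rnorm(150, sd = 0.8), 50, 3), 2, c0, "+")
  cl <- point_cloud(rbind(blob(c(-15, -20, 0)), blob(c(15, -20, 0))))
  pc <- pedicle_centers(cl, seed = 4)
  expect_lt(sqrt(sum((pc$left - colMeans(cl$points[1:50, ]))^2)), 0.5)
  expect_lt(sqrt(sum((pc$right - colMeans(cl$points[51:100, ]))^2)), 0.5)
  expect_lt(pc$left[1], pc$right[1])

  two <- pedicle_centers(point_cloud(rbind(c(-1, 2, 3), c(5, 0, 0))))
  expect_equal(two$left, c(-1, 2, 3), ignore_attr = TRUE)
  expect_equal(two$right, c(5, 0, 0), ignore_attr = TRUE)

  # K-means within-cluster SS equals the brute-force best 2-partition
  set.seed(5)
  toy <- matrix(rnorm(24, sd = 3), 8, 3)
  km <- vertrot:::.seeded_kmeans(toy, 2L, seed = 6, nstart = 10L)
  best <- Inf
  for (mask in 1:(2^7)) {  # partitions with point 1 fixed in group A
    g <- c(0L, as.integer(intToBits(mask))[1:7])
    if (all(g == 0L)) next
    wss <- sum(sapply(0:1, function(k) {
      pts <- toy[g == k, , drop = FALSE]
      if (nrow(pts) == 0) 0 else sum(sweep(pts, 2, colMeans(pts))^2)
    }))
    best <- min(best, wss)
  }
  expect_equal(km$tot.withinss, best, tolerance = 1e-8)

  expect_error(pedicle_centers(point_cloud(rbind(c(1, 1, 1), c(1, 1, 1)))),
               "degenerate")
})

test_that("centroid, transverse plane and local frame follow the construction", {
  ep <- list(upper = c(0, 0, 1), lower = c(0, 0, -1))
  expect_equal(vertebral_centroid(ep), c(0, 0, 0))
  expect_equal(vertebral_centroid(list(upper = c(2, 4, 6),
                                       lower = c(0, 0, 0))), c(1, 2, 3))
  expect_equal(vertebral_centroid(list(upper = ep$lower, lower = ep$upper)),
               vertebral_centroid(ep))

  pl <- transverse_plane(ep)
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(transverse_plane(list(upper = 10 * c(1, 1, 1),
                                     lower = c(0, 0, 0)))$normal,
               c(1, 1, 1) / sqrt(3))
  expect_error(transverse_plane(list(upper = c(1, 1, 1),
                                     lower = c(1, 1, 1))), "coincide")

  pd <- list(left = c(-15, -20, 0), right = c(15, -20, 0))
  fr <- local_frame(ep, pd)
  expect_equal(fr$x_axis, c(1, 0, 0))
  expect_equal(fr$y_axis, c(0, 1, 0))
  expect_equal(fr$z_axis, c(0, 0, 1))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    expect_equal(sqrt(sum(fr[[ax]]^2)), 1, tolerance = 1e-9)

  # rotating all landmarks by R rotates each axis by R
  R <- rotation_matrix(c(1, 2, -1), 20)
  rot <- function(v) as.numeric(R %*% v)
  fr2 <- local_frame(list(upper = rot(ep$upper), lower = rot(ep$lower)),
                     list(left = rot(pd$left), right = rot(pd$right)))
  expect_equal(fr2$x_axis, rot(fr$x_axis), tolerance = 1e-12)
  expect_equal(fr2$y_axis, rot(fr$y_axis), tolerance = 1e-12)
  expect_equal(fr2$z_axis, rot(fr$z_axis), tolerance = 1e-12)

  # pedicle midpoint on the endplate axis: y is parallel to z
  expect_error(local_frame(ep, list(left = c(0, 0, -4), right = c(0, 0, 2))),
               "parallel")
  expect_error(local_frame(ep, list(left = c(0, 0, -1), right = c(0, 0, 1))),
               "coincides")
})

test_that("the in-plane angle recovers explicit rotations with sign", {
  ep <- list(upper = c(0, 0, 1), lower = c(0, 0, -1))
  pd <- list(left = c(-15, -20, 0), right = c(15, -20, 0))
  fr <- local_frame(ep, pd)
  expect_equal(rotation_angle(fr)$angle, 0)

  for (deg in c(7, -7)) {
    R <- rotation_matrix(c(0, 0, 1), deg)
    rot <- function(v) as.numeric(R %*% v)
    fr2 <- local_frame(list(upper = rot(ep$upper), lower = rot(ep$lower)),
                       list(left = rot(pd$left), right = rot(pd$right)))
    a <- rotation_angle(fr2)
    expect_equal(a$angle, abs(deg), tolerance = 1e-6)
    expect_equal(a$signed, deg, tolerance = 1e-6)
  }
  # reference axis parallel to the normal leaves the angle undefined
  expect_error(rotation_angle(fr, global_y = c(0, 0, 1)), "undefined")
})

test_that("measurement is invariant to translation and scale, equivariant to axial rotation", {
  ph <- generate_vertebra(phantom_config(theta = 12, seed = 8))
  cl <- ph$endplate_task$cloud
  ep <- ph$endplate_task$labels
  pd <- ph$pedicle_task$labels
  base <- measure_vertebra(cl, ep, pd)
  expect_equal(base$angle, 12, tolerance = 1e-6)

  shifted <- transform_cloud(cl, translation = c(100, -42, 7))
  expect_equal(measure_vertebra(shifted, ep, pd)$angle, base$angle,
               tolerance = 1e-6)
  scaled <- point_cloud(cl$points * 3.7)
  expect_equal(measure_vertebra(scaled, ep, pd)$angle, base$angle,
               tolerance = 1e-6)

  # rotating about the endplate axis by alpha shifts the signed angle by alpha
  rotated <- transform_cloud(cl, rotation_matrix(c(0, 0, 1), 5))
  expect_equal(measure_vertebra(rotated, ep, pd)$signed, base$signed + 5,
               tolerance = 1e-6)

  # swapping upper/lower labels flips z but not the unsigned angle
  flipped <- transform_cloud(cl, rotation_matrix(c(0, 1, 0), 180))
  expect_equal(measure_vertebra(flipped, ep, pd)$angle, base$angle,
               tolerance = 1e-6)
})

test_that("noiseless phantoms are recovered exactly; noisy ones closely", {
  set.seed(9)
  thetas <- runif(10, 0, 25)
  errs_clean <- errs_noisy <- numeric(0)
  for (i in seq_along(thetas)) {
    for (noise in c(0, 0.5)) {
      ph <- generate_vertebra(phantom_config(theta = thetas[i],
                                             noise_sd = noise,
                                             seed = 1000 + i))
      mv <- measure_vertebra(ph$endplate_task$cloud, ph$endplate_task$labels,
                             ph$pedicle_task$labels)
      err <- abs(mv$angle - thetas[i])
      if (noise == 0) errs_clean <- c(errs_clean, err)
      else errs_noisy <- c(errs_noisy, err)
    }
  }
  expect_lt(max(errs_clean), 1e-6)
  expect_lt(mean(errs_noisy), 0.5)
})

test_that("pedicle centre offsets are per-side Euclidean distances", {
  a <- list(left = c(0, 0, 0), right = c(10, 0, 0))
  expect_equal(center_offset(a, a), c(left = 0, right = 0))
  b <- list(left = c(3, 4, 0), right = c(10, 0, 0))
  expect_equal(center_offset(b, a), c(left = 5, right = 0))
  set.seed(10)
  for (i in 1:5) {
    p <- list(left = rnorm(3), right = rnorm(3))
    r <- list(left = rnorm(3), right = rnorm(3))
    expect_equal(center_offset(p, r),
                 c(left = sqrt(sum((p$left - r$left)^2)),
                   right = sqrt(sum((p$right - r$right)^2))))
  }
})
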