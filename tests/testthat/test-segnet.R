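test_that("kNN grouping includes self and matches a brute-force sort", {
  cl <- random_cloud(12, seed = 1)
  g1 <- knn_group(cl, 1)
  expect_equal(as.integer(g1), 1:12)  # each point's nearest is itself

  line <- point_cloud(cbind(c(0, 1, 2, 3), 0, 0))
  g2 <- knn_group(line, 2)
  expect_equal(g2[1, ], c(1L, 2L))
  expect_equal(g2[4, ], c(4L, 3L))
  # interior point 2: ties between 1 and 3 at distance 1 -> lowest index
  expect_equal(g2[2, ], c(2L, 1L))

  g <- knn_group(cl, 5)
  d <- pairwise_distances(cl)
  for (i in 1:12)
    expect_equal(g[i, ], order(d[i, ])[1:5])

  # for k = N membership is symmetric: everyone is in everyone's patch
  gN <- knn_group(cl, 12)
  expect_true(all(apply(gN, 1L, function(r) setequal(r, 1:12))))
  expect_error(knn_group(cl, 13), "exceed")
})

test_that("self-attention rows are softmax-normalized and match hand arithmetic", {
  # singleton: attention weight is 1 and the output is the value vector
  f1 <- matrix(c(2, -1), 1, 2)
  sa1 <- self_attention(f1, diag(2), diag(2), diag(2))
  expect_equal(as.numeric(sa1$attention), 1)
  expect_equal(sa1$output, f1)

  # 2-point field with identity projections: closed-form 2x2 softmax
  f <- rbind(c(1, 0), c(0, 2))
  sa <- self_attention(f, diag(2), diag(2), diag(2))  # d_a = 2 scaling
  S <- (f %*% t(f)) / 2
  A <- exp(S) / rowSums(exp(S))
  expect_equal(sa$attention, A, ignore_attr = TRUE)
  expect_equal(sa$output, A %*% f)

  set.seed(3)
  fr <- matrix(rnorm(40), 10, 4)
  Wq <- matrix(rnorm(8), 4, 2); Wk <- matrix(rnorm(8), 4, 2)
  Wv <- matrix(rnorm(16), 4, 4)
  for (nb in list(NULL, knn_group(point_cloud(cbind(fr[, 1:3])), 4))) {
    sa <- self_attention(fr, Wq, Wk, Wv, neighbors = nb)
    expect_equal(rowSums(sa$attention), rep(1, 10), tolerance = 1e-6)
  }
  expect_error(self_attention(fr, matrix(0, 3, 2), Wk, Wv), "width")
})

test_that("position encoding concatenates a coordinate MLP with the features", {
  set.seed(4)
  coords <- matrix(rnorm(6), 2, 3)
  f <- matrix(rnorm(4), 2, 2)
  d <- 3L
  w <- list(phi_w1 = matrix(rnorm(9), 3, d), phi_b1 = matrix(rnorm(d), 1),
            phi_w2 = matrix(rnorm(9), d, d), phi_b2 = matrix(rnorm(d), 1),
            psi_w = matrix(rnorm((2 + d) * 4), 2 + d, 4),
            psi_b = matrix(0, 1, 4))
  got <- position_encode(coords, f, w)
  delta <- pmax(coords %*% w$phi_w1 + rep(1, 2) %*% w$phi_b1, 0) %*%
    w$phi_w2 + rep(1, 2) %*% w$phi_b2
  expect_equal(got, cbind(f, delta) %*% w$psi_w)

  # zero position branch: output depends only on the features
  w0 <- w
  w0$phi_w1[] <- 0; w0$phi_b1[] <- 0; w0$phi_w2[] <- 0; w0$phi_b2[] <- 0
  a <- position_encode(coords, f, w0)
  b <- position_encode(coords + 10, f, w0)
  expect_equal(a, b)
  # but a live position branch is translation sensitive
  expect_false(isTRUE(all.equal(position_encode(coords, f, w),
                                position_encode(coords + 10, f, w))))
})

test_that("relation attention is residual: zeroed LBR is the identity", {
  set.seed(5)
  f <- matrix(rnorm(24), 6, 4)
  d <- 4L
  w <- list(Wq = matrix(rnorm(d * 2), d, 2), Wk = matrix(rnorm(d * 2), d, 2),
            Wv = matrix(rnorm(d * d), d, d),
            lbr_w = matrix(0, d, d), lbr_b = matrix(0, 1, d),
            gamma = matrix(0, 1, d), beta = matrix(0, 1, d))
  expect_equal(relation_attention(f, w), f)

  # collapsed attention (value projection = identity on a 1-point field)
  # makes F_SA = F_in, so the deviation F_RA is exactly zero
  sa <- self_attention(f[1, , drop = FALSE], w$Wq, w$Wk, diag(d))
  expect_equal(f[1, , drop = FALSE] - sa$output,
               matrix(0, 1, d))
})

test_that("relation attention equals the staged composition computed by hand", {
  set.seed(6)
  f <- matrix(rnorm(12), 3, 4)
  d <- 4L
  w <- list(Wq = matrix(rnorm(d * 2), d, 2), Wk = matrix(rnorm(d * 2), d, 2),
            Wv = matrix(rnorm(d * d), d, d),
            lbr_w = matrix(rnorm(d * d), d, d),
            lbr_b = matrix(rnorm(d), 1, d),
            gamma = matrix(runif(d), 1, d), beta = matrix(rnorm(d), 1, d))
  got <- relation_attention(f, w)
  # independent staged recomputation: attention -> subtraction -> LBR -> add
  S <- (f %*% w$Wq) %*% t(f %*% w$Wk) / 2
  A <- exp(S) / rowSums(exp(S))
  f_sa <- A %*% (f %*% w$Wv)
  f_ra <- f - f_sa
  lin <- f_ra %*% w$lbr_w + rep(1, 3) %*% w$lbr_b
  mu <- colMeans(lin)
  v <- colMeans(sweep(lin, 2, mu)^2)
  xhat <- sweep(sweep(lin, 2, mu), 2, sqrt(v + 1e-5), "/")
  lbr <- pmax(sweep(sweep(xhat, 2, as.numeric(w$gamma), "*"), 2,
                    as.numeric(w$beta), "+"), 0)
  expect_equal(got, lbr + f, tolerance = 1e-12)
})

test_that("the encoder-decoder preserves point count and is deterministic", {
  cfg <- network_config(input_points = 96, base_width = 8,
                        stage_widths = c(8, 12, 16, 20),
                        downsample_ratio = 2, k_neighbors = 4, seed = 11)
  params <- vertrot:::.init_params(cfg)
  cl <- random_cloud(96, seed = 12)
  s1 <- encode_decode(cl, params, cfg)
  expect_equal(dim(s1), c(96L, 2L))
  s2 <- encode_decode(cl, params, cfg)
  expect_identical(s1, s2)
  # same seed, fresh params: identical initialization
  expect_identical(vertrot:::.init_params(cfg), params)
  expect_error(encode_decode(random_cloud(10), params, cfg), "smaller")
})

test_that("permuting the input point order permutes the scores identically", {
  cfg <- network_config(input_points = 96, base_width = 8,
                        stage_widths = c(8, 12, 16, 20),
                        downsample_ratio = 2, k_neighbors = 4, seed = 11)
  params <- vertrot:::.init_params(cfg)
  cl <- random_cloud(96, seed = 13)
  set.seed(99)
  perm <- sample(96)
  s <- encode_decode(cl, params, cfg)
  sp <- encode_decode(point_cloud(cl$points[perm, ]), params, cfg)
  expect_equal(sp, s[perm, ], tolerance = 1e-9)
})

test_that("network gradients agree with numerical differentiation", {
  cfg <- network_config(input_points = 32, base_width = 6,
                        stage_widths = c(6, 8, 10, 12),
                        downsample_ratio = 2, k_neighbors = 3, seed = 21)
  set.seed(22)
  pts <- matrix(rnorm(32 * 3), 32, 3)
  pts <- pts / sqrt(max(rowSums(pts^2)))
  labels <- as.integer(pts[, 3] > 0)
  params <- vertrot:::.init_params(cfg)
  lg <- vertrot:::.loss_and_grads(params, cfg, pts, labels)
  eps <- 1e-5
  for (nm in c("emb_w1", "enc1_Wk", "enc2_lbr_w", "enc3_psi_w", "enc4_Wv",
               "dec3_w", "dec1_b", "head_w2")) {
    i <- 2L
    up <- params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (vertrot:::.loss_and_grads(up, cfg, pts, labels)$loss -
            vertrot:::.loss_and_grads(dn, cfg, pts, labels)$loss) / (2 * eps)
    expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("cross-entropy matches hand-computed softmax sums", {
  expect_equal(cross_entropy_loss(matrix(0, 1, 2), 0L), log(2),
               tolerance = 1e-9)
  # confident correct predictions drive the loss monotonically to zero
  losses <- vapply(c(1, 2, 5, 10), function(a)
    cross_entropy_loss(cbind(a, 0), 0L), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[4], 1e-4)

  z <- rbind(c(1, 0, -1), c(0, 2, 0), c(-1, -1, 3))
  y <- c(0L, 1L, 2L)
  hand <- -mean(sapply(1:3, function(i)
    z[i, y[i] + 1] - log(sum(exp(z[i, ])))))
  expect_equal(cross_entropy_loss(z, y), hand, tolerance = 1e-12)
  expect_error(cross_entropy_loss(z, c(0L, 3L, 1L)), "out of range")
})

test_that("mIoU matches the hand example and a confusion-matrix oracle", {
  expect_equal(miou(c(0, 1, 1), c(0, 1, 1)), 100)
  expect_equal(miou(c(1, 0), c(0, 1)), 0)
  truth <- c(0, 0, 0, 1, 1, 1, 1, 1)
  pred <- c(0, 0, 1, 1, 1, 1, 1, 0)
  expect_equal(miou(pred, truth), (4 / 6 + 2 / 4) / 2 * 100,
               tolerance = 1e-9)

  oracle <- function(pred, truth, K) {
    cm <- table(factor(pred, 0:(K - 1)), factor(truth, 0:(K - 1)))
    ious <- sapply(1:K, function(k) {
      tp <- cm[k, k]; un <- sum(cm[k, ]) + sum(cm[, k]) - tp
      if (un == 0) 1 else tp / un
    })
    mean(ious) * 100
  }
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    K <- sample(2:4, 1)
    p <- sample(0:(K - 1), n, replace = TRUE)
    t <- sample(0:(K - 1), n, replace = TRUE)
    expect_equal(miou(p, t, K), oracle(p, t, K), tolerance = 1e-12)
  }
})
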