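#' Full Euclidean distance matrix of a cloud
#'
#' @param cloud A \code{point_cloud}.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
pairwise_distances <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  d <- as.matrix(stats::dist(cloud$points, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Shannon entropy of a distance distribution
#'
#' Discretizes a multiset of pairwise distances into a \code{bins}-bin
#' histogram over its range, converts counts to a frequency distribution P and
#' returns H = -sum(P * log(P + eps)) (natural log). High entropy indicates a
#' spread of inter-point distances (structurally rich neighbourhoods); a
#' degenerate multiset occupying one bin yields H close to 0.
#'
#' @param distances Numeric vector of distances (diagonal self-distances
#'   already removed by the caller).
#' @param bins Number of histogram bins (default 32).
#' @param eps Small stabilizer inside the log (default 1e-12).
#' @return Nonnegative (up to \code{-log(1+eps)}) scalar entropy.
#' @export
distance_entropy <- function(distances, bins = 32L, eps = 1e-12) {
  distances <- as.numeric(distances)
  if (length(distances) == 0L) stop("empty distance set")
  if (bins < 1L) stop("bins must be >= 1")
  if (any(!is.finite(distances))) stop("distances must be finite")
  rng <- range(distances)
  if (diff(rng) <= 1e-12 * max(abs(rng), 1)) {
    # (numerically) identical distances: all mass in a single bin
    p <- 1
  } else {
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    counts <- .bincount(distances, edges)
    p <- counts / sum(counts)
  }
  -sum(p * log(p + eps))
}

# histogram counts with right-closed last bin (findInterval semantics)
.bincount <- function(x, edges) {
  b <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = b)
}

#' Farthest point sampling
#'
#' Greedy max-min subset selection: starting from \code{start}, each
#' successive point maximizes its minimum distance to the already-selected
#' set. Ties are broken by lowest index, so the result is fully deterministic
#' given the start point.
#'
#' @param cloud A \code{point_cloud}.
#' @param m Target subset size, 1 <= m <= N.
#' @param start Index of the first selected point (default 1).
#' @return List of class \code{sampling_result}: \code{indices} (length m,
#'   1-based) and \code{scores} (the max-min distance achieved at each
#'   selection; \code{Inf} for the start point).
#' @export
farthest_point_sampling <- function(cloud, m, start = 1L) {
  .greedy_sampling(cloud, m, start, lambda = 0)
}

#' Entropy-augmented farthest point sampling
#'
#' Farthest point sampling biased toward structurally informative regions:
#' each candidate's greedy score is its max-min distance multiplied by
#' \code{1 + lambda * Hhat}, where \code{Hhat} is the candidate's local
#' distance-distribution entropy (entropy of its \code{k_local}
#' nearest-neighbour distances over cloud-wide shared histogram edges,
#' min-max rescaled to [0, 1] across the cloud; see
#' \code{\link{local_entropy}}).
#' With \code{lambda = 0} the score reduces to plain max-min distance and the
#' selection is identical to \code{\link{farthest_point_sampling}}.
#'
#' @param cloud A \code{point_cloud}.
#' @param m Target subset size.
#' @param k_local Neighbourhood size for the per-point entropy (default 16).
#' @param bins,eps Histogram parameters passed to
#'   \code{\link{distance_entropy}}.
#' @param lambda Nonnegative entropy weight (default 1).
#' @param start Index of the first selected point.
#' @return A \code{sampling_result} (see
#'   \code{\link{farthest_point_sampling}}); \code{scores} are the greedy
#'   scores at selection time.
#' @export
entropy_fps <- function(cloud, m, k_local = 16L, bins = 32L, eps = 1e-12,
                        lambda = 1, start = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda > 0 && k_local >= n)
    stop("k_local must be smaller than the number of points")
  ent <- if (lambda > 0) local_entropy(cloud, k_local, bins, eps) else NULL
  .greedy_sampling(cloud, m, start, lambda = lambda, entropy = ent)
}

#' Per-point local distance-distribution entropy
#'
#' For each point, the entropy of its \code{k_local} nearest-neighbour
#' distances (self excluded), histogrammed over bin edges shared by the whole
#' cloud (spanning the cloud-wide range of neighbour distances) and min-max
#' rescaled to [0, 1] over the cloud. The shared edges make the entropy
#' density-sensitive: a dense neighbourhood concentrates its distances in few
#' bins (low entropy) while a sparse one spreads them (high entropy), which
#' is what lets \code{\link{entropy_fps}} push samples into sparsely covered
#' regions. Computed in chunks so large clouds never materialize a full
#' N x N matrix.
#'
#' @inheritParams entropy_fps
#' @return Numeric vector of length N in [0, 1] (all zeros when the raw
#'   entropies are constant).
#' @export
local_entropy <- function(cloud, k_local = 16L, bins = 32L, eps = 1e-12) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  n <- nrow(p)
  if (k_local >= n) stop("k_local must be smaller than the number of points")
  sq <- rowSums(p^2)
  knnd <- matrix(0, n, k_local)
  chunk <- 1024L
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * p[rows, , drop = FALSE] %*% t(p)
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      di <- sqrt(d2[j, -rows[j]])
      knnd[rows[j], ] <- sort(di, partial = k_local)[seq_len(k_local)]
    }
  }
  rng <- range(knnd)
  h <- if (diff(rng) <= 1e-12 * max(abs(rng), 1)) {
    numeric(n)
  } else {
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    apply(knnd, 1L, function(d) {
      pb <- .bincount(d, edges) / k_local
      -sum(pb * log(pb + eps))
    })
  }
  rng_h <- range(h)
  if (rng_h[2] > rng_h[1]) (h - rng_h[1]) / (rng_h[2] - rng_h[1])
  else numeric(n)
}

# shared greedy max-min loop; lambda = 0 is plain FPS
.greedy_sampling <- function(cloud, m, start, lambda = 0, entropy = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  n <- nrow(p)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m > n) stop(sprintf("cannot sample %d points from a %d-point cloud", m, n))
  start <- as.integer(start)
  if (start < 1L || start > n) stop("start index out of range")
  idx <- integer(m)
  score <- numeric(m)
  idx[1] <- start
  score[1] <- Inf
  # running min distance to the selected set
  dmin <- sqrt(pmax(0, rowSums(sweep(p, 2L, p[start, ])^2)))
  if (m > 1L) {
    for (j in 2:m) {
      s <- if (lambda > 0) dmin * (1 + lambda * entropy) else dmin
      s[idx[seq_len(j - 1L)]] <- -Inf
      best <- which.max(s)  # which.max takes the first (lowest-index) maximum
      idx[j] <- best
      score[j] <- s[best]
      dnew <- sqrt(pmax(0, rowSums(sweep(p, 2L, p[best, ])^2)))
      dmin <- pmin(dmin, dnew)
    }
  }
  structure(list(indices = idx, scores = score), class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf("<sampling_result: %d indices>\n", length(x$indices)))
  invisible(x)
}

#' Extract the sampled sub-cloud
#'
#' @param cloud A \code{point_cloud} or \code{labeled_cloud}.
#' @param result A \code{sampling_result} for that cloud.
#' @return The subset as the same class as \code{cloud}; labels follow their
#'   points.
#' @export
take_sample <- function(cloud, result) {
  stopifnot(inherits(result, "sampling_result"))
  if (inherits(cloud, "labeled_cloud")) {
    labeled_cloud(point_cloud(cloud$cloud$points[result$indices, , drop = FALSE],
                              name = cloud$cloud$name),
                  cloud$labels[result$indices])
  } else {
    stopifnot(inherits(cloud, "point_cloud"))
    point_cloud(cloud$points[result$indices, , drop = FALSE], name = cloud$name)
  }
}

#' Resample a labelled cloud to a fixed size, with dataset expansion
#'
#' Networks require a fixed input size; vertebral models arrive with varying
#' point counts. Each draw is an (entropy-)FPS subset of exactly \code{m}
#' points carrying its points' original labels. Multiple draws from different
#' start points expand the training dataset.
#'
#' @param labeled A \code{labeled_cloud} with N >= m points.
#' @param m Target size (default 3072).
#' @param draws Number of subsets to draw (default 2).
#' @param seed Integer seed; start indices for the draws are derived from it.
#' @param method \code{"entropy-fps"} (default) or \code{"fps"}.
#' @param lambda,k_local,bins,eps Passed to \code{\link{entropy_fps}} when
#'   \code{method = "entropy-fps"}.
#' @return List of \code{draws} \code{labeled_cloud}s of exactly \code{m}
#'   points each.
#' @export
resample_to_size <- function(labeled, m = 3072L, draws = 2L, seed = 1L,
                             method = c("entropy-fps", "fps"), lambda = 1,
                             k_local = 16L, bins = 32L, eps = 1e-12) {
  stopifnot(inherits(labeled, "labeled_cloud"))
  method <- match.arg(method)
  n <- n_points(labeled)
  if (n < m)
    stop(sprintf("cloud has %d points; cannot resample up to %d (no upsampling)",
                 n, m))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  start_idx <- sample.int(n, draws, replace = FALSE)
  lapply(start_idx, function(s) {
    res <- if (method == "fps")
      farthest_point_sampling(labeled$cloud, m, start = s)
    else
      entropy_fps(labeled$cloud, m, k_local = k_local, bins = bins, eps = eps,
                  lambda = lambda, start = s)
    take_sample(labeled, res)
  })
}

# save/restore .Random.seed so library code does not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
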