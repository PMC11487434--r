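#' k-nearest-neighbour grouping
#'
#' Divides a cloud into overlapping local patches: for every point, the
#' indices of its \code{k} nearest neighbours by Euclidean distance (the
#' point itself included, distance 0). Ties are broken by lowest index.
#'
#' @param cloud A \code{point_cloud} (or bare N x 3 matrix).
#' @param k Patch size, 1 <= k <= N.
#' @return Integer N x k matrix; row i lists the patch of point i, nearest
#'   first.
#' @export
knn_group <- function(cloud, k) {
  p <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (k > nrow(p)) stop("k cannot exceed the number of points")
  .knn_idx(p, p, k)
}

# k nearest rows of `source` for each row of `query`; ties by lowest index
.knn_idx <- function(query, source, k) {
  d2 <- outer(rowSums(query^2), rowSums(source^2), "+") -
    2 * query %*% t(source)
  res <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

# canonical FPS start: the point nearest the centroid, ties broken
# lexicographically on coordinates so the choice is order-independent
.canonical_start <- function(p) {
  d2 <- rowSums(sweep(p, 2L, colMeans(p))^2)
  cand <- which(d2 == min(d2))
  if (length(cand) > 1L)
    cand <- cand[order(p[cand, 1], p[cand, 2], p[cand, 3])]
  cand[1]
}

.fps_idx <- function(p, m, start) {
  res <- farthest_point_sampling(point_cloud(p), m, start = start)
  res$indices
}

#' Attention configuration
#'
#' @param d_model Feature width of the attention block.
#' @param d_a Query/key width (default \code{d_model / 4}).
#' @param k_neighbors Local patch size over which attention is computed
#'   (default 16).
#' @param scale \code{"da"} divides attention scores by \code{d_a} as the
#'   method defines; \code{"sqrt_da"} selects the conventional
#'   \code{sqrt(d_a)} scaling instead.
#' @return Validated list of class \code{attention_config}.
#' @export
attention_config <- function(d_model, d_a = max(1L, d_model %/% 4L),
                             k_neighbors = 16L, scale = c("da", "sqrt_da")) {
  scale <- match.arg(scale)
  if (d_a > d_model) stop("d_a must not exceed d_model")
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  structure(list(d_model = as.integer(d_model), d_a = as.integer(d_a),
                 k_neighbors = as.integer(k_neighbors), scale = scale),
            class = "attention_config")
}

.att_scale <- function(d_a, scale) if (scale == "sqrt_da") sqrt(d_a) else d_a

#' Local self-attention over a feature field
#'
#' Scaled dot-product attention Q K' / d_a followed by a row softmax applied
#' to V, restricted to kNN patches (or global when \code{neighbors} covers
#' all points). Every attention row is softmax-normalized and sums to 1.
#'
#' @param f_in M x d feature matrix.
#' @param Wq,Wk M d x d_a query/key projections; \code{Wv} d x d value
#'   projection.
#' @param Wv Value projection matrix.
#' @param neighbors Optional M x k integer patch matrix
#'   (\code{\link{knn_group}}); default every point attends to every point.
#' @param scale \code{"da"} (default) or \code{"sqrt_da"}.
#' @return List with \code{output} (M x d) and \code{attention} (M x k
#'   row-stochastic weights).
#' @export
self_attention <- function(f_in, Wq, Wk, Wv, neighbors = NULL,
                           scale = c("da", "sqrt_da")) {
  scale <- match.arg(scale)
  f_in <- as.matrix(f_in)
  if (nrow(Wq) != ncol(f_in) || nrow(Wk) != ncol(f_in) ||
      nrow(Wv) != ncol(f_in)) stop("projection width does not match features")
  if (ncol(Wq) != ncol(Wk)) stop("Q and K widths differ")
  m <- nrow(f_in)
  if (is.null(neighbors))
    neighbors <- matrix(rep(seq_len(m), each = m), m, m, byrow = FALSE)
  tape <- ad_tape()
  nd <- ad_local_attention(tape,
                           ad_const(tape, f_in %*% Wq),
                           ad_const(tape, f_in %*% Wk),
                           ad_const(tape, f_in %*% Wv),
                           neighbors, .att_scale(ncol(Wq), scale))
  list(output = nd$value, attention = nd$attention)
}

#' Positional encoding of a feature field
#'
#' Raw coordinates are passed through a two-layer MLP with one ReLU to give a
#' positional code, which is concatenated with the input features and mapped
#' by a linear layer to the block width.
#'
#' @param coords M x 3 coordinates.
#' @param f M x df raw features.
#' @param w Weight list: \code{phi_w1} (3 x d), \code{phi_b1},
#'   \code{phi_w2} (d x d), \code{phi_b2}, \code{psi_w} ((df + d) x d_out),
#'   \code{psi_b}.
#' @return M x d_out feature matrix.
#' @export
position_encode <- function(coords, f, w) {
  coords <- as.matrix(coords); f <- as.matrix(f)
  h <- pmax(sweep(coords %*% w$phi_w1, 2L, as.numeric(w$phi_b1), "+"), 0)
  delta <- sweep(h %*% w$phi_w2, 2L, as.numeric(w$phi_b2), "+")
  sweep(cbind(f, delta) %*% w$psi_w, 2L, as.numeric(w$psi_b), "+")
}

#' Relation-attention block
#'
#' The residual attention update: the block computes the deviation between
#' the input features and their self-attention transform, F_RA = F_in - F_SA,
#' passes it through a Linear-BatchNorm-ReLU map and adds the input back:
#' F_out = LBR(F_RA) + F_in. Zeroing the LBR weights therefore recovers the
#' identity exactly, and a collapsed attention (F_SA = F_in) zeroes F_RA.
#'
#' @param f_in M x d feature matrix.
#' @param w Weight list: \code{Wq}, \code{Wk}, \code{Wv}, \code{lbr_w}
#'   (d x d), \code{lbr_b}, \code{gamma}, \code{beta} (1 x d each).
#' @param neighbors Optional patch matrix as in \code{\link{self_attention}}.
#' @param scale Attention scaling mode.
#' @return M x d output features.
#' @export
relation_attention <- function(f_in, w, neighbors = NULL,
                               scale = c("da", "sqrt_da")) {
  scale <- match.arg(scale)
  f_in <- as.matrix(f_in)
  sa <- self_attention(f_in, w$Wq, w$Wk, w$Wv, neighbors, scale)
  f_ra <- f_in - sa$output
  lin <- sweep(f_ra %*% w$lbr_w, 2L, as.numeric(w$lbr_b), "+")
  bn <- .bn_value(lin, as.numeric(w$gamma), as.numeric(w$beta))
  pmax(bn, 0) + f_in
}

.bn_value <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  sweep(sweep(sweep(xc, 2L, istd, "*"), 2L, gamma, "*"), 2L, beta, "+")
}

#' Network configuration
#'
#' Encoder-decoder with four downsampling and four mirrored upsampling
#' stages; a relation-attention block follows every downsampling step,
#' downsampling itself is farthest-point sampling plus local max-pooling over
#' kNN patches, and upsampling interpolates features from the three nearest
#' coarse points with inverse-distance weights. Skip connections concatenate
#' same-resolution encoder features.
#'
#' @param input_points Expected cloud size N (downsample ratios must divide
#'   into at least one point).
#' @param base_width Width of the input embedding MLP (default 64).
#' @param stage_widths Four encoder stage widths (default 64/128/256/512).
#' @param downsample_ratio Per-stage point reduction factor (default 4).
#' @param k_neighbors Patch size for pooling and attention (default 16).
#' @param num_classes Output classes s (default 2: background/structure).
#' @param scale Attention scaling mode (see \code{\link{attention_config}}).
#' @param seed Seed for weight initialization.
#' @return List of class \code{network_config}.
#' @export
network_config <- function(input_points = 3072L, base_width = 64L,
                           stage_widths = c(64L, 128L, 256L, 512L),
                           downsample_ratio = 4L, k_neighbors = 16L,
                           num_classes = 2L, scale = c("da", "sqrt_da"),
                           seed = 1L) {
  scale <- match.arg(scale)
  if (length(stage_widths) != 4L) stop("exactly 4 encoder stage widths")
  sizes <- input_points
  for (i in 1:4) sizes <- c(sizes, floor(sizes[length(sizes)] / downsample_ratio))
  if (min(sizes) < 1L)
    stop("input_points too small for four stages at this downsample_ratio")
  structure(list(input_points = as.integer(input_points),
                 base_width = as.integer(base_width),
                 stage_widths = as.integer(stage_widths),
                 downsample_ratio = as.integer(downsample_ratio),
                 k_neighbors = as.integer(k_neighbors),
                 num_classes = as.integer(num_classes),
                 scale = scale, seed = as.integer(seed),
                 level_sizes = as.integer(sizes)),
            class = "network_config")
}

.winit <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

.zeros <- function(nin, nout = NULL) {
  if (is.null(nout)) matrix(0, 1, nin) else matrix(0, nin, nout)
}

# build the full parameter list (named plain matrices), deterministic in seed
.init_params <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  p <- list()
  bw <- config$base_width
  p$emb_w1 <- .winit(3L, bw); p$emb_b1 <- .zeros(bw)
  p$emb_w2 <- .winit(bw, bw); p$emb_b2 <- .zeros(bw)
  din <- bw
  for (i in 1:4) {
    d <- config$stage_widths[i]
    da <- max(1L, d %/% 4L)
    pre <- sprintf("enc%d_", i)
    p[[paste0(pre, "phi_w1")]] <- .winit(3L, d)
    p[[paste0(pre, "phi_b1")]] <- .zeros(d)
    p[[paste0(pre, "phi_w2")]] <- .winit(d, d)
    p[[paste0(pre, "phi_b2")]] <- .zeros(d)
    p[[paste0(pre, "psi_w")]] <- .winit(din + d, d)
    p[[paste0(pre, "psi_b")]] <- .zeros(d)
    p[[paste0(pre, "Wq")]] <- .winit(d, da)
    p[[paste0(pre, "Wk")]] <- .winit(d, da)
    p[[paste0(pre, "Wv")]] <- .winit(d, d)
    p[[paste0(pre, "lbr_w")]] <- .winit(d, d)
    p[[paste0(pre, "lbr_b")]] <- .zeros(d)
    p[[paste0(pre, "gamma")]] <- matrix(1, 1, d)
    p[[paste0(pre, "beta")]] <- .zeros(d)
    din <- d
  }
  skips <- c(config$base_width, config$stage_widths[1:3])
  for (i in 4:1) {
    dskip <- skips[i]
    dcur <- config$stage_widths[i]
    pre <- sprintf("dec%d_", i)
    p[[paste0(pre, "w")]] <- .winit(dcur + dskip, dskip)
    p[[paste0(pre, "b")]] <- .zeros(dskip)
    p[[paste0(pre, "gamma")]] <- matrix(1, 1, dskip)
    p[[paste0(pre, "beta")]] <- .zeros(dskip)
  }
  p$head_w1 <- .winit(bw, bw); p$head_b1 <- .zeros(bw)
  p$head_w2 <- .winit(bw, config$num_classes)
  p$head_b2 <- .zeros(config$num_classes)
  p
}

# linear + bias on tape
.ad_linear <- function(tape, x, w, b) {
  ad_add_bias(tape, ad_mm(tape, x, w), b)
}

# forward pass for one normalized cloud; returns the logits node, the tape
# and the wrapped parameter nodes (for the backward sweep)
.forward <- function(params, config, pts) {
  tape <- ad_tape()
  pn <- lapply(params, function(m) ad_param(tape, m))
  k <- config$k_neighbors
  ratio <- config$downsample_ratio
  coords <- pts
  x <- ad_relu(tape, .ad_linear(tape, ad_const(tape, pts),
                                pn$emb_w1, pn$emb_b1))
  x <- ad_relu(tape, .ad_linear(tape, x, pn$emb_w2, pn$emb_b2))
  skip_feats <- list(x)
  level_coords <- list(coords)
  for (i in 1:4) {
    prev <- level_coords[[i]]
    m_i <- max(1L, nrow(prev) %/% ratio)
    sel <- .fps_idx(prev, m_i, .canonical_start(prev))
    cur <- prev[sel, , drop = FALSE]
    pool_idx <- .knn_idx(cur, prev, min(k, nrow(prev)))
    f_pool <- ad_group_max(tape, skip_feats[[i]], pool_idx)
    pre <- sprintf("enc%d_", i)
    h <- ad_relu(tape, .ad_linear(tape, ad_const(tape, cur),
                                  pn[[paste0(pre, "phi_w1")]],
                                  pn[[paste0(pre, "phi_b1")]]))
    delta <- .ad_linear(tape, h, pn[[paste0(pre, "phi_w2")]],
                        pn[[paste0(pre, "phi_b2")]])
    f_in <- .ad_linear(tape, ad_concat_cols(tape, f_pool, delta),
                       pn[[paste0(pre, "psi_w")]], pn[[paste0(pre, "psi_b")]])
    att_idx <- .knn_idx(cur, cur, min(k, nrow(cur)))
    d <- config$stage_widths[i]
    da <- max(1L, d %/% 4L)
    f_sa <- ad_local_attention(tape,
                               ad_mm(tape, f_in, pn[[paste0(pre, "Wq")]]),
                               ad_mm(tape, f_in, pn[[paste0(pre, "Wk")]]),
                               ad_mm(tape, f_in, pn[[paste0(pre, "Wv")]]),
                               att_idx, .att_scale(da, config$scale))
    f_ra <- ad_sub(tape, f_in, f_sa)
    lbr <- ad_relu(tape, ad_batchnorm(tape,
                                      .ad_linear(tape, f_ra,
                                                 pn[[paste0(pre, "lbr_w")]],
                                                 pn[[paste0(pre, "lbr_b")]]),
                                      pn[[paste0(pre, "gamma")]],
                                      pn[[paste0(pre, "beta")]]))
    f_out <- ad_add(tape, lbr, f_in)
    skip_feats[[i + 1L]] <- f_out
    level_coords[[i + 1L]] <- cur
  }
  x <- skip_feats[[5]]
  for (i in 4:1) {
    fine <- level_coords[[i]]
    coarse <- level_coords[[i + 1L]]
    kk <- min(3L, nrow(coarse))
    idx <- .knn_idx(fine, coarse, kk)
    d2 <- matrix(0, nrow(fine), kk)
    for (l in seq_len(kk))
      d2[, l] <- rowSums((fine - coarse[idx[, l], , drop = FALSE])^2)
    w <- 1 / (d2 + 1e-8)
    w <- w / rowSums(w)
    up <- ad_interp(tape, x, idx, w)
    pre <- sprintf("dec%d_", i)
    x <- ad_relu(tape, ad_batchnorm(tape,
                                    .ad_linear(tape,
                                               ad_concat_cols(tape, up,
                                                              skip_feats[[i]]),
                                               pn[[paste0(pre, "w")]],
                                               pn[[paste0(pre, "b")]]),
                                    pn[[paste0(pre, "gamma")]],
                                    pn[[paste0(pre, "beta")]]))
  }
  x <- ad_relu(tape, .ad_linear(tape, x, pn$head_w1, pn$head_b1))
  logits <- .ad_linear(tape, x, pn$head_w2, pn$head_b2)
  list(tape = tape, logits = logits, params = pn)
}

#' Per-point class scores from the encoder-decoder network
#'
#' Runs a forward pass for one cloud and returns an N x s matrix of class
#' scores (logits). The cloud is normalized to the unit ball internally; the
#' output row order matches the input point order.
#'
#' @param cloud A \code{point_cloud}.
#' @param params Named parameter list (from \code{.init_params} or a trained
#'   model's \code{params}).
#' @param config A \code{network_config}.
#' @return N x num_classes score matrix.
#' @export
encode_decode <- function(cloud, params, config) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  if (n < config$downsample_ratio^4)
    stop("cloud smaller than the product of the downsample ratios")
  pts <- normalize_cloud(cloud)$cloud$points
  fw <- .forward(params, config, pts)
  fw$logits$value
}

#' Mean softmax cross-entropy loss
#'
#' Mean over points of the negative log softmax probability of the true
#' class.
#'
#' @param scores N x s matrix of raw class scores.
#' @param labels Length-N integer labels in [0, s).
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) stop("labels do not match score rows")
  if (any(labels < 0L | labels >= ncol(scores)))
    stop("label out of range for the score matrix")
  zs <- scores - apply(scores, 1L, max)
  p <- exp(zs) / rowSums(exp(zs))
  -mean(log(pmax(p[cbind(seq_along(labels), labels + 1L)], 1e-300)))
}

#' Mean intersection-over-union (percent)
#'
#' Mean over classes of TP / (TP + FP + FN), times 100. A class absent from
#' both truth and prediction has an empty union; its ratio is taken as 1 so
#' that a perfect prediction always scores 100 regardless of which classes
#' occur.
#'
#' @param pred,truth Equal-length integer class vectors in [0, K).
#' @param K Number of classes (default 2).
#' @return Percentage in [0, 100].
#' @export
miou <- function(pred, truth, K = 2L) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (any(c(pred, truth) < 0L | c(pred, truth) >= K))
    stop("class out of range")
  ious <- vapply(seq_len(K) - 1L, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
  }, numeric(1))
  mean(ious) * 100
}
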