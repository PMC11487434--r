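# Adam optimizer state and update, operating on the named parameter list

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one forward/backward pass on a normalized cloud; returns loss and grads
.loss_and_grads <- function(params, config, pts, labels) {
  fw <- .forward(params, config, pts)
  loss_nd <- ad_softmax_xent(fw$tape, fw$logits, as.integer(labels))
  ad_backward(fw$tape, loss_nd)
  grads <- lapply(fw$params, function(nd) nd$grad)
  list(loss = as.numeric(loss_nd$value), grads = grads)
}

#' Train the relation-attention segmentation network
#'
#' Mini-batch training with the Adam optimizer and step learning-rate decay.
#' Defaults mirror the published training setup: learning rate 0.003, decay
#' factor 0.5, batch size 4. Gradients are accumulated over the clouds of a
#' batch; each cloud is normalized to the unit ball before the forward pass.
#' The checkpoint with the best validation mIoU is kept.
#'
#' @param dataset List of \code{labeled_cloud}s, all of the same size.
#' @param config A \code{\link{network_config}}.
#' @param epochs Number of epochs.
#' @param validation Optional list of held-out \code{labeled_cloud}s; when
#'   omitted, the training set is also the validation set.
#' @param lr Initial learning rate (default 0.003).
#' @param decay Learning-rate decay factor (default 0.5).
#' @param decay_every Epoch interval for the step decay (default 20).
#' @param batch_size Clouds per optimizer step (default 4).
#' @param seed Seed controlling initialization and shuffling; the run is
#'   fully deterministic given the seed.
#' @param verbose Print per-epoch loss/mIoU.
#' @return Object of class \code{vertrot_model}: \code{params} (best
#'   checkpoint), \code{final_params}, \code{config}, and \code{log}, a data
#'   frame with per-epoch \code{epoch}, \code{loss}, \code{val_miou},
#'   \code{lr}.
#' @export
train_segmentation <- function(dataset, config, epochs = 30L,
                               validation = NULL, lr = 0.003, decay = 0.5,
                               decay_every = 20L, batch_size = 4L,
                               seed = config$seed, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  sizes <- vapply(dataset, n_points, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("all training clouds must have the same size")
  if (is.null(validation)) validation <- dataset
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cfg <- config
  cfg$seed <- as.integer(seed)
  params <- .init_params(cfg)
  state <- .adam_init(params)
  norm_pts <- lapply(dataset, function(lc) normalize_cloud(lc$cloud)$cloud$points)
  labels <- lapply(dataset, function(lc) lc$labels)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_miou = numeric(0), lr = numeric(0))
  best <- list(miou = -Inf, params = params)
  n <- length(dataset)
  for (ep in seq_len(epochs)) {
    cur_lr <- lr * decay^((ep - 1L) %/% decay_every)
    ord <- sample.int(n)
    ep_loss <- 0
    nbatch <- 0L
    for (bs in seq(1L, n, by = batch_size)) {
      members <- ord[bs:min(n, bs + batch_size - 1L)]
      acc <- NULL
      bloss <- 0
      for (ix in members) {
        lg <- .loss_and_grads(params, cfg, norm_pts[[ix]], labels[[ix]])
        bloss <- bloss + lg$loss
        if (is.null(acc)) acc <- lg$grads
        else for (nm in names(acc))
          if (!is.null(lg$grads[[nm]]))
            acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
      }
      acc <- lapply(acc, function(g) g / length(members))
      up <- .adam_step(params, acc, state, cur_lr)
      params <- up$params
      state <- up$state
      ep_loss <- ep_loss + bloss / length(members)
      nbatch <- nbatch + 1L
    }
    ep_loss <- ep_loss / nbatch
    vm <- mean(vapply(validation, function(lc) {
      scores <- encode_decode(lc$cloud, params, cfg)
      miou(max.col(scores) - 1L, lc$labels, cfg$num_classes)
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss,
                                 val_miou = vm, lr = cur_lr))
    if (vm > best$miou) best <- list(miou = vm, params = params)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val mIoU %.2f%%  lr %.5f",
                      ep, ep_loss, vm, cur_lr))
  }
  structure(list(params = best$params, final_params = params, config = cfg,
                 log = log, best_val_miou = best$miou),
            class = "vertrot_model")
}

#' @export
print.vertrot_model <- function(x, ...) {
  cat(sprintf("<vertrot_model: %d-class, widths %s, best val mIoU %.2f%%>\n",
              x$config$num_classes,
              paste(x$config$stage_widths, collapse = "/"),
              x$best_val_miou))
  invisible(x)
}

#' Predict per-point labels with a trained model
#'
#' @param object A \code{vertrot_model}.
#' @param cloud A \code{point_cloud} (or \code{labeled_cloud}, labels
#'   ignored).
#' @param ... Unused.
#' @return Integer vector of predicted class labels (0-based).
#' @export
predict.vertrot_model <- function(object, cloud, ...) {
  if (inherits(cloud, "labeled_cloud")) cloud <- cloud$cloud
  scores <- encode_decode(cloud, object$params, object$config)
  max.col(scores) - 1L
}

#' Save / load a trained model as plain JSON
#'
#' Checkpoints are single JSON files with the configuration embedded, so they
#' survive text-only storage and remain inspectable.
#'
#' @param model A \code{vertrot_model}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(m)
      list(dim = dim(m), data = as.numeric(m))),
    best_val_miou = model$best_val_miou
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- network_config(cfg$input_points, cfg$base_width, cfg$stage_widths,
                           cfg$downsample_ratio, cfg$k_neighbors,
                           cfg$num_classes, cfg$scale, cfg$seed)
  params <- lapply(payload$params, function(p)
    matrix(p$data, p$dim[1], p$dim[2]))
  structure(list(params = params, final_params = params, config = config,
                 log = NULL, best_val_miou = payload$best_val_miou),
            class = "vertrot_model")
}
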