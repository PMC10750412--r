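#' Training configuration
#'
#' Collects the supervised-training recipe: binary cross-entropy loss,
#' Adadelta optimization (rho 0.95, eps 1e-6, lr 1 — the canonical settings;
#' Adadelta adapts its own step sizes), per-epoch shuffling, and
#' best-validation checkpoint selection. Reference batch sizes are 10 for
#' the completion network and 4 for the enhancement network; reference epoch
#' counts at full scale are 1,200 and 20, but defaults here are desk-scale.
#'
#' @param batch_size Samples per optimizer step (>= 1).
#' @param epochs Training epochs (>= 1).
#' @param rho,eps,lr Adadelta decay, stabilizer and learning-rate scale.
#' @param shuffle_each_epoch Reshuffle the training order every epoch.
#' @param validation_fraction Fraction of the data held out for validation
#'   when no explicit validation set is given.
#' @param seed RNG seed controlling the split, shuffling and initialization.
#' @param threshold Operating threshold for binarizing predictions.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 10L, epochs = 50L, rho = 0.95,
                            eps = 1e-6, lr = 1.0,
                            shuffle_each_epoch = TRUE,
                            validation_fraction = 0.2, seed = 1L,
                            threshold = 0.45) {
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  if (epochs < 1) stop("`epochs` must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), rho = rho, eps = eps, lr = lr,
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), threshold = threshold),
            class = "training_config")
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-(t * log(p) + (1 - t) * log(1 - p))`, with
#' predictions clipped to `[eps, 1 - eps]` for numerical safety. Targets are
#' 1 for bone tissue and 0 otherwise.
#'
#' @param pred A `scalar_volume` or numeric array of predicted
#'   probabilities.
#' @param target A `binary_volume` or 0/1 array on the same grid.
#' @param eps Clipping bound (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  p <- if (inherits(pred, "voxel_volume")) pred$values else pred
  t <- if (inherits(target, "voxel_volume")) target$values else target
  if (!identical(dim(p)[1:3], dim(t)[1:3])) stop("pred/target dim mismatch")
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  t <- as.numeric(t)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

# dLoss/dpred for the mean BCE; zero where the clip is active so saturated
# voxels (e.g. post-residual values above 1) stop contributing.
bce_grad <- function(pred, target, eps = 1e-7) {
  n <- length(pred)
  inside <- pred > eps & pred < 1 - eps
  p <- pmin(pmax(pred, eps), 1 - eps)
  g <- (p - target) / (p * (1 - p)) / n
  g[!inside] <- 0
  array(g, dim = dim(pred))
}

adadelta_init <- function(params) {
  lapply(params, function(p) list(
    EgW = array(0, dim = dim(p$W)), Eg_b = numeric(length(p$b)),
    EdW = array(0, dim = dim(p$W)), Ed_b = numeric(length(p$b))
  ))
}

adadelta_step <- function(params, grads, state, rho, eps, lr) {
  for (id in names(grads)) {
    g <- grads[[id]]
    s <- state[[id]]
    s$EgW <- rho * s$EgW + (1 - rho) * g$W^2
    dW <- -sqrt(s$EdW + eps) / sqrt(s$EgW + eps) * g$W
    s$EdW <- rho * s$EdW + (1 - rho) * dW^2
    params[[id]]$W <- params[[id]]$W + lr * dW
    s$Eg_b <- rho * s$Eg_b + (1 - rho) * g$b^2
    db <- -sqrt(s$Ed_b + eps) / sqrt(s$Eg_b + eps) * g$b
    s$Ed_b <- rho * s$Ed_b + (1 - rho) * db^2
    params[[id]]$b <- params[[id]]$b + lr * db
    state[[id]] <- s
  }
  list(params = params, state = state)
}

sample_io <- function(ds) {
  list(input = ds$input %||% ds$defective,
       input2 = ds$input2,
       target = ds$target %||% ds$intact)
}

net_loss_and_grads <- function(model, item, eps = 1e-7) {
  fwd <- net_forward(model, item$input, input2 = item$input2, tape = TRUE)
  tgt <- add_channel_dim(item$target)
  loss <- bce_loss(array(fwd$out, dim = dim(fwd$out)[1:3]),
                   array(tgt, dim = dim(tgt)[1:3]), eps)
  g <- bce_grad(fwd$out, tgt, eps)
  list(loss = loss, grads = net_backward(model, fwd, g))
}

net_val_loss <- function(model, items, eps = 1e-7) {
  mean(vapply(items, function(it) {
    out <- net_forward(model, it$input, input2 = it$input2)
    bce_loss(array(out, dim = dim(out)[1:3]),
             if (inherits(it$target, "voxel_volume")) it$target$values
             else it$target, eps)
  }, numeric(1)))
}

#' Train a network
#'
#' Supervised training with mean binary cross-entropy and Adadelta, gradient
#' averaging over mini-batches, optional per-epoch shuffling, and selection
#' of the parameters that achieved the best validation loss (ties resolved
#' toward the earliest epoch). Fully reproducible given `config$seed`.
#'
#' @param model A `cranionet` (its current parameters are the starting
#'   point).
#' @param datasets List of samples; each is a list with `input` (or
#'   `defective`), optional `input2`, and `target` (or `intact`) —
#'   `binary_volume`s or arrays matching the model dims.
#' @param config A [training_config()].
#' @param validation Optional explicit validation list of the same form;
#'   when `NULL`, `config$validation_fraction` of `datasets` is split off.
#' @return An object of class `cranionet_fit`: list with `model` (best
#'   validation parameters), `final_model`, `history` (data frame of
#'   per-epoch train/validation losses) and `best_epoch`.
#' @export
train_model <- function(model, datasets, config = training_config(),
                        validation = NULL) {
  stopifnot(inherits(model, "cranionet"), inherits(config, "training_config"))
  if (length(datasets) == 0L) stop("empty training set")
  items <- lapply(datasets, sample_io)
  set.seed(config$seed)
  if (is.null(validation)) {
    n_val <- max(1L, round(config$validation_fraction * length(items)))
    if (n_val >= length(items)) stop("validation split leaves no training data")
    vidx <- sample.int(length(items), n_val)
    val <- items[vidx]
    train <- items[-vidx]
  } else {
    val <- lapply(validation, sample_io)
    train <- items
  }
  state <- adadelta_init(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- if (config$shuffle_each_epoch) sample.int(length(train))
           else seq_along(train)
    ep_losses <- numeric(0)
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      gsum <- NULL
      bloss <- 0
      for (i in bidx) {
        lg <- net_loss_and_grads(model, train[[i]])
        bloss <- bloss + lg$loss
        if (is.null(gsum)) gsum <- lg$grads
        else for (id in names(gsum)) {
          gsum[[id]]$W <- gsum[[id]]$W + lg$grads[[id]]$W
          gsum[[id]]$b <- gsum[[id]]$b + lg$grads[[id]]$b
        }
      }
      nb <- length(bidx)
      for (id in names(gsum)) {
        gsum[[id]]$W <- gsum[[id]]$W / nb
        gsum[[id]]$b <- gsum[[id]]$b / nb
      }
      upd <- adadelta_step(model$params, gsum, state,
                           config$rho, config$eps, config$lr)
      model$params <- upd$params
      state <- upd$state
      ep_losses <- c(ep_losses, bloss / nb)
    }
    vloss <- net_val_loss(model, val)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(ep_losses),
                                         val_loss = vloss))
    if (vloss < best$loss) best <- list(loss = vloss, params = model$params,
                                        epoch = ep)
  }
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, final_model = model, history = history,
                 best_epoch = best$epoch, config = config),
            class = "cranionet_fit")
}

#' @export
print.cranionet_fit <- function(x, ...) {
  cat(sprintf("<cranionet fit: %s> %d epochs, best validation loss %.5f at epoch %d\n",
              x$model$name, nrow(x$history),
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
plot.cranionet_fit <- function(x, ...) {
  with(x$history, {
    plot(epoch, train_loss, type = "l", col = "steelblue",
         ylim = range(c(train_loss, val_loss)),
         xlab = "epoch", ylab = "binary cross-entropy", ...)
    graphics::lines(epoch, val_loss, col = "firebrick")
    graphics::legend("topright", c("training", "validation"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  })
  invisible(x)
}

#' @export
predict.cranionet_fit <- function(object, newdata, newdata2 = NULL, ...) {
  predict(object$model, newdata, newdata2, ...)
}

#' Select the checkpoint with the best validation loss
#'
#' @param history Data frame with a `val_loss` column (one row per epoch).
#' @param checkpoints List with one model (or parameter set) per epoch.
#' @return The checkpoint at the arg-min validation loss; ties go to the
#'   earliest epoch.
#' @export
select_best_checkpoint <- function(history, checkpoints) {
  if (nrow(history) == 0L) stop("empty training history")
  if (length(checkpoints) != nrow(history))
    stop("need exactly one checkpoint per epoch")
  checkpoints[[which.min(history$val_loss)]]
}

#' Save / load a network checkpoint
#'
#' @param model A `cranionet` or `cranionet_fit`.
#' @param path File path (`.rds`).
#' @return `load_model()` returns the saved object.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
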