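#' Training protocol configuration
#'
#' Defaults follow the study protocol: Adam at learning rate 1e-4, batch
#' size 32, at most 150 epochs in resumable sessions of 50, soft Dice as
#' the primary loss with the smoothed Jaccard distance logged as auxiliary,
#' `ReduceLROnPlateau` on validation Dice (factor 0.2, patience 5), early
#' stopping with patience 20, and periodic checkpoints every 5 epochs in
#' addition to the best-validation-Dice checkpoint.
#'
#' @param batch_size slices per gradient step.
#' @param learning_rate initial Adam step size.
#' @param max_epochs hard epoch cap.
#' @param session_epochs epochs per resumable session.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param plateau_patience epochs without validation-Dice improvement before
#'   the learning rate is reduced.
#' @param early_stop_patience epochs without improvement before training
#'   halts.
#' @param checkpoint_period periodic checkpoint interval in epochs.
#' @param jaccard_weight weight of the smoothed Jaccard distance added to
#'   the optimized loss (0 = log-only, the default interpretation).
#' @param dice_smooth smoothing constant of the soft Dice loss.
#' @param jaccard_smooth smoothing constant of the Jaccard distance.
#' @param min_delta minimum validation-Dice gain that counts as improvement.
#' @param seed integer seed for shuffling, augmentation draws and any other
#'   training-time randomness.
#' @return an object of class `sonoseg_train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-4,
                         max_epochs = 150L, session_epochs = 50L,
                         plateau_factor = 0.2, plateau_patience = 5L,
                         early_stop_patience = 20L, checkpoint_period = 5L,
                         jaccard_weight = 0, dice_smooth = 1,
                         jaccard_smooth = 100, min_delta = 1e-4,
                         seed = 42L) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1,
            early_stop_patience >= 1, checkpoint_period >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 session_epochs = as.integer(session_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 checkpoint_period = as.integer(checkpoint_period),
                 jaccard_weight = jaccard_weight,
                 dice_smooth = dice_smooth,
                 jaccard_smooth = jaccard_smooth,
                 min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "sonoseg_train_config")
}

# smoothed Jaccard distance as a tape node (auxiliary loss)
nn_jaccard_loss <- function(tp, pred, truth, smooth = 100, scaled = TRUE) {
  P <- tp_val(tp, pred)
  I <- sum(P * truth)
  U <- sum(P) + sum(truth)
  den <- U - I + smooth
  val <- 1 - (I + smooth) / den
  if (scaled) val <- val * smooth
  backward <- function(g) {
    s <- if (scaled) smooth else 1
    # d/dp [ -(I+sm)/(U-I+sm) ]  with dI/dp = t, dU/dp = 1
    dP <- -(truth * den - (I + smooth) * (1 - truth)) / den^2
    list(g * s * dP)
  }
  tp_push(tp, val, pred, backward)
}

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    if (!isTRUE(model$trainable[[nm]])) next
    g <- grads[[nm]]
    m <- st$m[[nm]]
    v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] -
      lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(NULL)
}

#' Train a segmentation network
#'
#' Minimizes the soft Dice loss (optionally plus a weighted smoothed Jaccard
#' distance) with Adam.  After every epoch the validation Dice (mean over
#' slices at threshold 0.5) is monitored: the learning rate is multiplied by
#' `plateau_factor` after `plateau_patience` epochs without improvement, and
#' training halts after `early_stop_patience` such epochs.  The best
#' validation epoch's weights are restored into the returned model; periodic
#' checkpoints are written every `checkpoint_period` epochs when
#' `checkpoint_dir` is given.  Augmentation, when configured, is applied to
#' the training partition only.
#'
#' @param model a built [sonoseg model][build_model()].
#' @param train_data,val_data lists with `images` (`H x W x 3 x N`, unit
#'   interval) and `masks` (`H x W x N`).
#' @param config a [train_config()].
#' @param augment an [augmentation_config()] for the training set, or `NULL`.
#' @param checkpoint_dir directory for periodic/best checkpoints, or `NULL`.
#' @param verbose print one line per epoch.
#' @return an object of class `sonoseg_fit`: list with `model` (best
#'   weights), `history` (tibble: epoch, loss, jaccard, val_dice, val_iou,
#'   lr, session), `best_epoch`, `best_val_dice`, `stopped_early`.
#' @export
train <- function(model, train_data, val_data, config = train_config(),
                  augment = NULL, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sonoseg_model"),
            inherits(config, "sonoseg_train_config"))
  n <- dim(train_data$images)[4]
  if (is.null(n) || n == 0L) {
    abort_sonoseg("empty training set", class = "sonoseg_train_error")
  }
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  st <- adam_state()
  lr <- config$learning_rate
  best <- -Inf
  best_epoch <- 0L
  best_params <- NULL
  best_state <- NULL
  wait <- 0L
  lr_wait <- 0L
  hist <- list()
  stopped <- FALSE
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      jaccs <- c()
      for (s in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- aperm(train_data$images[, , , idx, drop = FALSE], c(1, 2, 4, 3))
        mb <- train_data$masks[, , idx, drop = FALSE]
        if (!is.null(augment)) {
          for (bi in seq_along(idx)) {
            aug <- augment_slice(list(image = xb[, , bi, ],
                                      mask = mb[, , bi]), augment)
            xb[, , bi, ] <- aug$image
            mb[, , bi] <- aug$mask
          }
        }
        tb <- mb
        dim(tb) <- c(dim(mb)[1:2], length(idx), 1L)
        tp <- tp_new()
        pid <- model$forward(tp, tp_const(tp, xb), training = TRUE)
        lid <- nn_soft_dice_loss(tp, pid, tb, smooth = config$dice_smooth)
        jid <- nn_jaccard_loss(tp, pid, tb, smooth = config$jaccard_smooth)
        loss_id <- lid
        if (config$jaccard_weight > 0) {
          wnode <- tp_push(tp, tp_val(tp, lid) +
                             config$jaccard_weight * tp_val(tp, jid),
                           c(lid, jid),
                           function(g) list(g, g * config$jaccard_weight))
          loss_id <- wnode
        }
        grads <- tp_backward(tp, loss_id)
        adam_step(model, grads, st, lr)
        losses <- c(losses, tp_val(tp, lid))
        jaccs <- c(jaccs, tp_val(tp, jid))
      }
      vm <- eval_arrays(model, val_data)
      val_dice <- mean(vm$dice)
      val_iou <- mean(vm$iou)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(losses), jaccard = mean(jaccs),
        val_dice = val_dice, val_iou = val_iou, lr = lr,
        session = (epoch - 1L) %/% config$session_epochs + 1L)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %g",
                        epoch, mean(losses), val_dice, lr))
      }
      improved <- val_dice > best + config$min_delta
      if (improved) {
        best <- val_dice
        best_epoch <- epoch
        best_params <- as.list(model$params)
        best_state <- as.list(model$state)
        wait <- 0L
        lr_wait <- 0L
        if (!is.null(checkpoint_dir)) {
          save_checkpoint(model, file.path(checkpoint_dir, "best.rds"))
        }
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
      }
      if (!is.null(checkpoint_dir) && epoch %% config$checkpoint_period == 0L) {
        save_checkpoint(model, file.path(checkpoint_dir,
                                         sprintf("epoch_%03d.rds", epoch)))
      }
      if (lr_wait >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        lr_wait <- 0L
      }
      if (wait >= config$early_stop_patience) {
        stopped <- TRUE
        break
      }
    }
  })
  if (!is.null(best_params)) {
    for (nm in names(best_params)) model$params[[nm]] <- best_params[[nm]]
    for (nm in names(best_state)) model$state[[nm]] <- best_state[[nm]]
  }
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch, best_val_dice = best,
                 stopped_early = stopped, config = config),
            class = "sonoseg_fit")
}

#' @export
print.sonoseg_fit <- function(x, ...) {
  cat(sprintf("<sonoseg_fit> %s, %d epochs%s, best val Dice %.4f (epoch %d)\n",
              x$model$spec$architecture, nrow(x$history),
              if (x$stopped_early) " (early stop)" else "",
              x$best_val_dice, x$best_epoch))
  invisible(x)
}

# per-slice metrics of a model (or a plain images -> probabilities function)
# on an in-memory dataset
eval_arrays <- function(model, data, threshold = 0.5) {
  probs <- if (is.function(model)) model(data$images)
  else predict_probs(model, data$images)
  n <- dim(data$masks)[3]
  if (length(dim(probs)) == 2L) dim(probs) <- c(dim(probs), 1L)
  dice <- numeric(n); iou_ <- numeric(n); acc <- numeric(n)
  for (i in seq_len(n)) {
    pm <- (probs[, , i] >= threshold) * 1
    dice[i] <- dice_coefficient(pm, data$masks[, , i])
    iou_[i] <- iou(pm, data$masks[, , i])
    acc[i] <- binary_accuracy(probs[, , i], data$masks[, , i], threshold)
  }
  list(dice = dice, iou = iou_, accuracy = acc)
}

#' Evaluate a model on a dataset
#'
#' Computes per-slice Dice, IoU and binary accuracy at threshold 0.5 and
#' their means (macro average over slices).  `model` may also be a function
#' mapping an image stack to probabilities (e.g. a ground-truth oracle in
#' tests).
#'
#' @param model a [sonoseg model][build_model()] or a prediction function.
#' @param data list with `images` and `masks` as in [train()].
#' @param threshold binarization threshold (ties count as positive).
#' @return an object of class `sonoseg_metric_report`: tibble with one row
#'   per slice (`slice`, `dice`, `iou`, `accuracy`) and aggregate attributes.
#' @export
evaluate <- function(model, data, threshold = 0.5) {
  m <- eval_arrays(model, data, threshold)
  rep_ <- tibble::tibble(slice = seq_along(m$dice), dice = m$dice,
                         iou = m$iou, accuracy = m$accuracy)
  structure(rep_, class = c("sonoseg_metric_report", class(rep_)),
            aggregate = list(mean_dice = mean(m$dice), mean_iou = mean(m$iou),
                             mean_accuracy = mean(m$accuracy),
                             n_slices = length(m$dice),
                             aggregation = "macro (mean of per-slice metrics)"),
            threshold = threshold)
}

#' Write a metric report as CSV plus JSON summary
#'
#' @param report a [evaluate()] result.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return the two paths, invisibly.
#' @export
write_metric_report <- function(report, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  js <- file.path(dir, paste0(prefix, ".json"))
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(attr(report, "aggregate"), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv = csv, json = js))
}
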