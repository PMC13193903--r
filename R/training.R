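#' Training configuration
#'
#' Settings for the linear-probe (LP) and linear-probe-then-fine-tune (LP-FT)
#' regimes. In LP only the classifier head is trained on top of the frozen
#' backbone; in LP-FT the whole network is subsequently trained end-to-end at
#' a reduced learning rate. The default backbone is the package's compact
#' CPU-scale CNN, whose "frozen backbone" is its seed-fixed randomly
#' initialized convolutional stack.
#'
#' @param regime `"LP"` or `"LP_FT"`.
#' @param backbone_id backbone identifier; `"compact-cnn"` is built in.
#'   Identifiers of ImageNet-scale backbones may be registered by the user
#'   via `backbone_factory`, but are not required by any package workflow.
#' @param batch_size minibatch size (default 64).
#' @param lr_lp linear-probing learning rate (default 1e-3).
#' @param lr_ft fine-tuning learning rate (default 1e-4; expected to be
#'   below `lr_lp`).
#' @param max_epochs_lp,max_epochs_ft epoch budgets (default 30 each).
#' @param patience early-stopping patience in epochs on validation accuracy
#'   (default 5).
#' @param weight_decay AdamW decoupled weight decay (default 1e-4).
#' @param classes ordered class list; fixes the head/confusion-matrix class
#'   order everywhere.
#' @param seed integer seed controlling initialization and data order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(regime = c("LP", "LP_FT"),
                         backbone_id = "compact-cnn", batch_size = 64,
                         lr_lp = 1e-3, lr_ft = 1e-4, max_epochs_lp = 30,
                         max_epochs_ft = 30, patience = 5,
                         weight_decay = 1e-4, classes = morph_classes(),
                         seed = 1) {
  regime <- match.arg(regime)
  stopifnot(batch_size >= 1, max_epochs_lp >= 0, max_epochs_ft >= 0,
            patience >= 1, lr_lp > 0, lr_ft > 0)
  structure(list(regime = regime, backbone_id = backbone_id,
                 batch_size = as.integer(batch_size), lr_lp = lr_lp,
                 lr_ft = lr_ft, max_epochs_lp = as.integer(max_epochs_lp),
                 max_epochs_ft = as.integer(max_epochs_ft),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, classes = classes,
                 seed = as.integer(seed)),
            class = "train_config")
}

.as_class_index <- function(labels, classes) {
  y <- match(as.character(labels), classes)
  if (anyNA(y))
    stop("labels outside the configured class list: ",
         paste(unique(labels[is.na(y)]), collapse = ", "))
  y
}

# accuracy of head-on-features
.feat_accuracy <- function(feats, y, hw, hb) {
  logits <- sweep(feats %*% hw, 2, hb, `+`)
  mean(max.col(logits, ties.method = "first") == y)
}

#' Train a linear probe
#'
#' Trains only the classifier head on top of the frozen backbone (for the
#' compact CNN: its seed-fixed randomly initialized convolutional stack).
#' The backbone features of the train and validation sets are computed once;
#' the head is then optimized with AdamW and cross-entropy, monitoring
#' validation accuracy each epoch, keeping the best checkpoint (ties broken
#' by earliest epoch) and stopping early after `patience` non-improving
#' epochs.
#'
#' @param data list with elements `train` and `val`, each
#'   `list(x = stem-feature matrix from [prepare_inputs()], y = labels)`.
#' @param cfg a [train_config()].
#' @return an object of class `ifcmorph_classifier` with elements
#'   `backbone_id`, `params`, `classes`, `log` (per-epoch phase/loss/val
#'   accuracy), `best_epoch`, `val_accuracy` and `cfg`.
#' @export
linear_probe <- function(data, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(data$train) || length(data$train$y) == 0)
    stop("empty train split")
  if (cfg$backbone_id != "compact-cnn")
    stop("backbone '", cfg$backbone_id, "' is not built in; ",
         "only 'compact-cnn' ships with the package")
  arch <- .compact_arch()
  K <- length(cfg$classes)
  params <- .init_params(arch, K, cfg$seed)
  ytr <- .as_class_index(data$train$y, cfg$classes)
  yva <- .as_class_index(data$val$y, cfg$classes)

  feats_tr <- backbone_forward(params, arch, data$train$x)$features
  feats_va <- backbone_forward(params, arch, data$val$x)$features

  # Head optimization runs on per-feature standardized activations (centre
  # and scale estimated on the training split); the affine reparameterization
  # is folded back into the head weights at checkpoint time, so the stored
  # model is a plain linear head on raw backbone features.
  fmu <- colMeans(feats_tr)
  fsd <- pmax(apply(feats_tr, 2, stats::sd), 1e-3)
  feats_tr <- sweep(sweep(feats_tr, 2, fmu), 2, fsd, `/`)
  feats_va <- sweep(sweep(feats_va, 2, fmu), 2, fsd, `/`)

  hw <- params$head_w
  hb <- params$head_b
  opt <- .adamw_init(list(hw = hw, hb = hb))
  n <- nrow(feats_tr)
  log <- data.frame()
  best <- list(acc = -Inf, epoch = 0L, hw = hw, hb = hb)
  stall <- 0L
  with_seed(seed_stream(cfg$seed, 1), {
    for (epoch in seq_len(cfg$max_epochs_lp)) {
      perm <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[b0:min(b0 + cfg$batch_size - 1, n)]
        f <- feats_tr[idx, , drop = FALSE]
        logits <- sweep(f %*% hw, 2, hb, `+`)
        sc <- .softmax_ce(logits, ytr[idx])
        losses <- c(losses, sc$loss)
        g <- list(hw = crossprod(f, sc$grad), hb = colSums(sc$grad))
        up <- .adamw_step(list(hw = hw, hb = hb), g, opt, cfg$lr_lp,
                          cfg$weight_decay)
        hw <- up$params$hw; hb <- up$params$hb; opt <- up$state
      }
      acc <- .feat_accuracy(feats_va, yva, hw, hb)
      log <- rbind(log, data.frame(phase = "lp", epoch = epoch,
                                   train_loss = mean(losses),
                                   val_accuracy = acc))
      if (acc > best$acc) {
        best <- list(acc = acc, epoch = epoch, hw = hw, hb = hb)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  })
  params$head_w <- best$hw / fsd
  params$head_b <- as.numeric(best$hb - fmu %*% (best$hw / fsd))
  structure(list(backbone_id = cfg$backbone_id, params = params,
                 arch = arch, classes = cfg$classes, log = log,
                 best_epoch = best$epoch, val_accuracy = best$acc,
                 cfg = cfg),
            class = "ifcmorph_classifier")
}

#' Fine-tune a trained classifier end-to-end
#'
#' Continues from a linear-probe checkpoint with all parameters trainable at
#' the reduced learning rate `lr_ft`. The incoming checkpoint is the initial
#' best candidate, so the returned model's validation accuracy never falls
#' below the probe's. With `max_epochs_ft = 0` the model is returned
#' unchanged.
#'
#' @param model an `ifcmorph_classifier` (from [linear_probe()]).
#' @param data as in [linear_probe()].
#' @param cfg a [train_config()]; a warning is issued when
#'   `lr_ft >= lr_lp` (fine-tuning is meant to use a reduced rate).
#' @return the fine-tuned `ifcmorph_classifier`, with the training log
#'   appended.
#' @export
fine_tune <- function(model, data, cfg = model$cfg) {
  stopifnot(inherits(model, "ifcmorph_classifier"),
            inherits(cfg, "train_config"))
  if (cfg$max_epochs_ft == 0) return(model)
  if (cfg$lr_ft >= cfg$lr_lp)
    warning("lr_ft >= lr_lp: fine-tuning is expected to use a reduced rate")
  arch <- model$arch
  ytr <- .as_class_index(data$train$y, model$classes)
  yva <- .as_class_index(data$val$y, model$classes)
  n <- nrow(data$train$x)
  nl <- length(arch$layers)

  fl <- .flatten_params(model$params)
  opt <- .adamw_init(fl)
  val_acc <- function(fl) {
    p <- .unflatten_params(fl, nl)
    f <- backbone_forward(p, arch, data$val$x)$features
    .feat_accuracy(f, yva, p$head_w, p$head_b)
  }
  best <- list(acc = val_acc(fl), epoch = 0L, fl = fl)
  stall <- 0L
  log <- model$log
  with_seed(seed_stream(cfg$seed, 2), {
    for (epoch in seq_len(cfg$max_epochs_ft)) {
      perm <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[b0:min(b0 + cfg$batch_size - 1, n)]
        p <- .unflatten_params(fl, nl)
        fw <- backbone_forward(p, arch,
                               data$train$x[idx, , drop = FALSE],
                               keep_cache = TRUE)
        logits <- sweep(fw$features %*% p$head_w, 2, p$head_b, `+`)
        sc <- .softmax_ce(logits, ytr[idx])
        losses <- c(losses, sc$loss)
        g <- list(hw = crossprod(fw$features, sc$grad),
                  hb = colSums(sc$grad))
        dA <- sc$grad %*% t(p$head_w)
        for (i in rev(seq_len(nl))) {
          bk <- .conv_backward(dA, arch$layers[[i]], p$conv_w[[i]],
                               fw$caches[[i]], need_dx = (i > 1))
          g[[paste0("cw", i)]] <- bk$dW
          g[[paste0("cb", i)]] <- bk$db
          dA <- bk$dX
        }
        up <- .adamw_step(fl, g, opt, cfg$lr_ft, cfg$weight_decay)
        fl <- up$params; opt <- up$state
      }
      acc <- val_acc(fl)
      log <- rbind(log, data.frame(phase = "ft", epoch = epoch,
                                   train_loss = mean(losses),
                                   val_accuracy = acc))
      if (acc > best$acc) {
        best <- list(acc = acc, epoch = epoch, fl = fl)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  })
  model$params <- .unflatten_params(best$fl, nl)
  model$log <- log
  model$best_epoch <- best$epoch
  model$val_accuracy <- best$acc
  model$cfg <- cfg
  model
}

#' Train under a configured regime
#'
#' Convenience wrapper: runs [linear_probe()] and, when the regime is
#' `"LP_FT"`, [fine_tune()].
#'
#' @inheritParams linear_probe
#' @return an `ifcmorph_classifier`.
#' @export
train_classifier <- function(data, cfg = train_config()) {
  model <- linear_probe(data, cfg)
  if (cfg$regime == "LP_FT") model <- fine_tune(model, data, cfg)
  model
}

#' Predict classes and probabilities
#'
#' Deterministic inference; outputs are independent of how inputs are
#' batched. Inputs may be a stem-feature matrix (from [prepare_inputs()]), a
#' single `224 x 224 x 3` model input, or a list of model inputs.
#'
#' @param object an `ifcmorph_classifier`.
#' @param inputs input batch (see Details).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return list with `labels` (character vector) and `probs` (matrix, one
#'   row per input, columns in `object$classes` order; rows sum to 1).
#' @export
predict.ifcmorph_classifier <- function(object, inputs, batch_size = 256,
                                        ...) {
  X <- .coerce_inputs(inputs)
  K <- length(object$classes)
  probs <- matrix(0, nrow(X), K, dimnames = list(NULL, object$classes))
  for (b0 in seq(1, nrow(X), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, nrow(X))
    f <- backbone_forward(object$params, object$arch,
                          X[idx, , drop = FALSE])$features
    logits <- sweep(f %*% object$params$head_w, 2, object$params$head_b, `+`)
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    probs[idx, ] <- e / rowSums(e)
  }
  labels <- object$classes[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs)
}

.coerce_inputs <- function(inputs) {
  if (is.matrix(inputs)) {
    if (ncol(inputs) != 1024)
      stop("feature matrix must have 1024 columns (32 x 32 stem features)")
    return(inputs)
  }
  if (is.array(inputs) && length(dim(inputs)) == 3) inputs <- list(inputs)
  if (is.list(inputs)) {
    ok <- vapply(inputs, function(x)
      is.array(x) && length(dim(x)) == 3 && all(dim(x) == c(224, 224, 3)),
      logical(1))
    if (!all(ok)) stop("model inputs must be 224 x 224 x 3 arrays")
    return(do.call(rbind, lapply(inputs, function(x)
      matrix(stem_reduce(x), 1))))
  }
  stop("unsupported input type for prediction")
}

#' @export
print.ifcmorph_classifier <- function(x, ...) {
  cat("<ifcmorph_classifier ", x$backbone_id, ", ", length(x$classes),
      " classes, best epoch ", x$best_epoch, ", val accuracy ",
      sprintf("%.3f", x$val_accuracy), ">\n", sep = "")
  invisible(x)
}
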