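#' Training configuration
#'
#' Defaults follow the study protocol: per-channel binary cross-entropy on
#' one-hot targets over 5 prediction channels, ADAM, up to 30 epochs with
#' early stopping after 7 epochs without validation-loss improvement. The
#' encoder-decoder is the package's compact U-Net; `base_channels` sets its
#' width (tests and the desk-scale synthetic cohort use a narrow net so CPU
#' training stays tractable).
#'
#' @param base_channels U-Net width (channels of the first encoder level).
#' @param n_classes Prediction channels (4 foreground + background).
#' @param lr ADAM learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (consecutive epochs without
#'   validation-loss improvement); must be < `max_epochs`.
#' @param batch_size Patches per ADAM step.
#' @param val_fraction Fraction of cases held out for validation; the split
#'   is at case level so patches of one case never straddle the split.
#' @param seed Seed for initialization, shuffling and augmentation draws.
#' @param normalize Apply stain normalization to every patch.
#' @param augment Apply the augmentation policy during training.
#' @param policy An `augment_policy`.
#' @param reference A `stain_reference`.
#' @return A `train_config` object.
#' @export
train_config <- function(base_channels = 16L, n_classes = 5L, lr = 1e-4,
                         max_epochs = 30L, patience = 7L, batch_size = 4L,
                         val_fraction = 0.2, seed = 1L,
                         normalize = TRUE, augment = TRUE,
                         policy = augment_policy(),
                         reference = stain_reference()) {
  stopifnot(patience < max_epochs, val_fraction > 0, val_fraction <= 0.5,
            batch_size >= 1L, base_channels >= 2L)
  structure(list(base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 normalize = normalize, augment = augment,
                 policy = policy, reference = reference),
            class = "train_config")
}

# Early-stopping bookkeeping, separated so the rule is testable on a bare
# loss sequence: stop once `patience` consecutive epochs fail to improve on
# the best validation loss; the best epoch is the argmin seen so far.
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; stall <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        return(list(stopped_at = e, best_epoch = best_epoch))
      }
    }
  }
  list(stopped_at = length(val_losses), best_epoch = best_epoch)
}

# extract (and optionally stain-normalize) the image/mask windows of a
# patch set; returns a list of lists with image, target, weight
extract_patches <- function(patchset, rois, config) {
  lapply(seq_len(nrow(patchset)), function(i) {
    roi <- rois[[patchset$roi_id[i]]]
    p <- attr(patchset, "patch_size") %||% min(dim(roi$mask))
    x <- patchset$x[i]; y <- patchset$y[i]
    img <- roi$image[(y + 1):(y + p), (x + 1):(x + p), , drop = FALSE]
    msk <- roi$mask[(y + 1):(y + p), (x + 1):(x + p)]
    if (config$normalize) {
      img <- normalize_patch(img, config$reference)
    }
    list(image = img, mask = msk, case_id = patchset$case_id[i])
  })
}

#' Train the segmentation model
#'
#' Trains the compact U-Net on a balanced patch set with weighted
#' per-channel binary cross-entropy and ADAM. Cases are split into training
#' and validation at case level; after each epoch the validation loss is
#' evaluated and training halts early when it has not improved for
#' `patience` consecutive epochs. The returned weights are those of the
#' best (minimum validation loss) epoch. Fully seeded: identical seed,
#' data and configuration give identical weights.
#'
#' @param patchset A `patch_set` (from [build_patchset()]); its
#'   `patch_size` attribute, when present, overrides the window size.
#' @param rois List of `annotated_roi` indexed by `patchset$roi_id`.
#' @param config A `train_config`.
#' @param patch_size Patch window side; must be divisible by 4.
#' @return A `trained_model`: flat weight vector, config snapshot,
#'   per-epoch history and `best_epoch`.
#' @export
train <- function(patchset, rois, config = train_config(),
                  patch_size = NULL) {
  stopifnot(nrow(patchset) > 0L)
  if (!is.null(patch_size)) attr(patchset, "patch_size") <- patch_size
  p <- attr(patchset, "patch_size")
  stopifnot(!is.null(p), p %% 4 == 0)

  cases <- unique(patchset$case_id)
  if (length(cases) < 2L) {
    stop("no validation cases available: need >= 2 cases for a case-level split")
  }
  n_val <- max(1L, round(config$val_fraction * length(cases)))
  val_cases <- with_seed(config$seed,
                         sample(cases, n_val))
  data <- extract_patches(patchset, rois, config)
  is_val <- vapply(data, function(d) d$case_id %in% val_cases, logical(1))
  train_idx <- which(!is_val); val_idx <- which(is_val)
  if (length(train_idx) == 0L) stop("no training patches after split")

  present <- sort(unique(unlist(lapply(data[train_idx],
                                       function(d) unique(as.vector(d$mask))))))
  absent <- setdiff(unname(RPC_TARGET_CODES), present)
  if (length(absent) > 0L) {
    warning("class code(s) absent from training targets: ",
            paste(absent, collapse = ", "))
  }

  nb <- config$base_channels; K <- config$n_classes
  params <- unet_init(nb, K, seed = config$seed)
  state <- NULL
  prepared <- lapply(data, function(d) {
    tw <- make_targets(d$mask)
    list(image = d$image, mask = d$mask, target = tw$target,
         weight = tw$weight)
  })

  val_loss_of <- function(pars) {
    # forward-only: no gradients needed for the early-stopping metric
    mean(vapply(val_idx, function(i) {
      d <- prepared[[i]]
      scores <- cpp_unet_forward(pars, image_to_input(d$image), nb, K)
      bce_reference(scores, d$target, d$weight)
    }, numeric(1)))
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- Inf; best_epoch <- 0L; best_params <- params; stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- with_seed(config$seed + 17L * epoch, sample(train_idx))
    epoch_losses <- numeric(0)
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / config$batch_size))
    for (b in seq_along(batches)) {
      idxs <- batches[[b]]
      gsum <- NULL; lsum <- 0
      for (j in seq_along(idxs)) {
        d <- prepared[[idxs[j]]]
        img <- d$image; tgt <- d$target; wgt <- d$weight
        if (config$augment) {
          aug <- augment(img, d$mask, config$policy,
                         seed = config$seed + 7873L * epoch + 131L * idxs[j])
          img <- aug$patch
          tw <- make_targets(aug$mask)
          tgt <- tw$target; wgt <- tw$weight
        }
        lg <- cpp_unet_loss_grad(params, image_to_input(img), tgt, wgt, nb, K)
        gsum <- if (is.null(gsum)) lg$grad else gsum + lg$grad
        lsum <- lsum + lg$loss
      }
      step <- adam_step(params, gsum / length(idxs), state, lr = config$lr)
      params <- step$params; state <- step$state
      epoch_losses <- c(epoch_losses, lsum / length(idxs))
    }
    vl <- val_loss_of(params)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = mean(epoch_losses),
                                val_loss = vl))
    if (vl < best) {
      best <- vl; best_epoch <- epoch; best_params <- params; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(list(params = best_params, config = config,
                 patch_size = as.integer(p), history = history,
                 best_epoch = best_epoch),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d-channel U-Net, %d params, best epoch %d/%d (val loss %.4f)\n",
              x$config$base_channels, length(x$params), x$best_epoch,
              nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is plain JSON: the flat weight vector, the configuration
#' snapshot, the training history and the best epoch.
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @return `load_model` returns the `trained_model`.
#' @export
save_model <- function(model, path) {
  cfg <- model$config
  cfg$policy <- unclass(cfg$policy)
  cfg$reference <- list(stain_matrix = as.vector(cfg$reference$stain_matrix),
                        percentile = cfg$reference$percentile)
  obj <- list(params = model$params, config = unclass(cfg),
              patch_size = model$patch_size, history = model$history,
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$policy <- do.call(augment_policy, as.list(cfg$policy))
  cfg$reference <- stain_reference(
    matrix(cfg$reference$stain_matrix, nrow = 2),
    percentile = cfg$reference$percentile)
  config <- structure(cfg, class = "train_config")
  structure(list(params = as.numeric(obj$params), config = config,
                 patch_size = as.integer(obj$patch_size),
                 history = as.data.frame(obj$history),
                 best_epoch = as.integer(obj$best_epoch)),
            class = "trained_model")
}
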