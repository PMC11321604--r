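# Encoder-decoder model surface. The network itself lives in src/unet.cpp:
# a compact two-level U-Net with skip connections, per-channel sigmoid
# outputs, and weighted binary cross-entropy. Width is set by
# `base_channels`; tests and the desk-scale cohort use a narrow net.

unet_nparams <- function(base_channels, n_classes) {
  layout <- cpp_unet_layout(base_channels, n_classes)
  sum(layout[, 1] * layout[, 2] * layout[, 3]^2 + layout[, 2])
}

# He-initialized flat parameter vector (biases zero)
unet_init <- function(base_channels, n_classes, seed = 1L) {
  layout <- cpp_unet_layout(base_channels, n_classes)
  with_seed(seed, {
    unlist(lapply(seq_len(nrow(layout)), function(i) {
      cin <- layout[i, 1]; cout <- layout[i, 2]; k <- layout[i, 3]
      fan_in <- cin * k^2
      c(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), rep(0, cout))
    }))
  })
}

# image (0..255 integer array) -> centered float cube for the network
image_to_input <- function(image) {
  (image / 255) - 0.5
}

# forward pass on one patch -> H x W x K sigmoid score array
unet_scores <- function(params, image, base_channels, n_classes) {
  cpp_unet_forward(params, image_to_input(image), base_channels, n_classes)
}

#' One-hot training targets with ignore weighting
#'
#' Expands a target-code mask into five binary planes (background is an
#' explicit channel) plus a weight plane that is 0 at ignore pixels and 1
#' elsewhere; ignore pixels contribute nothing to the loss.
#'
#' @param mask Target-code mask (0..4, 255 = ignore).
#' @return List with `target` (H x W x 5 array) and `weight` (H x W matrix).
#' @export
make_targets <- function(mask) {
  mask <- validate_mask(mask)
  codes <- unname(RPC_TARGET_CODES)
  target <- array(0, dim = c(nrow(mask), ncol(mask), length(codes)))
  for (i in seq_along(codes)) {
    target[, , i] <- (mask == codes[i]) * 1
  }
  weight <- (mask != RPC_IGNORE_CODE) * 1
  list(target = target, weight = weight)
}

# scalar reference BCE for oracle tests: mean over weighted pixel-channel
# terms of -t*log(p) - (1-t)*log(1-p)
bce_reference <- function(scores, target, weight) {
  K <- dim(scores)[3]
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  terms <- -(target * log(p) + (1 - target) * log(1 - p))
  w <- array(rep(weight, K), dim = dim(scores))
  sum(terms * w) / (sum(weight) * K)
}

# Adam step on a flat parameter vector; state carries m, v, t
adam_step <- function(params, grad, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(m = 0 * params, v = 0 * params, t = 0L)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(params = as.numeric(params - lr * mhat / (sqrt(vhat) + eps)),
       state = state)
}
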