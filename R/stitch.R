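#' Stitching specification for sliding-window inference
#'
#' @param patch_size Patch side (divisible by 4 for the network).
#' @param stride Inference stride (defaults to half overlap).
#' @param eps Floor of the weight kernel; keeps every covered pixel at a
#'   strictly positive weight.
#' @return A `stitch_spec`.
#' @export
stitch_spec <- function(patch_size = 512L, stride = patch_size %/% 2L,
                        eps = 0.01) {
  stopifnot(stride >= 1L, stride <= patch_size, eps > 0)
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride), eps = eps),
            class = "stitch_spec")
}

# separable raised-cosine window peaking at the patch center, floored at eps
stitch_kernel <- function(patch_size, eps = 0.01) {
  i <- seq_len(patch_size) - 0.5
  w <- pmax(0.5 - 0.5 * cos(2 * pi * i / patch_size), eps)
  outer(w, w)
}

# inference anchor positions along one axis: multiples of the stride plus a
# final anchor clamped so the last patch reaches the border
infer_positions <- function(extent, patch_size, stride) {
  last <- extent - patch_size
  pos <- seq.int(0L, last, by = stride)
  if (pos[length(pos)] != last) pos <- c(pos, last)
  pos
}

#' Predict a whole ROI by weighted sliding-window stitching
#'
#' Runs the model over partially overlapping patches (stride `spec$stride`,
#' final anchors clamped so the last row/column reaches the ROI border) and
#' combines the per-patch sigmoid scores into per-pixel class scores by a
#' weighted average with a separable raised-cosine kernel: at every pixel,
#' `score = sum(kernel * patch_score) / sum(kernel)` over covering patches.
#' The label is the argmax over channels, ties resolved to the lowest class
#' code. ROIs smaller than the patch are reflect-padded for inference only.
#'
#' @param model A `trained_model`.
#' @param roi An `annotated_roi` (or bare image array).
#' @param spec A `stitch_spec`; defaults to the model's training patch size
#'   with half-overlap stride.
#' @return A `stitched_prediction`: `scores` (H x W x K), `labels`
#'   (H x W target codes), `weight` (accumulated kernel mass).
#' @export
predict_roi <- function(model, roi, spec = NULL) {
  stopifnot(inherits(model, "trained_model"))
  image <- if (inherits(roi, "annotated_roi")) roi$image else roi
  if (is.null(spec)) {
    spec <- stitch_spec(model$patch_size, model$patch_size %/% 2L)
  }
  if (spec$patch_size %% 4 != 0) {
    stop("patch_size must be divisible by 4 for the encoder-decoder")
  }
  K <- model$config$n_classes
  H0 <- dim(image)[1]; W0 <- dim(image)[2]; P <- spec$patch_size
  # reflect-pad small ROIs for inference only
  padh <- max(0L, P - H0); padw <- max(0L, P - W0)
  if (padh > 0 || padw > 0) {
    ri <- c(seq_len(H0), rev(seq_len(H0)))[seq_len(H0 + padh)]
    ci <- c(seq_len(W0), rev(seq_len(W0)))[seq_len(W0 + padw)]
    image <- image[ri, ci, , drop = FALSE]
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  kern <- stitch_kernel(P, spec$eps)
  acc <- array(0, dim = c(H, W, K))
  wacc <- matrix(0, H, W)
  nb <- model$config$base_channels
  for (y in infer_positions(H, P, spec$stride)) {
    for (x in infer_positions(W, P, spec$stride)) {
      patch <- image[(y + 1):(y + P), (x + 1):(x + P), , drop = FALSE]
      if (isTRUE(model$config$normalize)) {
        patch <- normalize_patch(patch, model$config$reference)
      }
      s <- unet_scores(model$params, patch, nb, K)
      rows <- (y + 1):(y + P); cols <- (x + 1):(x + P)
      for (k in seq_len(K)) {
        acc[rows, cols, k] <- acc[rows, cols, k] + s[, , k] * kern
      }
      wacc[rows, cols] <- wacc[rows, cols] + kern
    }
  }
  scores <- acc / array(rep(wacc, K), dim = dim(acc))
  scores <- scores[seq_len(H0), seq_len(W0), , drop = FALSE]
  wacc <- wacc[seq_len(H0), seq_len(W0), drop = FALSE]
  # argmax with ties to the lowest class code
  flat <- matrix(scores, ncol = K)
  labels <- matrix(unname(RPC_TARGET_CODES)[max.col(flat, ties.method = "first")],
                   H0, W0)
  structure(list(scores = scores, labels = labels, weight = wacc),
            class = "stitched_prediction")
}

RPC_PALETTE <- rbind(
  background      = c(0, 0, 0),
  normal_ducts    = c(0, 200, 0),
  cancer          = c(230, 0, 0),
  other_epithelium = c(255, 140, 0),
  fat             = c(255, 235, 120),
  ignore          = c(255, 255, 255)
)

#' Render a prediction (or mask) as an RGB overlay
#'
#' Fixed palette: cancer red, non-neoplastic ducts green, other epithelium
#' orange, fat pale yellow (configurable), background black, ignore white.
#' The palette is a bijection, so [rgb_to_codes()] inverts it exactly.
#'
#' @param x A `stitched_prediction` or a target-code mask.
#' @param fat_color Length-3 RGB (0..255) override for the fat class.
#' @return Integer H x W x 3 RGB array.
#' @export
render_rgb <- function(x, fat_color = NULL) {
  labels <- if (inherits(x, "stitched_prediction")) x$labels else x
  pal <- RPC_PALETTE
  if (!is.null(fat_color)) pal["fat", ] <- fat_color
  codes <- c(unname(RPC_TARGET_CODES), RPC_IGNORE_CODE)
  out <- array(0L, dim = c(nrow(labels), ncol(labels), 3L))
  idx <- match(as.vector(labels), codes)
  for (c in 1:3) out[, , c] <- matrix(pal[idx, c], nrow(labels))
  storage.mode(out) <- "integer"
  out
}

#' @rdname render_rgb
#' @param rgb Integer H x W x 3 array produced by [render_rgb()].
#' @export
rgb_to_codes <- function(rgb, fat_color = NULL) {
  pal <- RPC_PALETTE
  if (!is.null(fat_color)) pal["fat", ] <- fat_color
  codes <- c(unname(RPC_TARGET_CODES), RPC_IGNORE_CODE)
  key <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  got <- rgb[, , 1] * 65536 + rgb[, , 2] * 256 + rgb[, , 3]
  idx <- match(as.vector(got), key)
  if (anyNA(idx)) stop("RGB image contains colors outside the palette")
  matrix(codes[idx], nrow = dim(rgb)[1])
}

#' Per-class pixel counts and the RPC count
#'
#' Exact histogram of class codes in a prediction or mask; the residual
#' pancreatic cancer (RPC) burden is the cancer-class pixel count.
#'
#' @param x A `stitched_prediction` or target-code mask.
#' @return Named integer vector of counts (`background`, `normal_ducts`,
#'   `cancer`, `other_epithelium`, `fat`, `ignore`) with the RPC count in
#'   `attr(, "rpc")`.
#' @export
count_class_pixels <- function(x) {
  labels <- if (inherits(x, "stitched_prediction")) x$labels else x
  codes <- c(unname(RPC_TARGET_CODES), RPC_IGNORE_CODE)
  counts <- vapply(codes, function(cd) sum(labels == cd), integer(1))
  names(counts) <- c(names(RPC_TARGET_CODES), "ignore")
  attr(counts, "rpc") <- counts[["cancer"]]
  counts
}
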