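#' Stain normalization reference
#'
#' Holds the reference hematoxylin/eosin optical-density basis that patches
#' are mapped onto, the robust percentile used when estimating a patch's
#' stain extremes, and (for the channel-statistics method) reference OD
#' channel means/SDs.
#'
#' @param stain_matrix 2 x 3 reference OD basis (rows: H, E); row-normalized.
#' @param percentile Robust angle/concentration percentile in (90, 100].
#' @param od_stats Optional list with `mean` and `sd` (length-3 OD channel
#'   statistics) for the Reinhard-style method; computed lazily from a
#'   canonical reference rendering when absent.
#' @return A `stain_reference` object.
#' @export
stain_reference <- function(stain_matrix = RPC_REF_STAIN_MATRIX,
                            percentile = 99, od_stats = NULL) {
  stopifnot(identical(dim(stain_matrix), c(2L, 3L)),
            percentile > 90, percentile <= 100)
  stain_matrix <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  structure(list(stain_matrix = stain_matrix, percentile = percentile,
                 od_stats = od_stats),
            class = "stain_reference")
}

# image (0..255) -> optical density, N x 3
image_to_od <- function(image) {
  od <- -log((pmax(image, 0) + 1) / 256)
  dim(od) <- c(prod(dim(image)[1:2]), 3L)
  od
}

od_to_image <- function(od, dims) {
  img <- 256 * exp(-od) - 1
  img <- pmin(pmax(round(img), 0), 255)
  dim(img) <- dims
  storage.mode(img) <- "integer"
  img
}

# Macenko-style stain basis estimation: eigen-plane of the tissue OD cloud,
# robust angular extremes as the two stain vectors. Returns NULL when the
# patch has too little tissue to estimate from.
estimate_stain_basis <- function(image, percentile = 99, beta = 0.15) {
  od <- image_to_od(image)
  tissue <- od[rowSums(od) > 3 * beta & apply(od, 1, min) > 0.03, ,
               drop = FALSE]
  if (nrow(tissue) < 50L) return(NULL)
  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  basis <- ev$vectors[, 1:2, drop = FALSE]          # 3 x 2 plane
  # orient the plane so projections are positive for tissue OD
  if (mean(tissue %*% basis[, 1]) < 0) basis[, 1] <- -basis[, 1]
  proj <- tissue %*% basis                           # N x 2
  phi <- atan2(proj[, 2], proj[, 1])
  alpha <- (100 - percentile) / 100
  lo <- stats::quantile(phi, alpha, names = FALSE)
  hi <- stats::quantile(phi, 1 - alpha, names = FALSE)
  v1 <- basis %*% c(cos(lo), sin(lo))
  v2 <- basis %*% c(cos(hi), sin(hi))
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
  v1 <- v1 / n1; v2 <- v2 / n2
  if (abs(sum(v1 * v2)) > 0.999) return(NULL)  # collinear: no 2-stain basis
  # hematoxylin absorbs more red than eosin does
  s <- if (v1[1] >= v2[1]) rbind(as.vector(v1), as.vector(v2))
       else rbind(as.vector(v2), as.vector(v1))
  rownames(s) <- c("h", "e")
  s
}

#' Normalize a patch onto the reference stain basis
#'
#' Stain-deconvolution color normalization: the patch's two-stain OD basis
#' is estimated from the angular extremes of its tissue OD cloud
#' (Macenko-style singular-plane estimation), per-pixel stain
#' concentrations are obtained by least squares against that basis, and the
#' image is re-rendered through the reference basis. The alternative
#' `method = "reinhard"` matches per-channel OD means and SDs to reference
#' statistics instead. Masks are never touched.
#'
#' @param patch Integer image array H x W x 3 (0..255).
#' @param reference A `stain_reference`.
#' @param method `"macenko"` (deconvolution, default) or `"reinhard"`
#'   (channel statistics).
#' @return Normalized image, same shape and dtype. Degenerate (blank /
#'   near-white) patches are returned unchanged with a warning.
#' @export
normalize_patch <- function(patch, reference = stain_reference(),
                            method = c("macenko", "reinhard")) {
  method <- match.arg(method)
  dims <- dim(patch)
  if (method == "reinhard") {
    stats_ref <- reference$od_stats %||% reference_od_stats()
    od <- image_to_od(patch)
    m <- colMeans(od); s <- apply(od, 2, stats::sd)
    if (all(s < 1e-6)) {
      warning("degenerate (blank) patch; returned unchanged")
      return(patch)
    }
    s[s < 1e-6] <- 1e-6
    od <- sweep(sweep(od, 2, m), 2, stats_ref$sd / s, `*`)
    od <- sweep(od, 2, stats_ref$mean, `+`)
    return(od_to_image(pmax(od, 0), dims))
  }
  basis <- estimate_stain_basis(patch, reference$percentile)
  if (is.null(basis)) {
    warning("degenerate (blank / near-white) patch; returned unchanged")
    return(patch)
  }
  od <- image_to_od(patch)
  conc <- od %*% t(basis) %*% solve(basis %*% t(basis))  # N x 2 least squares
  conc <- pmax(conc, 0)
  od_new <- conc %*% reference$stain_matrix
  od_to_image(od_new, dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# OD channel statistics of a canonical reference rendering; cached.
reference_od_stats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(roi_size = 96, seed = 424242L)
      roi <- generate_roi(spec, default_scanner_profiles()$philips,
                          seed = 424242L)
      od <- image_to_od(roi$image)
      cache <<- list(mean = colMeans(od), sd = apply(od, 2, stats::sd))
    }
    cache
  }
})

#' Training-time augmentation policy
#'
#' Geometric part: the identity, 90/180/270-degree rotations, and
#' horizontal/vertical flips, one drawn uniformly per call and applied to
#' image and mask alike. Color part: jitter of brightness, contrast and
#' saturation by a factor drawn from `1 +/- range` and an additive hue
#' rotation, applied to the image only.
#'
#' @param geometric,color Enable flags for the two parts.
#' @param brightness,contrast,saturation Jitter half-ranges (fractions).
#' @param hue Hue rotation half-range (fraction of the hue circle).
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(geometric = TRUE, color = TRUE,
                           brightness = 0.10, contrast = 0.10,
                           saturation = 0.10, hue = 0.02) {
  stopifnot(brightness >= 0, contrast >= 0, saturation >= 0, hue >= 0)
  structure(list(geometric = geometric, color = color,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue),
            class = "augment_policy")
}

# 90-degree CCW rotation / flips for H x W matrices and H x W x C arrays
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
apply_geom <- function(x, op) {
  f <- switch(op,
    identity = function(m) m,
    rot90 = rot90_mat,
    rot180 = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = function(m) rot90_mat(rot90_mat(rot90_mat(m))),
    hflip = function(m) m[, ncol(m):1, drop = FALSE],
    vflip = function(m) m[nrow(m):1, , drop = FALSE]
  )
  if (length(dim(x)) == 2L) return(f(x))
  planes <- lapply(seq_len(dim(x)[3]), function(c) f(x[, , c]))
  out <- array(0L, dim = c(dim(planes[[1]]), length(planes)))
  for (c in seq_along(planes)) out[, , c] <- planes[[c]]
  storage.mode(out) <- storage.mode(x)
  out
}

color_jitter <- function(image, policy) {
  img <- image / 255
  jit <- function(r) stats::runif(1, -r, r)
  img <- pmin(pmax(img * (1 + jit(policy$brightness)), 0), 1)
  img <- pmin(pmax((img - 0.5) * (1 + jit(policy$contrast)) + 0.5, 0), 1)
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  sat <- 1 + jit(policy$saturation)
  for (c in 1:3) img[, , c] <- pmin(pmax(gray + sat * (img[, , c] - gray), 0), 1)
  dh <- jit(policy$hue)
  if (abs(dh) > 0) {
    flat <- matrix(aperm(img, c(3, 1, 2)), nrow = 3)
    hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + dh) %% 1
    rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
    img <- aperm(array(rgb, dim = c(3, dim(img)[1], dim(img)[2])), c(2, 3, 1))
  }
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Apply a random augmentation draw to a patch/mask pair
#'
#' @param patch Image array H x W x 3.
#' @param mask Aligned target-code mask.
#' @param policy An `augment_policy`.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return List with `patch` and `mask`.
#' @export
augment <- function(patch, mask, policy = augment_policy(), seed = 1L) {
  with_seed(seed, {
    if (policy$geometric) {
      op <- sample(c("identity", "rot90", "rot180", "rot270",
                     "hflip", "vflip"), 1L)
      patch <- apply_geom(patch, op)
      mask <- apply_geom(mask, op)
    }
    if (policy$color &&
        (policy$brightness > 0 || policy$contrast > 0 ||
         policy$saturation > 0 || policy$hue > 0)) {
      patch <- color_jitter(patch, policy)
    }
  })
  list(patch = patch, mask = mask)
}
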