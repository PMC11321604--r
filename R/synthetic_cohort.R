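# Classic H&E optical-density unit vectors (hematoxylin, eosin).
RPC_REF_STAIN_MATRIX <- local({
  m <- rbind(h = c(0.65, 0.70, 0.29),
             e = c(0.07, 0.99, 0.11))
  m / sqrt(rowSums(m^2))
})

#' Scanner color profile
#'
#' Describes how one scanner renders the same stained tissue: its effective
#' stain basis in optical-density space plus simple post-hoc photometric
#' distortions. Profiles perturb only the image; the label mask of a given
#' geometry seed is identical across profiles.
#'
#' @param name Profile name.
#' @param stain_matrix 2 x 3 matrix of OD vectors (rows: hematoxylin,
#'   eosin); rows are normalized to unit length.
#' @param brightness Additive offset in 8-bit units.
#' @param contrast Multiplicative gain about mid-gray (128).
#' @param gamma Per-channel gamma exponents, length 3.
#' @param noise_sd Gaussian sensor noise SD in 8-bit units.
#' @return A `scanner_profile` object.
#' @export
scanner_profile <- function(name, stain_matrix = RPC_REF_STAIN_MATRIX,
                            brightness = 0, contrast = 1,
                            gamma = c(1, 1, 1), noise_sd = 2) {
  stopifnot(identical(dim(stain_matrix), c(2L, 3L)), all(stain_matrix >= 0),
            length(gamma) == 3L, noise_sd >= 0)
  stain_matrix <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  structure(list(name = name, stain_matrix = stain_matrix,
                 brightness = brightness, contrast = contrast,
                 gamma = gamma, noise_sd = noise_sd),
            class = "scanner_profile")
}

# rotate the two stain vectors toward each other by fraction `mix`
mix_stains <- function(m, mix) {
  out <- rbind((1 - mix) * m[1, ] + mix * m[2, ],
               (1 - mix) * m[2, ] + mix * m[1, ])
  out / sqrt(rowSums(out^2))
}

#' Default profiles for the four scanner types
#'
#' The philips profile is the neutral reference; hamamatsu is a mild
#' perturbation; leica is moderate; 3dhistech is deliberately the most
#' divergent (rotated stain basis, strong gamma/brightness shift), mirroring
#' the qualitative color-profile differences reported between scanner
#' vendors.
#'
#' @return Named list of four `scanner_profile`s.
#' @export
default_scanner_profiles <- function() {
  ref <- RPC_REF_STAIN_MATRIX
  list(
    philips = scanner_profile("philips", ref, brightness = 0, contrast = 1,
                              gamma = c(1, 1, 1), noise_sd = 2),
    hamamatsu = scanner_profile("hamamatsu", mix_stains(ref, 0.05),
                                brightness = 3, contrast = 1,
                                gamma = c(0.98, 1, 1.02), noise_sd = 2),
    `3dhistech` = scanner_profile("3dhistech", mix_stains(ref, 0.25),
                                  brightness = -12, contrast = 1.1,
                                  gamma = c(1.2, 0.85, 1.1), noise_sd = 3),
    leica = scanner_profile("leica", mix_stains(ref, 0.12),
                            brightness = 8, contrast = 0.95,
                            gamma = c(1.05, 0.95, 1.0), noise_sd = 2.5)
  )
}

#' Synthetic cohort specification
#'
#' @param n_cases Cases to generate per (center, scanner) combination.
#' @param roi_size ROI side length in pixels (square ROIs).
#' @param class_mixture Named expected area fractions for `normal_ducts`,
#'   `cancer`, `other_epithelium`, `fat`; must be non-negative and sum to
#'   at most 1 (the remainder is stroma background).
#' @param duct_radius Range (min, max) of duct radii in px.
#' @param wall_frac Duct wall thickness as a fraction of the radius.
#' @param atypia Cancer boundary irregularity amplitude (0 = smooth);
#'   normal ducts always render smooth.
#' @param seed Global integer seed; case `i` uses `seed + i`.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases = 2,
                        roi_size = 192,
                        class_mixture = c(normal_ducts = 0.10, cancer = 0.18,
                                          other_epithelium = 0.08, fat = 0.08),
                        duct_radius = c(14, 26),
                        wall_frac = 0.55,
                        atypia = 0.35,
                        seed = 1L) {
  need <- c("normal_ducts", "cancer", "other_epithelium", "fat")
  stopifnot(all(need %in% names(class_mixture)))
  class_mixture <- class_mixture[need]
  if (any(class_mixture < 0) || sum(class_mixture) > 1) {
    stop("class_mixture fractions must be >= 0 and sum to <= 1")
  }
  stopifnot(roi_size >= 32, duct_radius[1] <= duct_radius[2],
            wall_frac > 0, wall_frac <= 1)
  structure(list(n_cases = n_cases, roi_size = roi_size,
                 class_mixture = class_mixture, duct_radius = duct_radius,
                 wall_frac = wall_frac, atypia = atypia,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# smooth low-frequency noise field, bilinear upsample of a coarse grid
smooth_field <- function(n, coarse = 8, sd = 1) {
  g <- matrix(stats::rnorm(coarse^2, sd = sd), coarse, coarse)
  idx <- seq(1, coarse, length.out = n)
  i0 <- pmin(floor(idx), coarse - 1); f <- idx - i0
  a <- g[i0, i0, drop = FALSE] * outer(1 - f, 1 - f) +
    g[i0 + 1, i0, drop = FALSE] * outer(f, 1 - f) +
    g[i0, i0 + 1, drop = FALSE] * outer(1 - f, f) +
    g[i0 + 1, i0 + 1, drop = FALSE] * outer(f, f)
  a
}

# per-class stain concentrations (hematoxylin, eosin)
RPC_CLASS_STAINS <- list(
  stroma           = c(h = 0.10, e = 0.38),
  normal_wall      = c(h = 0.55, e = 0.22),
  cancer_wall      = c(h = 1.05, e = 0.30),
  other_epithelium = c(h = 0.38, e = 0.70),
  fat              = c(h = 0.02, e = 0.04),
  lumen            = c(h = 0.03, e = 0.05),
  nucleus          = c(h = 1.80, e = 0.00),  # chromatin: pure hematoxylin
  fiber            = c(h = 0.00, e = 0.90)   # dense collagen: pure eosin
)

# Geometry + concentration maps for one ROI; scanner-independent.
# Returns mask, ch, ce and the realized per-class fractions.
generate_geometry <- function(spec) {
  n <- spec$roi_size
  mask <- matrix(0L, n, n)
  st <- RPC_CLASS_STAINS
  ch <- matrix(st$stroma["h"], n, n) + 0.03 * smooth_field(n, sd = 1)
  ce <- matrix(st$stroma["e"], n, n) + 0.06 * smooth_field(n, sd = 1)
  # sparse near-pure eosin collagen specks: anchor the eosin extreme of the
  # stain basis so deconvolution-based normalization is well-posed
  specks <- which(stats::runif(n * n) < 0.02)
  ch[specks] <- st$fiber["h"]; ce[specks] <- st$fiber["e"]

  rows <- matrix(seq_len(n), n, n)          # row index grid
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)

  place_disk <- function(code, hconc, econc, r_rng, jagged = FALSE,
                         lumen = FALSE, dots = 0) {
    r <- stats::runif(1, r_rng[1], r_rng[2])
    cy <- stats::runif(1, 1 + r, n - r)
    cx <- stats::runif(1, 1 + r, n - r)
    dy <- rows - cy; dx <- cols - cx
    dist <- sqrt(dy^2 + dx^2)
    if (jagged && spec$atypia > 0) {
      theta <- atan2(dy, dx)
      k <- sample(3:6, 2)
      ph <- stats::runif(2, 0, 2 * pi)
      a <- stats::runif(2, 0.4, 1) * spec$atypia
      rb <- r * (1 + a[1] * sin(k[1] * theta + ph[1]) +
                   a[2] * sin(k[2] * theta + ph[2]))
    } else {
      rb <- r
    }
    inside <- dist <= rb
    mask[inside] <<- code
    wall <- inside & dist > rb * (1 - spec$wall_frac)
    core <- inside & !wall
    ch[wall] <<- hconc; ce[wall] <<- econc
    if (lumen) {
      ch[core] <<- st$lumen["h"]; ce[core] <<- st$lumen["e"]
    } else {
      ch[core] <<- hconc; ce[core] <<- econc
    }
    if (dots > 0) {
      wi <- which(wall)
      if (length(wi) > 0) {
        pick <- wi[stats::runif(length(wi)) < dots]
        ch[pick] <<- st$nucleus["h"]; ce[pick] <<- st$nucleus["e"]
      }
    }
    sum(inside)
  }

  budget <- spec$class_mixture * n^2
  realize <- function(code_name) sum(mask == RPC_TARGET_CODES[[code_name]])

  # draw order: fat, other epithelium, normal ducts, cancer last (on top)
  fill_class <- function(code_name, fun) {
    tries <- 0L
    while (realize(code_name) < budget[[code_name]] && tries < 400L) {
      fun(); tries <- tries + 1L
    }
  }
  fill_class("fat", function()
    place_disk(4L, st$fat["h"], st$fat["e"],
               spec$duct_radius * 0.8, lumen = FALSE))
  fill_class("other_epithelium", function() {
    r0 <- spec$duct_radius * 0.45
    for (i in seq_len(sample(3:5, 1)))
      place_disk(3L, st$other_epithelium["h"], st$other_epithelium["e"], r0)
  })
  fill_class("normal_ducts", function()
    place_disk(1L, st$normal_wall["h"], st$normal_wall["e"],
               spec$duct_radius, jagged = FALSE, lumen = TRUE, dots = 0.04))
  fill_class("cancer", function()
    place_disk(2L, st$cancer_wall["h"], st$cancer_wall["e"],
               spec$duct_radius, jagged = TRUE, lumen = TRUE, dots = 0.25))

  fractions <- vapply(names(spec$class_mixture), realize, numeric(1)) / n^2
  list(mask = mask, ch = ch, ce = ce, fractions = fractions)
}

#' Render stain concentration maps to RGB via Beer-Lambert composition
#'
#' `I_c = 256 * exp(-(ch * H_c + ce * E_c)) - 1` per channel `c`, where the rows
#' of `stain_matrix` are the hematoxylin and eosin OD vectors. This is the
#' exact forward model of the synthetic cohort, which is what makes
#' deconvolution-based normalization verifiable against a known basis.
#'
#' @param ch,ce Matrices of hematoxylin / eosin concentrations.
#' @param stain_matrix 2 x 3 OD basis.
#' @return Numeric array H x W x 3 in [0, 255] (unrounded).
#' @export
render_stains <- function(ch, ce, stain_matrix = RPC_REF_STAIN_MATRIX) {
  stopifnot(identical(dim(ch), dim(ce)))
  out <- array(0, dim = c(nrow(ch), ncol(ch), 3L))
  for (c in 1:3) {
    # exact inverse of the pipeline's optical-density transform
    out[, , c] <- 256 * exp(-(ch * stain_matrix[1, c] + ce * stain_matrix[2, c])) - 1
  }
  out
}

apply_scanner <- function(img, profile) {
  for (c in 1:3) {
    x <- img[, , c] / 255
    x <- pmin(pmax(x, 0), 1)^profile$gamma[c] * 255
    x <- (x - 128) * profile$contrast + 128 + profile$brightness
    if (profile$noise_sd > 0) {
      x <- x + stats::rnorm(length(x), sd = profile$noise_sd)
    }
    img[, , c] <- pmin(pmax(round(x), 0), 255)
  }
  img
}

#' Generate one synthetic annotated ROI
#'
#' Draws a gland-like scene — smooth-walled non-neoplastic ducts,
#' irregular jagged-walled cancerous ducts with dense nuclear stippling,
#' clustered epithelial blobs, pale fat circles, textured pink stroma — as
#' hematoxylin/eosin concentration maps, renders them through the scanner's
#' stain basis by Beer-Lambert composition, then applies the scanner's
#' photometric distortions and sensor noise. Identical seeds give
#' bit-identical output; the mask depends only on the seed, not the scanner.
#'
#' @param spec A `cohort_spec`.
#' @param scanner A `scanner_profile`.
#' @param seed Integer seed fixing all randomness for this ROI.
#' @param case_id,center_id Provenance recorded on the result.
#' @return An `annotated_roi`; realized per-class area fractions are stored
#'   in `attr(, "fractions")`.
#' @export
generate_roi <- function(spec, scanner, seed, case_id = "case",
                         center_id = "center") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(scanner, "scanner_profile"))
  geom <- with_seed(seed, generate_geometry(spec))
  img <- render_stains(geom$ch, geom$ce, scanner$stain_matrix)
  # separate noise stream so masks stay profile-invariant per geometry seed
  img <- with_seed(seed + 7919L * (utf8ToInt(substr(scanner$name, 1, 1)) %% 97L),
                   apply_scanner(img, scanner))
  roi <- annotated_roi(img, geom$mask, case_id, center_id, scanner$name)
  attr(roi, "fractions") <- geom$fractions
  roi
}

#' Generate a multi-center, multi-scanner synthetic cohort on disk
#'
#' Writes `n_cases` ROIs per scanner profile as PNG image/mask pairs plus a
#' manifest CSV, in the same formats the I/O layer reads. Each scanner is
#' assigned its own synthetic center. Case `i` of the cohort uses seed
#' `spec$seed + i`, so any case can be regenerated independently.
#'
#' @param spec A `cohort_spec`.
#' @param profiles List of `scanner_profile`s (>= 2 for cross-validation).
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly written to
#'   `file.path(dir, "manifest.csv")`; realized fractions per case in
#'   `attr(, "fractions")`.
#' @export
generate_cohort <- function(spec, profiles = default_scanner_profiles(),
                            dir = tempfile("cohort")) {
  stopifnot(length(profiles) >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create cohort directory: ", dir)
  rows <- list(); fracs <- list()
  i <- 0L
  for (p in profiles) {
    for (k in seq_len(spec$n_cases)) {
      i <- i + 1L
      case_id <- sprintf("%s_case%02d", p$name, k)
      center_id <- paste0("center_", p$name)
      roi <- generate_roi(spec, p, seed = spec$seed + i,
                          case_id = case_id, center_id = center_id)
      image_path <- paste0(case_id, "_img.png")
      mask_path <- paste0(case_id, "_mask.png")
      write_roi(roi, file.path(dir, image_path), file.path(dir, mask_path))
      rows[[i]] <- data.frame(case_id = case_id, center_id = center_id,
                              scanner_type = p$name, image_path = image_path,
                              mask_path = mask_path, stringsAsFactors = FALSE)
      fracs[[case_id]] <- attr(roi, "fractions")
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  attr(manifest, "dir") <- dir
  attr(manifest, "fractions") <- fracs
  invisible(manifest)
}
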