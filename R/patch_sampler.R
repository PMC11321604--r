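#' Patch sampling specification
#'
#' Defaults follow the training protocol: 512 px patches on a half-overlap
#' grid, a patch is kept only when some foreground class covers at least 10%
#' of its area, and at most 50 patches per class per case.
#'
#' @param patch_size Patch side length in px.
#' @param stride Sliding-window stride in px (<= patch_size).
#' @param inclusion_fraction Minimum area fraction of a single foreground
#'   class for a patch to qualify (inclusive).
#' @param per_case_class_cap Maximum retained patches per (case, class).
#' @return A `patch_spec` object.
#' @export
patch_spec <- function(patch_size = 512L, stride = patch_size %/% 2L,
                       inclusion_fraction = 0.10, per_case_class_cap = 50L) {
  stopifnot(inclusion_fraction > 0, inclusion_fraction <= 1,
            stride >= 1L, stride <= patch_size, per_case_class_cap >= 1L)
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 inclusion_fraction = inclusion_fraction,
                 per_case_class_cap = as.integer(per_case_class_cap)),
            class = "patch_spec")
}

#' Enumerate sliding-window patch anchors
#'
#' Top-left anchors `(i * stride, j * stride)` (0-based) for every position
#' where the full patch lies inside the ROI, in row-major order. ROIs
#' smaller than the patch in either dimension yield no anchors (no padding
#' at training time).
#'
#' @param roi_shape Integer (height, width).
#' @param spec A `patch_spec`.
#' @return data.frame with 0-based columns `x` (column) and `y` (row).
#' @export
enumerate_anchors <- function(roi_shape, spec = patch_spec()) {
  h <- roi_shape[1]; w <- roi_shape[2]; p <- spec$patch_size; s <- spec$stride
  if (h < p || w < p) {
    warning("ROI (", h, "x", w, ") smaller than patch size ", p,
            "; no anchors")
    return(data.frame(x = integer(0), y = integer(0)))
  }
  ys <- seq.int(0L, h - p, by = s)
  xs <- seq.int(0L, w - p, by = s)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

# per-class pixel counts of one patch window (0-based anchor)
patch_class_counts <- function(mask, x, y, p) {
  win <- mask[(y + 1):(y + p), (x + 1):(x + p)]
  tabulate(factor(win, levels = c(unname(RPC_TARGET_CODES), RPC_IGNORE_CODE)),
           nbins = 6L)
}

#' Filter patches by foreground content
#'
#' A patch is retained iff at least one non-background, non-ignore class
#' covers at least `inclusion_fraction` of the patch area (inclusive
#' threshold). Each retained patch is tagged with every qualifying class.
#'
#' @param anchors data.frame of `x`, `y` anchors (0-based).
#' @param mask Target-code mask the anchors index into.
#' @param spec A `patch_spec`.
#' @return data.frame `x`, `y`, `classes` (comma-separated qualifying
#'   target codes).
#' @export
filter_by_content <- function(anchors, mask, spec = patch_spec()) {
  p <- spec$patch_size
  thresh <- spec$inclusion_fraction * p * p
  keep <- logical(nrow(anchors)); classes <- character(nrow(anchors))
  fg_codes <- unname(RPC_TARGET_CODES[c("normal_ducts", "cancer",
                                        "other_epithelium", "fat")])
  for (i in seq_len(nrow(anchors))) {
    counts <- patch_class_counts(mask, anchors$x[i], anchors$y[i], p)
    qual <- fg_codes[counts[fg_codes + 1L] >= thresh]
    keep[i] <- length(qual) > 0L
    classes[i] <- paste(qual, collapse = ",")
  }
  out <- anchors[keep, , drop = FALSE]
  out$classes <- classes[keep]
  rownames(out) <- NULL
  out
}

#' Apply the per-case per-class patch cap
#'
#' For every (case, class) with more qualifying patches than the cap, a
#' uniform random subsample of exactly `per_case_class_cap` patches is
#' retained for that class; a patch kept for any of its qualifying classes
#' appears once in the result.
#'
#' @param patches data.frame with `case_id`, `roi_id`, `x`, `y`, `classes`
#'   (as produced by [build_patchset()] / [filter_by_content()]).
#' @param spec A `patch_spec`.
#' @param seed Integer seed for the subsampling.
#' @return A `patch_set`: the retained patches plus a `class_tally`
#'   attribute (case x class retained counts).
#' @export
apply_cap <- function(patches, spec = patch_spec(), seed = 1L) {
  cap <- spec$per_case_class_cap
  keep <- rep(FALSE, nrow(patches))
  class_list <- strsplit(patches$classes, ",", fixed = TRUE)
  codes <- unname(RPC_TARGET_CODES[-1])
  cases <- unique(patches$case_id)
  # tally counts patches retained FOR a class (its subsample), so it is
  # bounded by the cap even when a patch qualifies for several classes
  tally <- matrix(0L, length(cases), length(codes),
                  dimnames = list(cases, as.character(codes)))
  with_seed(seed, {
    for (case in cases) {
      in_case <- which(patches$case_id == case)
      for (code in codes) {
        tagged <- in_case[vapply(class_list[in_case],
                                 function(cl) as.character(code) %in% cl,
                                 logical(1))]
        if (length(tagged) > cap) tagged <- sort(sample(tagged, cap))
        keep[tagged] <- TRUE
        tally[case, as.character(code)] <- length(tagged)
      }
    }
  })
  out <- patches[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("patch_set", "data.frame"),
            rng_seed = as.integer(seed),
            patch_size = spec$patch_size,
            class_tally = tally)
}

#' Build a balanced patch set from a cohort
#'
#' Runs anchor enumeration, the content filter and the per-case cap over a
#' list of ROIs.
#'
#' @param rois List of `annotated_roi`.
#' @param spec A `patch_spec`.
#' @param seed Seed for cap subsampling.
#' @return A `patch_set` data.frame with `case_id`, `roi_id`, `x`, `y`,
#'   `classes`.
#' @export
build_patchset <- function(rois, spec = patch_spec(), seed = 1L) {
  per_roi <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    anchors <- enumerate_anchors(dim(roi$mask), spec)
    if (nrow(anchors) == 0L) return(NULL)
    kept <- filter_by_content(anchors, roi$mask, spec)
    if (nrow(kept) == 0L) return(NULL)
    data.frame(case_id = roi$case_id, roi_id = i, x = kept$x, y = kept$y,
               classes = kept$classes, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_roi)
  if (is.null(all) || nrow(all) == 0L) {
    stop("no qualifying patches in any ROI")
  }
  apply_cap(all, spec, seed)
}

#' Write / read a patch set as CSV
#' @param patchset A `patch_set`.
#' @param path CSV path.
#' @return The patch data.frame (read) or `path` invisibly (write).
#' @export
write_patchset <- function(patchset, path) {
  utils::write.csv(as.data.frame(patchset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patchset
#' @export
read_patchset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(classes = "character"))
}
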