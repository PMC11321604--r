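RPC_SCANNER_TYPES <- c("philips", "hamamatsu", "3dhistech", "leica")

#' Recognized scanner types
#' @return Character vector of the four scanner types.
#' @export
rpc_scanner_types <- function() RPC_SCANNER_TYPES

# px per micrometre of the working resolution ("20x"); 1 mm^2 = (2 * 1000)^2 px
RPC_PX_PER_UM <- 2

#' Construct an annotated region of interest
#'
#' An `annotated_roi` pairs an RGB image at 2 px/um with a target-code label
#' mask and case/center/scanner provenance.
#'
#' @param image Integer array `H x W x 3`, values 0..255.
#' @param mask Integer matrix `H x W` of target codes (0..4) and the ignore
#'   code 255.
#' @param case_id,center_id Identifiers.
#' @param scanner_type One of [rpc_scanner_types()].
#' @param annotated_area_mm2 Annotated area; defaults to the non-background,
#'   non-ignore mask area converted at 2 px/um.
#' @return An `annotated_roi` object.
#' @export
annotated_roi <- function(image, mask, case_id, center_id, scanner_type,
                          annotated_area_mm2 = NULL) {
  image <- validate_image(image)
  mask <- validate_mask(mask)
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("image/mask shape mismatch: image is ",
         paste(dim(image)[1:2], collapse = "x"), ", mask is ",
         paste(dim(mask), collapse = "x"))
  }
  scanner_type <- match.arg(scanner_type, RPC_SCANNER_TYPES)
  if (is.null(annotated_area_mm2)) {
    fg <- sum(mask != 0L & mask != RPC_IGNORE_CODE)
    annotated_area_mm2 <- fg / (RPC_PX_PER_UM * 1000)^2
  }
  if (annotated_area_mm2 < 0) stop("annotated_area_mm2 must be >= 0")
  structure(
    list(image = image, mask = mask, case_id = as.character(case_id),
         center_id = as.character(center_id), scanner_type = scanner_type,
         annotated_area_mm2 = annotated_area_mm2),
    class = "annotated_roi"
  )
}

validate_image <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop("image values must lie in [0, 255]")
  }
  storage.mode(image) <- "integer"
  image
}

validate_mask <- function(mask) {
  if (length(dim(mask)) != 2L) stop("mask must be an H x W matrix")
  vals <- unique(as.vector(mask))
  bad <- setdiff(vals, c(unname(RPC_TARGET_CODES), RPC_IGNORE_CODE))
  if (length(bad) > 0L) {
    stop("mask contains value(s) outside the target codes {0..4, 255}: ",
         paste(bad, collapse = ", "))
  }
  storage.mode(mask) <- "integer"
  mask
}

#' @export
print.annotated_roi <- function(x, ...) {
  cat(sprintf("<annotated_roi> case %s (center %s, %s), %dx%d px, %.3f mm2 annotated\n",
              x$case_id, x$center_id, x$scanner_type,
              nrow(x$mask), ncol(x$mask), x$annotated_area_mm2))
  invisible(x)
}

#' Read and write ROI image/mask pairs
#'
#' Images are stored as 24-bit RGB PNG, masks as single-channel 8-bit PNG
#' holding the target codes directly (0..4, 255 = ignore). A write followed
#' by a read is bit-identical for both planes.
#'
#' @param image_path,mask_path PNG paths.
#' @param case_id,center_id,scanner_type Provenance for the returned object.
#' @param roi An `annotated_roi` to write.
#' @return `read_roi` returns an `annotated_roi`; `write_roi` returns the
#'   paths, invisibly.
#' @export
read_roi <- function(image_path, mask_path, case_id = image_path,
                     center_id = "unknown", scanner_type = "philips") {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  image <- array(as.integer(round(img * 255)), dim = dim(img))
  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  mask <- matrix(as.integer(round(m * 255)), nrow = nrow(m), ncol = ncol(m))
  annotated_roi(image, mask, case_id, center_id, scanner_type)
}

#' @rdname read_roi
#' @export
write_roi <- function(roi, image_path, mask_path) {
  stopifnot(inherits(roi, "annotated_roi"))
  png::writePNG(roi$image / 255, image_path)
  png::writePNG(roi$mask / 255, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' Read and write cohort manifests
#'
#' A manifest is a CSV with columns `case_id`, `center_id`, `scanner_type`,
#' `image_path`, `mask_path`, one row per ROI; one representative slide per
#' case. Validation requires unique (case_id, image_path) rows, one scanner
#' per case, and recognized scanner types.
#'
#' @param path CSV path.
#' @param manifest Manifest data.frame to write.
#' @return `read_manifest` returns the validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  validate_manifest(m)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  required <- c("case_id", "center_id", "scanner_type", "image_path",
                "mask_path")
  miss <- setdiff(required, names(m))
  if (length(miss) > 0L) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(m$scanner_type), RPC_SCANNER_TYPES)
  if (length(bad) > 0L) {
    stop("unrecognized scanner_type(s): ", paste(bad, collapse = ", "))
  }
  per_case <- tapply(m$scanner_type, m$case_id,
                     function(s) length(unique(s)))
  if (any(per_case > 1L)) {
    stop("case(s) assigned to multiple scanners: ",
         paste(names(per_case)[per_case > 1L], collapse = ", "))
  }
  if (anyDuplicated(m[c("case_id", "image_path")])) {
    stop("duplicated (case_id, image_path) manifest rows")
  }
  m
}

#' Load the ROIs referenced by a manifest
#'
#' @param manifest Manifest data.frame.
#' @param base_dir Directory the manifest paths are relative to.
#' @return List of `annotated_roi`, one per manifest row.
#' @export
load_cohort <- function(manifest, base_dir = ".") {
  validate_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_roi(file.path(base_dir, manifest$image_path[i]),
             file.path(base_dir, manifest$mask_path[i]),
             case_id = manifest$case_id[i],
             center_id = manifest$center_id[i],
             scanner_type = manifest$scanner_type[i])
  })
}
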