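#' @useDynLib rpcseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Target class codes used throughout the pipeline. 255 marks pixels that are
# displayed but excluded from loss and metrics.
RPC_TARGET_CODES <- c(
  background      = 0L,
  normal_ducts    = 1L,
  cancer          = 2L,
  other_epithelium = 3L,
  fat             = 4L
)
RPC_IGNORE_CODE <- 255L

# The twelve original annotation classes in their canonical order.
RPC_ORIGINAL_CLASSES <- c(
  "normal_ducts", "cancer", "in_situ_neoplasia", "islets_of_langerhans",
  "acinar_tissue", "atrophic_metaplastic", "adipose_tissue", "vessels",
  "nerves", "uncertain", "lumina", "lymphoid_inflammatory"
)

#' Target class codes
#'
#' Named integer vector of the five prediction classes. The ignore code
#' (255) is available as `rpc_ignore_code()`.
#'
#' @return Named integer vector `c(background = 0, normal_ducts = 1,
#'   cancer = 2, other_epithelium = 3, fat = 4)`.
#' @export
rpc_target_codes <- function() RPC_TARGET_CODES

#' @rdname rpc_target_codes
#' @export
rpc_ignore_code <- function() RPC_IGNORE_CODE

#' Build the annotation class taxonomy
#'
#' Defines the twelve-class annotation system used when labeling ductal
#' structures in H&E regions of interest, and the merge map that collapses
#' them onto the five target classes scored by the pipeline: cancer and
#' in-situ neoplasia merge into a single cancer class; islets of Langerhans,
#' acinar tissue and atrophic/metaplastic parenchyma form "other epithelium";
#' adipose tissue is "fat"; vessels, nerves and lymphoid/inflammatory
#' infiltrates are background (as is stroma, which is never annotated);
#' "uncertain" structures are mapped to the ignore code and excluded from
#' loss and metrics. Lumina are context-dependent: at rasterization time a
#' lumen takes the class of its smallest enclosing annotated structure
#' (see [rasterize_annotations()]); the static map records background as the
#' fallback used when a lumen encloses nothing.
#'
#' @param classes Character vector of the original class names. Must contain
#'   each of the twelve recognized classes exactly once (order is free).
#' @return An object of class `rpc_taxonomy`: a list with `original`
#'   (data.frame of name, code, target_code), `target_labels`,
#'   `merge_map` (named integer, original code -> target code) and
#'   `ignore_code`.
#' @examples
#' tax <- load_taxonomy()
#' tax$merge_map[["islets_of_langerhans"]]  # 3: other_epithelium
#' @export
load_taxonomy <- function(classes = RPC_ORIGINAL_CLASSES) {
  classes <- as.character(classes)
  missing <- setdiff(RPC_ORIGINAL_CLASSES, classes)
  extra   <- setdiff(classes, RPC_ORIGINAL_CLASSES)
  if (length(missing) > 0L || length(extra) > 0L || anyDuplicated(classes)) {
    stop("taxonomy configuration error: expected the 12 original classes ",
         "exactly once each; missing: [", paste(missing, collapse = ", "),
         "]; unknown: [", paste(extra, collapse = ", "),
         "]; duplicated: [",
         paste(unique(classes[duplicated(classes)]), collapse = ", "), "]")
  }
  target_of <- c(
    normal_ducts          = 1L,
    cancer                = 2L,
    in_situ_neoplasia     = 2L,
    islets_of_langerhans  = 3L,
    acinar_tissue         = 3L,
    atrophic_metaplastic  = 3L,
    adipose_tissue        = 4L,
    vessels               = 0L,
    nerves                = 0L,
    uncertain             = RPC_IGNORE_CODE,
    lumina                = 0L,   # resolved contextually at rasterization
    lymphoid_inflammatory = 0L
  )
  original <- data.frame(
    name = RPC_ORIGINAL_CLASSES,
    code = seq_along(RPC_ORIGINAL_CLASSES),
    target_code = unname(target_of[RPC_ORIGINAL_CLASSES]),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      original = original,
      target_labels = RPC_TARGET_CODES,
      merge_map = stats::setNames(original$target_code, original$name),
      ignore_code = RPC_IGNORE_CODE
    ),
    class = "rpc_taxonomy"
  )
}

#' Merge original class codes onto target codes
#'
#' Applies the taxonomy merge map to a vector or matrix of codes. With
#' `domain = "original"` the input holds original codes 1..12 (0 =
#' unannotated -> background). With `domain = "target"` the input already
#' holds target codes and the map is the identity, so merging is idempotent.
#'
#' @param codes Integer vector or matrix of class codes.
#' @param taxonomy An `rpc_taxonomy`.
#' @param domain Either "original" or "target".
#' @return Object of the same shape with target codes.
#' @export
merge_codes <- function(codes, taxonomy = load_taxonomy(),
                        domain = c("original", "target")) {
  domain <- match.arg(domain)
  valid_targets <- c(unname(taxonomy$target_labels), taxonomy$ignore_code)
  if (domain == "target") {
    bad <- setdiff(unique(as.vector(codes)), valid_targets)
    if (length(bad) > 0L) {
      stop("unknown target code(s): ", paste(bad, collapse = ", "))
    }
    return(codes)
  }
  lut <- integer(length(RPC_ORIGINAL_CLASSES) + 1L)
  lut[1L] <- 0L  # unannotated
  lut[taxonomy$original$code + 1L] <- taxonomy$original$target_code
  bad <- setdiff(unique(as.vector(codes)), 0:length(RPC_ORIGINAL_CLASSES))
  if (length(bad) > 0L) {
    stop("unknown original code(s): ", paste(bad, collapse = ", "))
  }
  out <- codes
  out[] <- lut[as.vector(codes) + 1L]
  out
}

#' Look up an original class code by name
#' @param name Class name from the original taxonomy.
#' @param taxonomy An `rpc_taxonomy`.
#' @return Integer original code.
#' @export
original_code <- function(name, taxonomy = load_taxonomy()) {
  i <- match(name, taxonomy$original$name)
  if (anyNA(i)) stop("unknown original class: ",
                     paste(name[is.na(i)], collapse = ", "))
  taxonomy$original$code[i]
}

#' @export
print.rpc_taxonomy <- function(x, ...) {
  cat("<rpc_taxonomy> 12 original classes -> 5 target classes + ignore\n")
  print(x$original)
  invisible(x)
}
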