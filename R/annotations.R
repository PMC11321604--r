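#' Read an ASAP-dialect annotation XML file
#'
#' Parses `Annotation` elements whose `PartOfGroup` attribute names an
#' original taxonomy class, each holding a `Coordinate` list in pixel units.
#'
#' @param path Path to the XML file.
#' @return A list of polygons; each has `label` (original class name) and
#'   `x`, `y` numeric vertex vectors (0-based pixel coordinates), in file
#'   order.
#' @export
read_asap_xml <- function(path) {
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  lapply(anns, function(a) {
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    ord <- order(as.integer(xml2::xml_attr(coords, "Order")))
    list(
      label = xml2::xml_attr(a, "PartOfGroup"),
      x = as.numeric(xml2::xml_attr(coords, "X"))[ord],
      y = as.numeric(xml2::xml_attr(coords, "Y"))[ord]
    )
  })
}

#' Write polygons as ASAP-dialect XML
#'
#' @param polygons List of polygons as returned by [read_asap_xml()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asap_xml <- function(polygons, path) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1L),
                             Type = "Polygon", PartOfGroup = p$label)
    cs <- xml2::xml_add_child(a, "Coordinates")
    for (j in seq_along(p$x)) {
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(j - 1L),
                          X = as.character(p$x[j]), Y = as.character(p$y[j]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Rasterize labeled polygons to a target-class mask
#'
#' Converts a set of polygons labeled with original taxonomy classes into an
#' `height` x `width` integer mask of merged target codes. Pixel membership
#' uses the pixel-center convention (pixel `(r, c)`, 0-based, is covered iff
#' its center `(c + 0.5, r + 0.5)` lies inside the polygon, even-odd rule).
#' Later polygons in file order overwrite earlier ones, with two
#' context-dependent rules:
#'
#' * Cancerous annotations (cancer, in-situ neoplasia) are drawn last, so
#'   cancer annotated within vessels or nerves remains cancer regardless of
#'   file order.
#' * A lumen takes the target class of its smallest enclosing annotated
#'   structure (containment tested at the lumen's centroid and first
#'   vertex), else background.
#'
#' Pixels covered by no polygon are background. Polygons extending beyond
#' the image are clipped with a warning.
#'
#' @param polygons List of polygons (`label`, `x`, `y`); labels must be
#'   original taxonomy class names.
#' @param height,width Mask dimensions in pixels.
#' @param taxonomy An `rpc_taxonomy`.
#' @return Integer matrix of target codes.
#' @export
rasterize_annotations <- function(polygons, height, width,
                                  taxonomy = load_taxonomy()) {
  if (length(polygons) == 0L) {
    return(matrix(0L, nrow = height, ncol = width))
  }
  labels <- vapply(polygons, `[[`, character(1), "label")
  unknown <- setdiff(unique(labels), taxonomy$original$name)
  if (length(unknown) > 0L) {
    stop("unknown annotation label(s): ", paste(unknown, collapse = ", "))
  }
  out_of_bounds <- vapply(polygons, function(p) {
    any(p$x < 0 | p$x > width | p$y < 0 | p$y > height)
  }, logical(1))
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " polygon(s) extend beyond the image and ",
            "were clipped to ", height, "x", width)
  }

  target_of <- stats::setNames(taxonomy$original$target_code,
                               taxonomy$original$name)
  is_lumen  <- labels == "lumina"
  is_cancer <- labels %in% c("cancer", "in_situ_neoplasia")

  resolve_value <- function(i) {
    p <- polygons[[i]]
    if (!is_lumen[i]) return(as.integer(target_of[[p$label]]))
    # smallest enclosing non-lumen structure, else background
    cx <- mean(p$x); cy <- mean(p$y)
    best_area <- Inf; best_value <- 0L
    for (j in seq_along(polygons)) {
      if (j == i || is_lumen[j]) next
      q <- polygons[[j]]
      if (cpp_point_in_poly(cx, cy, q$x, q$y) &&
          cpp_point_in_poly(p$x[1], p$y[1], q$x, q$y)) {
        area <- abs(cpp_poly_area(q$x, q$y))
        if (area < best_area) {
          best_area <- area
          best_value <- as.integer(target_of[[q$label]])
        }
      }
    }
    best_value
  }

  draw_order <- c(which(!is_cancer), which(is_cancer))
  polys <- lapply(draw_order, function(i) {
    list(x = polygons[[i]]$x, y = polygons[[i]]$y, value = resolve_value(i))
  })
  cpp_rasterize_polys(height, width, polys)
}
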