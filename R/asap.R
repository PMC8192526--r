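# I/O for the ASAP (Automated Slide Analysis Platform) XML annotation
# dialect: rectangles (4-corner polygons) grouped by annotation-class code.

#' Read ASAP XML annotations
#'
#' Parses an ASAP annotation document into a table of annotation targets. Each
#' `Annotation` element of type `Rectangle` (or a 4-point `Polygon` forming an
#' axis-aligned rectangle) becomes one target; the `PartOfGroup` attribute is
#' the annotation-class code and is resolved against the taxonomy.
#'
#' @param path Path to an ASAP XML file.
#' @param slide_id Slide identifier; defaults to the file name without
#'   extension.
#' @param taxonomy Taxonomy table from [load_taxonomy()].
#' @return data.frame with columns `slide_id, x, y, width, height,
#'   class_index`.
#' @export
read_asap_annotations <- function(path, slide_id = NULL,
                                  taxonomy = load_taxonomy()) {
  if (is.null(slide_id))
    slide_id <- tools::file_path_sans_ext(basename(path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed ASAP XML in ", path, ": ", conditionMessage(e)))
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  out <- data.frame(slide_id = character(), x = integer(), y = integer(),
                    width = integer(), height = integer(),
                    class_index = integer(), stringsAsFactors = FALSE)
  if (length(anns) == 0L) return(out)
  rows <- lapply(anns, function(a) {
    grp <- xml2::xml_attr(a, "PartOfGroup")
    cls <- annotation_index_of(grp, taxonomy)
    co <- xml2::xml_find_all(a, ".//Coordinate")
    xs <- as.numeric(xml2::xml_attr(co, "X"))
    ys <- as.numeric(xml2::xml_attr(co, "Y"))
    if (length(xs) < 2L || anyNA(xs) || anyNA(ys))
      stop("annotation '", xml2::xml_attr(a, "Name"),
           "' in ", path, " has no usable coordinates")
    data.frame(x = as.integer(min(xs)), y = as.integer(min(ys)),
               width = as.integer(max(xs) - min(xs)),
               height = as.integer(max(ys) - min(ys)),
               class_index = cls)
  })
  out <- do.call(rbind, rows)
  out <- cbind(slide_id = slide_id, out, stringsAsFactors = FALSE)
  out
}

#' Write annotation targets as ASAP XML
#'
#' Inverse of [read_asap_annotations()]: writes each target as a `Rectangle`
#' annotation whose four corner coordinates are `(x, y)`, `(x+width, y)`,
#' `(x+width, y+height)`, `(x, y+height)`, grouped under its annotation-class
#' code. `write` then `read` reproduces the targets exactly.
#'
#' @param targets data.frame with `x, y, width, height, class_index`.
#' @param path Output path.
#' @param taxonomy Taxonomy table.
#' @export
write_asap_annotations <- function(targets, path, taxonomy = load_taxonomy()) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  if (nrow(targets) > 0L) {
    codes <- taxonomy$code[match(targets$class_index, taxonomy$index)]
    if (anyNA(codes)) stop("class_index outside taxonomy")
    for (i in seq_len(nrow(targets))) {
      a <- xml2::xml_add_child(anns, "Annotation",
                               Name = sprintf("Annotation %d", i - 1L),
                               Type = "Rectangle", PartOfGroup = codes[i],
                               Color = "#F4FA58")
      cs <- xml2::xml_add_child(a, "Coordinates")
      xs <- c(targets$x[i], targets$x[i] + targets$width[i],
              targets$x[i] + targets$width[i], targets$x[i])
      ys <- c(targets$y[i], targets$y[i],
              targets$y[i] + targets$height[i],
              targets$y[i] + targets$height[i])
      for (k in 1:4)
        xml2::xml_add_child(cs, "Coordinate", Order = as.character(k - 1L),
                            X = as.character(xs[k]), Y = as.character(ys[k]))
    }
    groups <- xml2::xml_add_child(doc, "AnnotationGroups")
    for (g in unique(codes))
      xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None",
                          Color = "#64FE2E")
  } else {
    xml2::xml_add_child(doc, "AnnotationGroups")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
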