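# Annotation taxonomy: 24 cytological annotation classes, their TBS
# correspondences, detection-time merge groups and clinical groupings.

# canonical TBS reporting codes and their clinical groups
.tbs_groups <- c(
  NILM    = "negative",
  ASCUS   = "squamous-intraepithelial",
  LSIL    = "squamous-intraepithelial",
  ASCH    = "squamous-intraepithelial",
  HSIL    = "squamous-intraepithelial",
  SCC     = "squamous-intraepithelial",
  AGC     = "glandular-intraepithelial",
  AGC_NOS = "glandular-intraepithelial",
  AGC_FN  = "glandular-intraepithelial",
  AIS     = "glandular-intraepithelial",
  ADC     = "glandular-intraepithelial",
  EMC     = "EMC",
  TRI     = "infectious",
  CAN     = "infectious",
  HSV     = "infectious",
  ACTINO  = "infectious",
  CC      = "infectious"
)

.taxonomy_categories <- c(
  "glandular-intraepithelial", "squamous-intraepithelial", "normal",
  "infectious", "evidence-of-infection", "EMC"
)

# AGC_FN, AIS and ADC are too rare to predict separately; they collapse into
# one merged AGC prediction class at decision time.
.agc_merged <- c("AGC_NOS", "AGC_FN", "AIS", "ADC")

.taxonomy_env <- new.env(parent = emptyenv())

#' Load the annotation-class taxonomy table
#'
#' Returns the authoritative table of the 24 cytological annotation classes
#' used throughout the package: class index (1-24), short code (`AGC_A` ...
#' `Debris`), lesion category, the set of TBS diagnoses each class can
#' indicate (pipe-separated in the `tbs_targets` column), and the
#' detection-time class each annotation class is merged into (`excluded` for
#' classes the detector does not learn: GEC, MC, RC, Neutrophils, Mucus,
#' Debris).
#'
#' @param path Optional path to an alternative taxonomy CSV with the same
#'   header (`index,code,category,tbs_targets,detection_class`). Defaults to
#'   the table shipped with the package.
#' @return A `data.frame` with one row per annotation class, ordered by
#'   `index`.
#' @export
#' @examples
#' tax <- load_taxonomy()
#' tax[tax$code == "KC", ]
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.taxonomy_env$default)) return(.taxonomy_env$default)
    path <- system.file("extdata", "taxonomy.csv", package = "tbscreen")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_taxonomy(tab)
  tab <- tab[order(tab$index), , drop = FALSE]
  rownames(tab) <- NULL
  if (path == system.file("extdata", "taxonomy.csv", package = "tbscreen"))
    .taxonomy_env$default <- tab
  tab
}

validate_taxonomy <- function(tab) {
  need <- c("index", "code", "category", "tbs_targets", "detection_class")
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 24L || !setequal(tab$index, 1:24))
    stop("taxonomy must have exactly 24 classes with indices 1..24")
  if (anyDuplicated(tab$code))
    stop("taxonomy codes must be unique")
  if (!all(tab$category %in% .taxonomy_categories))
    stop("unknown taxonomy category: ",
         paste(setdiff(tab$category, .taxonomy_categories), collapse = ", "))
  targets <- strsplit(tab$tbs_targets, "|", fixed = TRUE)
  if (any(lengths(targets) == 0L))
    stop("every annotation class needs at least one TBS target")
  bad <- setdiff(toupper(unlist(targets)), names(.tbs_groups))
  if (length(bad))
    stop("unknown TBS codes in taxonomy: ", paste(bad, collapse = ", "))
  invisible(tab)
}

#' List the TBS reporting codes and their clinical groups
#'
#' @return A `data.frame` with columns `code` and `clinical_group`. Groups are
#'   `negative`, `squamous-intraepithelial`, `glandular-intraepithelial`,
#'   `infectious` and `EMC`.
#' @export
tbs_classes <- function() {
  data.frame(code = names(.tbs_groups), clinical_group = unname(.tbs_groups),
             stringsAsFactors = FALSE)
}

.check_class_index <- function(class_index) {
  if (length(class_index) != 1L || !is.finite(class_index) ||
      class_index != as.integer(class_index) ||
      class_index < 1L || class_index > 24L)
    stop("invalid annotation class index: ", class_index,
         " (must be an integer in 1..24)")
  as.integer(class_index)
}

#' Map an annotation class to its TBS diagnoses
#'
#' Each of the 24 annotation classes corresponds to one or more TBS reporting
#' classes; e.g. a single koilocyte (KC, class 4) indicates LSIL, while
#' superficial squamous epithelium (MC, class 11) indicates NILM.
#'
#' @param class_index Integer in 1..24.
#' @param taxonomy Taxonomy table from [load_taxonomy()].
#' @return Character vector of TBS codes, always non-empty.
#' @export
#' @examples
#' map_annotation_to_tbs(4)   # "LSIL"
#' map_annotation_to_tbs(16)  # "TRI"
map_annotation_to_tbs <- function(class_index, taxonomy = load_taxonomy()) {
  i <- .check_class_index(class_index)
  toupper(strsplit(taxonomy$tbs_targets[taxonomy$index == i], "|",
                   fixed = TRUE)[[1]])
}

#' Detection-time class of an annotation class
#'
#' The detector is trained on a reduced label space: morphologically similar
#' annotation classes are merged (AGC_A/AGC_B; KC/ASC_L_F; the five
#' high-N:C-ratio and carcinoma classes C6-C10) and six classes carrying no
#' lesion signal (GEC, MC, RC, Neutrophils, Mucus, Debris) are excluded.
#'
#' @inheritParams map_annotation_to_tbs
#' @return The detection-class code (character), or `"excluded"`.
#' @export
#' @examples
#' detection_class_of(14)  # "excluded" (GEC)
#' detection_class_of(6) == detection_class_of(10)
detection_class_of <- function(class_index, taxonomy = load_taxonomy()) {
  i <- .check_class_index(class_index)
  taxonomy$detection_class[taxonomy$index == i]
}

#' Detection class labels in canonical order
#'
#' @inheritParams map_annotation_to_tbs
#' @return Character vector of the distinct detection classes (default 12),
#'   ordered by the lowest annotation index they contain; excludes
#'   `"excluded"`.
#' @export
detection_classes <- function(taxonomy = load_taxonomy()) {
  dc <- taxonomy$detection_class[order(taxonomy$index)]
  unique(dc[dc != "excluded"])
}

#' Clinical group of a TBS code
#'
#' Groups follow clinical treatment: LSIL, ASCH, HSIL and SCC (and ASCUS, the
#' undetermined reporting class) form the squamous-intraepithelial group; the
#' AGC family is glandular-intraepithelial; TRI/CAN/HSV/ACTINO/CC are
#' infectious; EMC and NILM stand alone.
#'
#' @param tbs TBS code (case-insensitive). Vectorised.
#' @return Character vector of clinical groups.
#' @export
#' @examples
#' clinical_group_of(c("SCC", "NILM", "CAN"))
clinical_group_of <- function(tbs) {
  code <- toupper(as.character(tbs))
  code[code == "NIL"] <- "NILM"
  unknown <- setdiff(unique(code), names(.tbs_groups))
  if (length(unknown))
    stop("unknown TBS code(s): ", paste(unknown, collapse = ", "))
  unname(.tbs_groups[code])
}

#' Collapse rare glandular diagnoses into the merged AGC class
#'
#' AGC_NOS, AGC_FN, AIS and ADC are combined into a single `AGC` prediction
#' class; all other codes pass through unchanged.
#'
#' @param tbs TBS code(s), case-insensitive.
#' @return Character vector of canonical codes with the AGC family merged.
#' @export
merge_agc <- function(tbs) {
  code <- toupper(as.character(tbs))
  code[code == "NIL"] <- "NILM"
  code[code %in% .agc_merged] <- "AGC"
  code
}

#' Annotation class index for a code
#'
#' @param code Annotation class code such as `"KC"` (case-insensitive).
#' @inheritParams map_annotation_to_tbs
#' @return Integer index in 1..24. Errors on unknown codes.
#' @export
annotation_index_of <- function(code, taxonomy = load_taxonomy()) {
  i <- match(toupper(as.character(code)), toupper(taxonomy$code))
  if (anyNA(i))
    stop("unknown annotation class code(s): ",
         paste(code[is.na(i)], collapse = ", "))
  taxonomy$index[i]
}
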