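#' Feature schema for morphometric tables
#'
#' A `feature_schema` is an ordered, named layout of feature columns,
#' organised in contiguous blocks (cortical thickness/area/curvature/volume,
#' subcortical volumes, hippocampal-subfield volumes, one global measure).
#' The default schema ([default_schema()]) enumerates the 317-feature
#' FreeSurfer-derived layout used throughout the package.
#'
#' @param blocks named list of character vectors; block order defines
#'   column order.
#' @return An object of class `feature_schema` with elements `names`
#'   (ordered feature identifiers) and `blocks` (named list of contiguous
#'   name sublists).
#' @export
feature_schema <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) > 0L, !is.null(names(blocks)))
  nms <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(nms)) {
    stop("duplicate feature names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (any(!nzchar(nms))) stop("empty feature name in schema")
  structure(list(names = nms, blocks = blocks), class = "feature_schema")
}

# Desikan-Killiany cortical parcellation: 34 regions per hemisphere.
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

# FreeSurfer v7 hippocampal subdivision; CA2 and CA3 are segmented as one
# combined CA2/3 label.
hippo_subfields <- function() {
  c("hippocampal_tail", "subiculum", "presubiculum", "parasubiculum",
    "CA1", "CA2/3", "CA4", "GC_ML_DG", "molecular_layer", "fimbria",
    "HATA", "hippocampal_fissure")
}

# Subcortical (aseg) structures kept in the default layout, 10 per
# hemisphere. "accumbens_area" is FreeSurfer's label for the nucleus
# accumbens; its entries carry no extra _volume suffix.
aseg_structures <- function() {
  c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
    "amygdala", "accumbens_area", "cerebellum_cortex",
    "cerebellum_white_matter", "lateral_ventricle")
}

#' The canonical 317-feature morphometric schema
#'
#' Enumerates the default feature layout: 34 Desikan-Killiany cortical
#' regions x 2 hemispheres x 4 measures (thickness, area, mean curvature,
#' volume) = 272 cortical entries; 12 hippocampal subfields x 2 hemispheres
#' = 24 subfield volumes; 10 subcortical (aseg) structures x 2 hemispheres
#' = 20 volumes; and the estimated total intracranial volume, for 317
#' features in total. Naming follows the lowercase underscore convention,
#' e.g. `left_temporalpole_meancurv`, `right_hipposubfields_subiculum_volume`,
#' `left_accumbens_area`, `estimated_totalintracranial_volume`.
#'
#' @return A [feature_schema] with blocks `cortical_thickness`,
#'   `cortical_area`, `cortical_meancurv`, `cortical_volume`,
#'   `hippo_subfield_volume`, `aseg_volume` and `global`.
#' @examples
#' sch <- default_schema()
#' length(sch$names)           # 317
#' lengths(sch$blocks)
#' @export
default_schema <- function() {
  hemis <- c("left", "right")
  cort <- function(measure) {
    as.vector(t(outer(hemis, dk_regions(),
                      function(h, r) paste(h, r, measure, sep = "_"))))
  }
  hippo <- as.vector(t(outer(hemis, hippo_subfields(), function(h, s)
    paste0(h, "_hipposubfields_", s, "_volume"))))
  aseg <- as.vector(t(outer(hemis, aseg_structures(), function(h, s)
    ifelse(s == "accumbens_area", paste(h, s, sep = "_"),
           paste(h, s, "volume", sep = "_")))))
  feature_schema(list(
    cortical_thickness    = cort("thickness"),
    cortical_area         = cort("area"),
    cortical_meancurv     = cort("meancurv"),
    cortical_volume       = cort("volume"),
    hippo_subfield_volume = hippo,
    aseg_volume           = aseg,
    global                = "estimated_totalintracranial_volume"
  ))
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", length(x$names), " features in ",
      length(x$blocks), " blocks\n", sep = "")
  for (b in names(x$blocks)) {
    cat(sprintf("  %-22s %3d  (%s, ...)\n", b, length(x$blocks[[b]]),
                x$blocks[[b]][1L]))
  }
  invisible(x)
}

#' Export a schema as JSON
#'
#' Writes the ordered name list and block map, so a layout can be audited
#' or consumed outside R.
#'
#' @param schema a [feature_schema].
#' @param path output file path.
#' @export
schema_to_json <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(list(names = schema$names, blocks = schema$blocks),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
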