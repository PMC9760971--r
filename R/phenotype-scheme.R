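#' Phenotype scheme for the tumor-core classification
#'
#' The pipeline classifies every segmented cell into one of ten phenotypes:
#' tumor cells, stromal cells, and eight named immune classes plus an
#' unclassified-immune catch-all. Broad classes collapse the scheme to
#' Tumor / Stroma / Immune for the first classification tier.
#'
#' @return `phenotype_levels()` returns the character vector of all eleven
#'   fine phenotype labels (including `"UnclassifiedImmune"`);
#'   `immune_levels()` the nine immune labels; `broad_levels()` the three
#'   broad labels.
#' @examples
#' phenotype_levels()
#' broad_class_of(c("BCell", "Tumor", "Macrophage"))
#' @export
phenotype_levels <- function() {
  c("Tumor", "Stroma", immune_levels())
}

#' @rdname phenotype_levels
#' @export
immune_levels <- function() {
  c("BCell", "CytotoxicT", "HelperT", "Treg", "Neutrophil",
    "Monocyte", "Macrophage", "Dendritic", "UnclassifiedImmune")
}

#' @rdname phenotype_levels
#' @export
broad_levels <- function() {
  c("Tumor", "Stroma", "Immune")
}

#' Collapse fine phenotypes to broad classes
#'
#' Maps each fine phenotype to Tumor, Stroma or Immune. Labels outside the
#' scheme (including `"UNASSIGNED"`) map to `NA`.
#'
#' @param phenotype character vector of fine phenotype labels.
#' @return character vector of broad labels, same length.
#' @export
broad_class_of <- function(phenotype) {
  out <- rep(NA_character_, length(phenotype))
  out[phenotype %in% c("Tumor", "Stroma")] <- phenotype[phenotype %in% c("Tumor", "Stroma")]
  out[phenotype %in% immune_levels()] <- "Immune"
  out
}

# Sentinel used for cells whose phenotype is unknown or unrecognized.
UNASSIGNED <- "UNASSIGNED"

# Normalize a phenotype column: anything outside the scheme becomes
# UNASSIGNED so that classification can be (re)run inside the pipeline.
normalize_phenotype <- function(phenotype) {
  phenotype <- as.character(phenotype)
  phenotype[is.na(phenotype) | !(phenotype %in% phenotype_levels())] <- UNASSIGNED
  phenotype
}
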