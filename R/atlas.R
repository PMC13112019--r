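# Packaged region lookup table.

#' Load the 116-region anatomical atlas table
#'
#' Returns the packaged AAL-style parcellation lookup: 116 regions split
#' into 78 cortical, 12 subcortical and 26 cerebellar labels, each with a
#' lobe and a coarse canonical functional-network assignment. The table is
#' bookkeeping for reports and degree tables; it carries no coordinates.
#'
#' @param path optional path to an alternative atlas CSV with columns
#'   `region_id`, `name`, `lobe`, `class`, `canonical_network`.
#' @return data.frame with one row per region, ordered by `region_id`.
#' @examples
#' atlas <- load_atlas()
#' table(atlas$class)
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal116_atlas.csv", package = "connectopipe",
                        mustWork = TRUE)
  }
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("region_id", "name", "lobe", "class", "canonical_network")
  missing <- setdiff(required, names(atlas))
  if (length(missing)) {
    stop("atlas table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atlas$region_id)) stop("atlas region_id values must be unique")
  atlas[order(atlas$region_id), , drop = FALSE]
}
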