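#' Load the packaged subregion atlas
#'
#' Returns the 38-entry hippocampal subfield scheme (FreeSurfer-style
#' head/body subsegmentation labels, both hemispheres) and the 91-entry
#' default-network parcel scheme with an anatomical grouping
#' (temporal / PFC / parietal / PCC-RSC) for every parcel.
#'
#' The DN parcel list and its lobe groupings are a documented
#' reconstruction: the reference parcellation provides 91 default-network
#' parcels, but no public table ties each parcel to the four-way grouping
#' used for hit tallies, so the packaged mapping assigns parcels to
#' groupings by parcel-name subtype and is editable by replacing the
#' extdata tables.
#'
#' @return An \linkS4class{AtlasSpec}.
#' @examples
#' atlas <- loadAtlas()
#' nrow(atlas@hc)  # 38
#' nrow(atlas@dn)  # 91
#' @export
loadAtlas <- function() {
  hcPath <- system.file("extdata", "atlas_hc.tsv", package = "codecomp",
                        mustWork = TRUE)
  dnPath <- system.file("extdata", "atlas_dn.tsv", package = "codecomp",
                        mustWork = TRUE)
  hc <- utils::read.delim(hcPath, stringsAsFactors = FALSE)
  dn <- utils::read.delim(dnPath, stringsAsFactors = FALSE)
  if (!identical(sort(names(hc)), sort(c("name", "hemisphere", "subfield",
                                         "division"))) ||
      nrow(hc) != 38L || anyDuplicated(hc$name))
    stop("corrupted atlas file: ", hcPath)
  if (!identical(sort(names(dn)), sort(c("name", "hemisphere", "subtype",
                                         "grouping"))) ||
      nrow(dn) != 91L || anyDuplicated(dn$name))
    stop("corrupted atlas file: ", dnPath)
  hc$grouping <- hc$subfield
  new("AtlasSpec", hc = hc, dn = dn,
      hcVersion = "fs7-subfields-r1",
      dnVersion = "schaefer400x7-default-reconstruction-r1")
}

setMethod("show", "AtlasSpec", function(object) {
  cat("AtlasSpec:", nrow(object@hc), "HC subfields (", object@hcVersion,
      "),", nrow(object@dn), "DN parcels (", object@dnVersion, ")\n")
  cat("DN groupings:",
      paste(sprintf("%s=%d", names(table(object@dn$grouping)),
                    table(object@dn$grouping)), collapse = ", "), "\n")
})
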