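#' @rdname dosage
#' @export
setMethod("dosage", "CloneCohort", function(x) assay(x, "dosage"))

#' @rdname cloneAssignments
#' @export
setMethod("cloneAssignments", "CloneCohort", function(x) {
  setNames(as.character(colData(x)$clone_id), colnames(x))
})

#' @rdname siteKeys
#' @export
setMethod("siteKeys", "CloneCohort", function(x) {
  rd <- rowData(x)
  siteKey(as.character(seqnames(x)),
          GenomicRanges::start(rowRanges(x)), rd$ref, rd$alt)
})

#' @rdname cloneNames
#' @export
setMethod("cloneNames", "CloneCohort", function(x) {
  unique(as.character(colData(x)$clone_id))
})

setMethod("show", "CloneCohort", function(object) {
  callNextMethod()
  cl <- cloneAssignments(object)
  cat("clones(", length(unique(cl)), "):",
      paste(sprintf("%s(%d)", unique(cl), tabulate(factor(cl, unique(cl)))),
            collapse = " "), "\n")
})

#' @rdname consistentSites
#' @export
setMethod("consistentSites", "CloneVariantSets", function(x, ...) x@consistent)

#' @rdname exclusiveSites
#' @export
setMethod("exclusiveSites", "CloneVariantSets", function(x, ...) x@exclusive)

#' @rdname cloneNames
#' @export
setMethod("cloneNames", "CloneVariantSets", function(x) names(x@exclusive))

setMethod("show", "CloneVariantSets", function(object) {
  cat("CloneVariantSets over", length(object@exclusive), "clones\n")
  for (cl in names(object@exclusive)) {
    cat(sprintf("  %s: %d consistent, %d exclusive\n", cl,
                length(object@consistent[[cl]]),
                length(object@exclusive[[cl]])))
  }
})

#' @rdname markers
#' @export
setMethod("markers", "MarkerPanel", function(x) x@markers)

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat("MarkerPanel with", nrow(m), "markers (",
      sum(m$variant_type == "SNV"), "SNV /",
      sum(m$variant_type == "InDel"), "InDel ) across",
      length(unique(m$clone_id)), "clones\n")
  if (nrow(m)) {
    print(utils::head(m[, c("cultivar", "clone_id", "marker_id",
                            "variant_type", "contig", "position")], 5L))
    if (nrow(m) > 5L) cat("  ...", nrow(m) - 5L, "more\n")
  }
})

#' Number of markers in a panel
#' @param x a [MarkerPanel-class].
#' @export
setMethod("length", "MarkerPanel", function(x) nrow(x@markers))
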