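#' Alternate-allele dosage matrix
#'
#' @param x a [CloneCohort-class].
#' @return integer matrix, sites x samples, values 0/1/2 or `NA` (missing).
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Sample-to-clone assignments
#'
#' @param x a [CloneCohort-class].
#' @return named character vector mapping sample names to clone identifiers.
#' @export
setGeneric("cloneAssignments", function(x) standardGeneric("cloneAssignments"))

#' Site keys of a cohort
#'
#' @param x a [CloneCohort-class].
#' @return character vector `"contig:pos:REF>ALT"`, one per row.
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' Clones represented in an object
#'
#' @param x a [CloneCohort-class], [CohortDesign-class] or
#'   [CloneVariantSets-class].
#' @return character vector of clone identifiers.
#' @export
setGeneric("cloneNames", function(x) standardGeneric("cloneNames"))

#' Replicate-consistent site sets
#'
#' @param x a [CloneCohort-class] (or [CloneVariantSets-class] accessor).
#' @param ... further arguments for methods.
#' @return named list of character site-key sets, one per clone.
#' @export
setGeneric("consistentSites", function(x, ...) standardGeneric("consistentSites"))

#' Clone-exclusive site sets
#'
#' @param x a [CloneVariantSets-class].
#' @param ... further arguments for methods.
#' @return named list of character site-key sets, one per clone.
#' @export
setGeneric("exclusiveSites", function(x, ...) standardGeneric("exclusiveSites"))

#' Marker table of a panel
#'
#' @param x a [MarkerPanel-class].
#' @return the underlying marker `data.frame`.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
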