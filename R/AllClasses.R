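#' Design of a simulated clonal cohort
#'
#' A `CohortDesign` bundles the clone/replicate structure of a cohort of
#' vegetatively propagated lineages together with every parameter of the
#' synthetic-data generator: the background heterozygosity shared by all
#' clones, the per-clone burden of planted clone-exclusive variants, the
#' SNV/InDel mixture, the transition/transversion ratio, the heterozygous
#' fraction of clone-specific variants, and the per-replicate call-noise
#' model (dropouts, false positives, QUAL score distributions).
#'
#' Defaults follow what deep resequencing of grapevine clonal selections
#' typically shows: ~5 background heterozygous variants per kbp, Ts/Tv 2.1,
#' ~26% of variants being InDels, and 94% of clone-specific variants
#' heterozygous.
#'
#' @slot clones character vector of unique clone identifiers.
#' @slot replicatesPerClone named integer, replicates per clone (>= 1; a
#'   single-replicate clone is legal).
#' @slot genomeLength total reference length in bp (>= 1000).
#' @slot nContigs number of contigs the reference is split into.
#' @slot backgroundHetRate background heterozygous variants per bp, shared by
#'   every sample.
#' @slot cloneSpecificCount named integer, planted exclusive variants per
#'   clone.
#' @slot indelFraction proportion of planted variants that are InDels.
#' @slot indelSizeRange integer length-2, min/max InDel size in bp.
#' @slot tstvRatio target transition/transversion ratio for simulated SNVs.
#' @slot hetFractionSpecific proportion of clone-specific variants planted
#'   heterozygous (the rest are homozygous-alternate).
#' @slot dropoutRate per-replicate probability that a truly present variant
#'   is not called (genotype recorded missing).
#' @slot falsePositiveRate per-site, per-replicate probability of a spurious
#'   singleton call.
#' @slot qualModel list with `trueMean`, `trueSd`, `falseMean`, `falseSd`:
#'   normal QUAL distributions for true and false calls. False calls sit
#'   mostly below 100 so the conventional Q > 100 site filter removes them.
#' @slot seed integer; all randomness flows from this one seed.
#'
#' @seealso [CohortDesign()] for the user-facing constructor,
#'   [plantCohort()], [simulateCalls()].
#' @export
setClass("CohortDesign", representation(
  clones = "character",
  replicatesPerClone = "integer",
  genomeLength = "numeric",
  nContigs = "integer",
  backgroundHetRate = "numeric",
  cloneSpecificCount = "integer",
  indelFraction = "numeric",
  indelSizeRange = "integer",
  tstvRatio = "numeric",
  hetFractionSpecific = "numeric",
  dropoutRate = "numeric",
  falsePositiveRate = "numeric",
  qualModel = "list",
  seed = "integer"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (length(object@clones) < 1L) {
    msg <- c(msg, "at least one clone is required")
  }
  if (anyDuplicated(object@clones)) {
    msg <- c(msg, "clone identifiers must be unique")
  }
  if (!setequal(names(object@replicatesPerClone), object@clones)) {
    msg <- c(msg, "replicatesPerClone must be named by the clones")
  }
  if (any(object@replicatesPerClone < 1L)) {
    msg <- c(msg, "every clone needs >= 1 replicate")
  }
  if (!setequal(names(object@cloneSpecificCount), object@clones)) {
    msg <- c(msg, "cloneSpecificCount must be named by the clones")
  }
  if (any(object@cloneSpecificCount < 0L)) {
    msg <- c(msg, "cloneSpecificCount must be non-negative")
  }
  if (object@genomeLength < 1000) {
    msg <- c(msg, "genomeLength must be >= 1000 bp")
  }
  if (object@nContigs < 1L) {
    msg <- c(msg, "nContigs must be positive")
  }
  rates <- c(
    backgroundHetRate = object@backgroundHetRate,
    indelFraction = object@indelFraction,
    hetFractionSpecific = object@hetFractionSpecific,
    dropoutRate = object@dropoutRate,
    falsePositiveRate = object@falsePositiveRate
  )
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    msg <- c(msg, paste0(
      "rates/proportions must lie in [0,1]: ",
      paste(names(rates)[bad], collapse = ", ")
    ))
  }
  if (length(object@indelSizeRange) != 2L ||
      any(object@indelSizeRange < 1L) ||
      object@indelSizeRange[1L] > object@indelSizeRange[2L]) {
    msg <- c(msg, "indelSizeRange must be an increasing pair of sizes >= 1")
  }
  if (object@tstvRatio <= 0) {
    msg <- c(msg, "tstvRatio must be positive")
  }
  need <- c("trueMean", "trueSd", "falseMean", "falseSd")
  if (!all(need %in% names(object@qualModel))) {
    msg <- c(msg, paste0("qualModel must contain ",
                         paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Genotype matrix of a clonal cohort
#'
#' `CloneCohort` extends [SummarizedExperiment::RangedSummarizedExperiment]:
#' rows are variant sites (ranges carry the REF footprint; `rowData` holds
#' `ref`, `alt`, `qual`), columns are samples (biological replicates), and
#' the single assay `"dosage"` holds the alternate-allele dosage 0/1/2 with
#' `NA` for missing calls. `colData` maps every sample to its clone
#' (`clone_id`) and optionally cultivar.
#'
#' @seealso [buildMatrix()], [dosage()], [cloneAssignments()],
#'   [replicateConsistent()], [cloneExclusive()].
#' @export
setClass("CloneCohort", contains = "RangedSummarizedExperiment")

setValidity("CloneCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'dosage' is required")
  }
  cd <- colData(object)
  if (!"clone_id" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'clone_id'")
  } else if (any(is.na(cd$clone_id))) {
    msg <- c(msg, "every sample must map to a clone")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample names must be unique")
  }
  rd <- rowData(object)
  if (!all(c("ref", "alt") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'ref' and 'alt'")
  } else {
    keys <- siteKey(as.character(seqnames(object)),
                    GenomicRanges::start(rowRanges(object)), rd$ref, rd$alt)
    if (anyDuplicated(keys)) {
      msg <- c(msg, "site keys (contig,pos,ref,alt) must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Replicate-consistent and clone-exclusive variant sets
#'
#' Holds, per clone, the set of sites called in every one of its replicates
#' (`consistent`) and the subset of those additionally absent from every
#' sample of every other clone (`exclusive`) — the clone-specific variants
#' that can become diagnostic markers. Exclusive sets are pairwise disjoint
#' by construction.
#'
#' @slot consistent named list of character site keys per clone.
#' @slot exclusive named list of character site keys per clone.
#' @seealso [cloneExclusive()], [replicateConsistent()].
#' @export
setClass("CloneVariantSets", representation(
  consistent = "list",
  exclusive = "list"
))

setValidity("CloneVariantSets", function(object) {
  msg <- character()
  if (!identical(names(object@consistent), names(object@exclusive))) {
    msg <- c(msg, "consistent and exclusive must cover the same clones")
  }
  for (cl in names(object@exclusive)) {
    if (!all(object@exclusive[[cl]] %in% object@consistent[[cl]])) {
      msg <- c(msg, sprintf("exclusive['%s'] must be a subset of consistent", cl))
    }
  }
  ex <- unlist(object@exclusive, use.names = FALSE)
  if (anyDuplicated(ex)) {
    msg <- c(msg, "exclusive sets must be pairwise disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' A panel of clone-diagnostic amplicon markers
#'
#' Wraps a marker table in the six-column schema used for validated clonal
#' markers (cultivar, clone, marker id, variant type with SNV alleles,
#' contig/position, amplicon allele length(s)), optionally augmented with
#' the amplicon window and allele sequences when markers were selected from
#' a reference. SNV markers carry one amplicon length, InDel markers two
#' distinct lengths; every validated marker is heterozygous in its clone.
#'
#' @slot markers data.frame with columns `cultivar`, `clone_id`,
#'   `marker_id`, `variant_type` ("SNV"/"InDel"), `allele_a`, `allele_b`
#'   (SNV bases, NA for InDel), `contig`, `position`, `length_a`,
#'   `length_b` (NA for SNV), and optionally `amp_start`, `amp_end`,
#'   `seq_a`, `seq_b`, `qual`.
#' @seealso [selectCandidates()], [loadMarkerTable()], [summarizePanel()].
#' @export
setClass("MarkerPanel", representation(markers = "data.frame"))

setValidity("MarkerPanel", function(object) {
  m <- object@markers
  need <- c("cultivar", "clone_id", "marker_id", "variant_type",
            "allele_a", "allele_b", "contig", "position",
            "length_a", "length_b")
  miss <- setdiff(need, colnames(m))
  if (length(miss)) {
    return(paste0("missing marker columns: ", paste(miss, collapse = ", ")))
  }
  msg <- character()
  if (anyDuplicated(m$marker_id)) {
    msg <- c(msg, "marker_id must be unique")
  }
  if (!all(m$variant_type %in% c("SNV", "InDel"))) {
    msg <- c(msg, "variant_type must be 'SNV' or 'InDel'")
  }
  snv <- m$variant_type == "SNV"
  if (any(snv & !is.na(m$length_b))) {
    msg <- c(msg, "SNV markers must have a single amplicon length")
  }
  indel <- m$variant_type == "InDel"
  if (any(indel & (is.na(m$length_b) | m$length_a == m$length_b))) {
    msg <- c(msg, "InDel markers need two distinct allele lengths")
  }
  if (length(msg)) msg else TRUE
})
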