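#' Construct a cohort design
#'
#' User-facing constructor for [CohortDesign-class]. Scalar `replicates` or
#' `cloneSpecific` values are recycled across clones; named vectors assign
#' per-clone values (a mixed design such as the 1--3 replicates per clone of
#' a real clonal survey is expressed this way).
#'
#' @param clones character vector of unique clone identifiers.
#' @param replicates integer scalar or named vector, replicates per clone.
#' @param genomeLength total reference length in bp.
#' @param nContigs number of contigs.
#' @param backgroundHetRate background heterozygous variants per bp (default
#'   0.005, i.e. ~5/kbp as observed for grapevine cultivars).
#' @param cloneSpecific integer scalar or named vector, planted exclusive
#'   variants per clone.
#' @param indelFraction proportion of planted variants that are InDels
#'   (default 0.26).
#' @param indelSizeRange length-2 integer, InDel sizes in bp.
#' @param tstvRatio target transition/transversion ratio (default 2.1).
#' @param hetFractionSpecific heterozygous proportion of clone-specific
#'   variants (default 0.94).
#' @param dropoutRate per-replicate missed-call probability (default 0.05).
#' @param falsePositiveRate per-site per-replicate spurious-call probability
#'   (default 1e-5).
#' @param qualModel list(trueMean, trueSd, falseMean, falseSd) for QUAL
#'   simulation; false calls centred well below 100.
#' @param seed integer master seed; every downstream draw derives from it.
#' @return a validated [CohortDesign-class] object.
#' @examples
#' d <- CohortDesign(c("A", "B"), replicates = 2, genomeLength = 50000,
#'                   cloneSpecific = 10, seed = 1)
#' cloneNames(d)
#' @export
CohortDesign <- function(clones,
                         replicates = 3L,
                         genomeLength = 1e6,
                         nContigs = 1L,
                         backgroundHetRate = 0.005,
                         cloneSpecific = 100L,
                         indelFraction = 0.26,
                         indelSizeRange = c(1L, 10L),
                         tstvRatio = 2.1,
                         hetFractionSpecific = 0.94,
                         dropoutRate = 0.05,
                         falsePositiveRate = 1e-5,
                         qualModel = list(trueMean = 800, trueSd = 150,
                                          falseMean = 60, falseSd = 30),
                         seed = 1L) {
  expand <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- rep(x, length(clones))
      if (length(x) != length(clones)) {
        invalidDesign(sprintf("%s must be scalar or one value per clone", what))
      }
      names(x) <- clones
    } else if (!setequal(names(x), clones)) {
      invalidDesign(sprintf("names of %s must match the clones", what))
    }
    setNames(as.integer(x[clones]), clones)
  }
  obj <- tryCatch(new("CohortDesign",
    clones = as.character(clones),
    replicatesPerClone = expand(replicates, "replicates"),
    genomeLength = as.numeric(genomeLength),
    nContigs = as.integer(nContigs),
    backgroundHetRate = backgroundHetRate,
    cloneSpecificCount = expand(cloneSpecific, "cloneSpecific"),
    indelFraction = indelFraction,
    indelSizeRange = as.integer(indelSizeRange),
    tstvRatio = tstvRatio,
    hetFractionSpecific = hetFractionSpecific,
    dropoutRate = dropoutRate,
    falsePositiveRate = falsePositiveRate,
    qualModel = qualModel,
    seed = as.integer(seed)
  ), error = function(e) invalidDesign(conditionMessage(e)))
  obj
}

#' Sample names implied by a design
#'
#' Replicates are named `<clone>_r<i>`; the order (clones in design order,
#' replicates within clone) is the column order used throughout.
#'
#' @param design a [CohortDesign-class].
#' @return data.frame with `sample_id` and `clone_id`.
#' @export
designSamples <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  cl <- rep(design@clones, design@replicatesPerClone[design@clones])
  idx <- unlist(lapply(design@replicatesPerClone[design@clones], seq_len),
                use.names = FALSE)
  data.frame(sample_id = sprintf("%s_r%d", cl, idx), clone_id = cl,
             stringsAsFactors = FALSE)
}

#' @rdname cloneNames
#' @export
setMethod("cloneNames", "CohortDesign", function(x) x@clones)

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign with", length(object@clones), "clones,",
      sum(object@replicatesPerClone), "replicates\n")
  cat("  genome:", format(object@genomeLength, big.mark = ","), "bp in",
      object@nContigs, "contig(s)\n")
  cat("  background het rate:", object@backgroundHetRate, "/bp;",
      "clone-specific:", paste0(object@clones, "=",
                                object@cloneSpecificCount[object@clones],
                                collapse = " "), "\n")
  cat("  indel fraction:", object@indelFraction,
      " Ts/Tv:", object@tstvRatio,
      " het(specific):", object@hetFractionSpecific, "\n")
  cat("  noise: dropout", object@dropoutRate,
      " FP", object@falsePositiveRate,
      " seed", object@seed, "\n")
})
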