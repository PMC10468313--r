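## The core inference: which variants are concordant across a clone's
## biological replicates, and which of those are exclusive to the clone --
## the somatic variants that separate lineages of one cultivar.

#' Replicate-consistent variant sets per clone
#'
#' A site belongs to a clone's consistent set iff every replicate of that
#' clone carries the alternate allele (dosage >= 1); a missing call counts
#' as not-present. A single-replicate clone's consistent set is simply its
#' own presence set.
#'
#' @param cohort a [CloneCohort-class].
#' @return named list of character site-key sets, one per clone.
#' @export
replicateConsistent <- function(cohort) {
  stopifnot(is(cohort, "CloneCohort"))
  cl <- cloneAssignments(cohort)
  if (any(is.na(cl)) || length(cl) == 0L) {
    invalidDesign("every sample must map to a clone")
  }
  m <- dosage(cohort)
  keys <- siteKeys(cohort)
  present <- !is.na(m) & m >= 1L
  out <- lapply(unique(cl), function(cc) {
    cols <- which(cl == cc)
    if (length(cols) == 0L) invalidDesign(paste0("clone without samples: ", cc))
    keys[rowSums(present[, cols, drop = FALSE]) == length(cols)]
  })
  names(out) <- unique(cl)
  out
}

#' Clone-exclusive variant sets
#'
#' Extracts, for every clone, the variants present in all of its replicates
#' and absent from every sample of every other clone -- the clone-specific
#' somatic variants. Under the default (joint-genotyping) interpretation a
#' missing call in a non-focal sample counts as absent; `strict = TRUE`
#' treats missing as potentially-present and drops the site.
#'
#' @param cohort a [CloneCohort-class] with >= 2 clones.
#' @param strict treat missing calls outside the focal clone as
#'   potentially-present.
#' @return a [CloneVariantSets-class].
#' @examples
#' d <- CohortDesign(c("A", "B"), replicates = 2, genomeLength = 20000,
#'                   backgroundHetRate = 0, cloneSpecific = c(A = 5, B = 3),
#'                   dropoutRate = 0, falsePositiveRate = 0, seed = 2)
#' ref <- generateReference(20000, seed = 2)
#' truth <- plantCohort(d, ref)
#' calls <- simulateCalls(truth, d, ref)
#' cohort <- buildMatrix(calls, designSamples(d))
#' lengths(exclusiveSites(cloneExclusive(cohort)))
#' @export
cloneExclusive <- function(cohort, strict = FALSE) {
  stopifnot(is(cohort, "CloneCohort"))
  cl <- cloneAssignments(cohort)
  if (length(unique(cl)) < 2L) {
    invalidDesign("cloneExclusive needs at least two clones")
  }
  cons <- replicateConsistent(cohort)
  m <- dosage(cohort)
  keys <- siteKeys(cohort)
  blocking <- if (strict) (is.na(m) | m >= 1L) else (!is.na(m) & m >= 1L)
  excl <- lapply(names(cons), function(cc) {
    outside <- which(cl != cc)
    bad <- keys[rowSums(blocking[, outside, drop = FALSE]) > 0L]
    setdiff(cons[[cc]], bad)
  })
  names(excl) <- names(cons)
  new("CloneVariantSets", consistent = cons, exclusive = excl)
}

isTransition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Summary statistics of a variant set
#'
#' Tallies SNVs and InDels, the heterozygous fraction of called sites, the
#' per-kbp densities, the transition/transversion ratio (transitions are
#' A<->G and C<->T; `NA` when there are no transversions), and per-window
#' counts in BED-like 0-based half-open windows.
#'
#' @param records a records `data.frame` (only `contig`, `pos`, `ref`,
#'   `alt` are required).
#' @param genomeLength total reference length in bp, for the per-kbp rates.
#' @param window window size in bp for the density track (default 100 kbp).
#' @param dosage optional dosage vector (0/1/2/NA), one value per record,
#'   for the focal sample; needed for the heterozygous fraction.
#' @param contigLengths optional named contig lengths for the window track;
#'   defaults to the highest observed position per contig.
#' @return list with `n_snv`, `n_indel`, `n_other`, `het_fraction` (percent
#'   of called variant sites that are heterozygous), `snv_per_kbp`,
#'   `indel_per_kbp`, `tstv`, and `windows` (data.frame `contig`, `start`,
#'   `end`, `snv_count`, `indel_count`).
#' @examples
#' rec <- data.frame(contig = "c", pos = c(10, 20, 30),
#'                   ref = c("A", "C", "A"), alt = c("G", "T", "C"))
#' summarizeVariants(rec, genomeLength = 1000)$tstv  # 2 Ts / 1 Tv
#' @export
summarizeVariants <- function(records, genomeLength = NULL, window = 1e5,
                              dosage = NULL, contigLengths = NULL) {
  cls <- classifyVariant(records$ref, records$alt)
  nSnv <- sum(cls == "SNV"); nIndel <- sum(cls == "InDel")
  snv <- cls == "SNV"
  ts <- sum(isTransition(records$ref[snv], records$alt[snv]))
  tv <- sum(snv) - ts
  tstv <- if (tv == 0L) NA_real_ else ts / tv
  hetFrac <- NA_real_
  if (!is.null(dosage)) {
    called <- !is.na(dosage) & dosage >= 1L
    hetFrac <- if (any(called)) 100 * sum(dosage[called] == 1L) /
      sum(called) else NA_real_
  }
  snvKbp <- indelKbp <- NA_real_
  if (!is.null(genomeLength)) {
    if (genomeLength <= 0) invalidDesign("genomeLength must be positive")
    snvKbp <- nSnv * 1000 / genomeLength
    indelKbp <- nIndel * 1000 / genomeLength
  }
  if (is.null(contigLengths)) {
    contigLengths <- if (nrow(records)) {
      tapply(records$pos + nchar(records$ref) - 1L, records$contig, max)
    } else integer()
  }
  windows <- do.call(rbind, lapply(names(contigLengths), function(cn) {
    len <- contigLengths[[cn]]
    starts <- seq(0L, max(len - 1L, 0L), by = window)
    ends <- pmin(starts + window, len)
    sel <- records$contig == cn
    wi <- findInterval(records$pos[sel] - 1L, starts)  # 0-based half-open
    data.frame(contig = cn, start = as.integer(starts),
               end = as.integer(ends),
               snv_count = tabulate(wi[cls[sel] == "SNV"],
                                    nbins = length(starts)),
               indel_count = tabulate(wi[cls[sel] == "InDel"],
                                      nbins = length(starts)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(windows)) {
    windows <- data.frame(contig = character(), start = integer(),
                          end = integer(), snv_count = integer(),
                          indel_count = integer())
  }
  list(n_snv = nSnv, n_indel = nIndel, n_other = sum(cls == "other"),
       het_fraction = hetFrac, snv_per_kbp = snvKbp,
       indel_per_kbp = indelKbp, tstv = tstv, windows = windows)
}

#' Per-clone summary of exclusive variants
#'
#' Mirrors the clone-specific variant tally of a clonal survey: exclusive
#' SNV and InDel counts per clone with their heterozygous percentages
#' (computed over the focal clone's replicate genotypes).
#'
#' @param cohort a [CloneCohort-class].
#' @param sets a [CloneVariantSets-class] from [cloneExclusive()].
#' @return data.frame with one row per clone: `clone`, `n_snv`, `n_indel`,
#'   `het_pct_snv`, `het_pct_indel`.
#' @export
exclusiveSummary <- function(cohort, sets) {
  m <- dosage(cohort)
  keys <- siteKeys(cohort)
  cl <- cloneAssignments(cohort)
  rd <- rowData(cohort)
  cls <- classifyVariant(rd$ref, rd$alt)
  rows <- lapply(cloneNames(sets), function(cc) {
    idx <- match(exclusiveSites(sets)[[cc]], keys)
    focal <- m[idx, cl == cc, drop = FALSE]
    hetOf <- function(sel) {
      g <- focal[sel, , drop = FALSE]
      called <- !is.na(g) & g >= 1L
      if (!any(called)) return(NA_real_)
      100 * sum(g[called] == 1L) / sum(called)
    }
    data.frame(clone = cc,
               n_snv = sum(cls[idx] == "SNV"),
               n_indel = sum(cls[idx] == "InDel"),
               het_pct_snv = hetOf(cls[idx] == "SNV"),
               het_pct_indel = hetOf(cls[idx] == "InDel"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA of clones on replicate-consistent variants
#'
#' Principal component analysis of the samples on alternate-allele dosage
#' (0/1/2; missing imputed to the site mean; centred, not variance-scaled),
#' by default restricted to the union of the clones' replicate-consistent
#' sites. Coordinates are sign-canonicalised (the largest-magnitude
#' coordinate of each axis is made positive) so repeated runs are
#' identical.
#'
#' @param cohort a [CloneCohort-class] with >= 2 samples.
#' @param sites character site keys to use; default is the
#'   replicate-consistent union.
#' @return list with `coordinates` (samples x PCs), `varExplained`
#'   (fractions summing to <= 1) and `clones` (named vector).
#' @export
pcaClones <- function(cohort, sites = NULL) {
  stopifnot(is(cohort, "CloneCohort"))
  if (ncol(cohort) < 2L) invalidDesign("PCA needs at least two samples")
  if (is.null(sites)) {
    sites <- Reduce(union, replicateConsistent(cohort))
  }
  keys <- siteKeys(cohort)
  idx <- match(sites, keys)
  if (anyNA(idx)) invalidDesign("unknown site keys in 'sites'")
  x <- t(dosage(cohort)[idx, , drop = FALSE])
  for (j in seq_len(ncol(x))) {            # impute missing to site mean
    nas <- is.na(x[, j])
    if (any(nas)) {
      mu <- mean(x[!nas, j])
      x[nas, j] <- if (is.nan(mu)) 0 else mu
    }
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  coords <- p$x
  for (j in seq_len(ncol(coords))) {       # per-axis sign canonicalisation
    k <- which.max(abs(coords[, j]))
    if (length(k) && coords[k, j] < 0) coords[, j] <- -coords[, j]
  }
  total <- sum(p$sdev^2)
  ve <- if (total > 0) p$sdev^2 / total else rep(0, length(p$sdev))
  list(coordinates = coords, varExplained = ve,
       clones = cloneAssignments(cohort))
}

#' Write per-clone exclusive variants as VCF subsets
#'
#' @param cohort a [CloneCohort-class] built from records.
#' @param sets a [CloneVariantSets-class].
#' @param records the records `data.frame` the cohort was built from.
#' @param dir output directory; one `exclusive_<clone>.vcf` per clone.
#' @return named vector of paths, invisibly.
#' @export
writeExclusiveVcfs <- function(cohort, sets, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- siteKey(records$contig, records$pos, records$ref, records$alt)
  paths <- vapply(cloneNames(sets), function(cc) {
    sub <- records[keys %in% exclusiveSites(sets)[[cc]], , drop = FALSE]
    attr(sub, "sample_ids") <- recordSamples(records)
    p <- file.path(dir, paste0("exclusive_", cc, ".vcf"))
    writeVcfRecords(sub, p)
    p
  }, character(1L))
  invisible(paths)
}
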