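## Shared fixtures and independent oracles for the test suite.

smallDesign <- function(clones = c("A", "B"), replicates = 2L,
                        genomeLength = 20000, cloneSpecific = 10L,
                        backgroundHetRate = 0.001, dropoutRate = 0,
                        falsePositiveRate = 0, seed = 1L, ...) {
  CohortDesign(clones = clones, replicates = replicates,
               genomeLength = genomeLength,
               backgroundHetRate = backgroundHetRate,
               cloneSpecific = cloneSpecific, dropoutRate = dropoutRate,
               falsePositiveRate = falsePositiveRate, seed = seed, ...)
}

## simulate a cohort and build its genotype matrix in one go
makeCohort <- function(design, gc = 0.345, qualityThreshold = NULL) {
  ref <- generateReference(design@genomeLength, design@nContigs, gc,
                           design@seed)
  truth <- plantCohort(design, ref)
  calls <- simulateCalls(truth, design, ref)
  rec <- if (is.null(qualityThreshold)) calls else
    qualityFilter(calls, qualityThreshold)
  list(reference = ref, truth = truth, calls = calls,
       cohort = buildMatrix(rec, designSamples(design)))
}

## Oracle: exhaustive per-site scan for consistent / exclusive sets.
## Independent of the package's rowSums-based implementation.
bruteSets <- function(mat, cloneOf, strict = FALSE) {
  clones <- unique(cloneOf)
  cons <- excl <- setNames(vector("list", length(clones)), clones)
  for (cc in clones) {
    inC <- character(); exC <- character()
    for (i in seq_len(nrow(mat))) {
      focal <- mat[i, cloneOf == cc]
      others <- mat[i, cloneOf != cc]
      consistent <- all(!is.na(focal) & focal >= 1L)
      if (consistent) {
        inC <- c(inC, rownames(mat)[i])
        blocked <- if (strict) any(is.na(others) | others >= 1L) else
          any(!is.na(others) & others >= 1L)
        if (!blocked) exC <- c(exC, rownames(mat)[i])
      }
    }
    cons[[cc]] <- inC; excl[[cc]] <- exC
  }
  list(consistent = cons, exclusive = excl)
}

## build a CloneCohort straight from a dosage matrix (rows already keyed)
matrixCohort <- function(mat, cloneOf, contig = "c1") {
  n <- nrow(mat)
  rec <- data.frame(contig = contig, pos = seq_len(n) * 10L,
                    ref = rep("A", n), alt = rep("G", n),
                    qual = rep(500, n), stringsAsFactors = FALSE)
  for (s in colnames(mat)) rec[[s]] <- ampliClone:::dosageToGT(mat[, s])
  attr(rec, "sample_ids") <- colnames(mat)
  design <- data.frame(sample_id = colnames(mat), clone_id = cloneOf,
                       stringsAsFactors = FALSE)
  buildMatrix(rec, design)
}

## Oracle: canonical minimal left-aligned representation via a global
## string diff of the reference haplotype vs the edited haplotype --
## maximal common suffix first, then maximal common prefix, with a left
## anchor base when one side empties.
globalDiffNormalize <- function(pos, ref, alt, contigSeq) {
  refSeq <- contigSeq
  altSeq <- paste0(substr(contigSeq, 1, pos - 1), alt,
                   substr(contigSeq, pos + nchar(ref), nchar(contigSeq)))
  r <- strsplit(refSeq, "")[[1]]
  a <- strsplit(altSeq, "")[[1]]
  nr <- length(r); na <- length(a)
  s <- 0L
  while (s < min(nr, na) && r[nr - s] == a[na - s]) s <- s + 1L
  p <- 0L
  while (p < min(nr, na) - s && r[p + 1L] == a[p + 1L]) p <- p + 1L
  newRef <- if (p + 1L <= nr - s) paste(r[(p + 1L):(nr - s)], collapse = "")
    else ""
  newAlt <- if (p + 1L <= na - s) paste(a[(p + 1L):(na - s)], collapse = "")
    else ""
  newPos <- p + 1L
  if (nchar(newRef) == 0L || nchar(newAlt) == 0L) {  # anchor
    newPos <- p
    newRef <- paste0(r[p], newRef)
    newAlt <- paste0(r[p], newAlt)
  }
  list(pos = newPos, ref = newRef, alt = newAlt)
}

## precision/recall of discovered exclusive sets against planted truth
recoveryStats <- function(sets, truth) {
  found <- unlist(exclusiveSites(sets), use.names = FALSE)
  planted <- truthKeys(truth, clone = unique(stats::na.omit(truth$clone)))
  tp <- length(intersect(found, planted))
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_)
}

fixturePath <- function(file) {
  system.file("extdata", file, package = "ampliClone", mustWork = TRUE)
}
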