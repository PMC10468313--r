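## Synthetic clonal cohorts: a diploid reference, background heterozygous
## variants shared by every sample, planted clone-exclusive SNVs/InDels,
## noisy per-replicate genotype calls, and amplicon read sets -- all seeded,
## all with ground truth attached.

DNA_BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Generate a random reference sequence set
#'
#' Draws i.i.d. bases at a target GC content and splits them over contigs of
#' (near-)equal length named `contig_1 ... contig_n`. The default GC of
#' 0.345 matches the 34.1--34.8% observed across grapevine cultivar
#' assemblies.
#'
#' @param genomeLength total length in bp (>= 1000).
#' @param nContigs number of contigs.
#' @param gcFraction target GC proportion, strictly between 0 and 1.
#' @param seed integer seed; the same seed reproduces the sequence exactly.
#' @return a [Biostrings::DNAStringSet] whose lengths sum to `genomeLength`.
#' @examples
#' ref <- generateReference(2000, nContigs = 2, seed = 7)
#' names(ref)
#' @export
generateReference <- function(genomeLength, nContigs = 1L,
                              gcFraction = 0.345, seed = 1L) {
  if (length(genomeLength) != 1L || is.na(genomeLength) ||
      genomeLength < 1000) {
    invalidDesign("genomeLength must be a single value >= 1000 bp")
  }
  if (length(nContigs) != 1L || is.na(nContigs) || nContigs < 1L) {
    invalidDesign("nContigs must be a positive integer")
  }
  if (gcFraction <= 0 || gcFraction >= 1) {
    invalidDesign("gcFraction must lie strictly between 0 and 1")
  }
  genomeLength <- as.integer(genomeLength)
  nContigs <- as.integer(nContigs)
  lens <- rep(genomeLength %/% nContigs, nContigs)
  extra <- genomeLength %% nContigs
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  probs <- c((1 - gcFraction) / 2, gcFraction / 2,
             gcFraction / 2, (1 - gcFraction) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(lens, function(n) {
      paste(sample(DNA_BASES, n, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1L))
  })
  names(seqs) <- sprintf("contig_%d", seq_len(nContigs))
  DNAStringSet(seqs)
}

## sample variant positions per contig with a minimum spacing so that
## deletion footprints never overlap a neighbouring variant
sampleSpacedPositions <- function(contigLens, n, minGap) {
  usable <- pmax(contigLens - minGap - 2L, 0L)
  if (n * (minGap + 1) > 0.5 * sum(usable)) {
    capacityError(sprintf(
      "cannot place %d variants with %d-bp spacing in %d usable bp",
      n, minGap + 1L, sum(usable)))
  }
  perContig <- as.vector(stats::rmultinom(1L, n, prob = usable / sum(usable)))
  out <- vector("list", length(contigLens))
  for (i in seq_along(contigLens)) {
    ni <- perContig[i]
    if (ni == 0L) { out[[i]] <- integer() ; next }
    lo <- 2L
    hi <- contigLens[i] - minGap - 1L
    kept <- integer()
    attempts <- 0L
    while (length(kept) < ni && attempts < 60L) {
      attempts <- attempts + 1L
      cand <- sort(unique(c(kept, sample(lo:hi, min(ni * 3L, hi - lo + 1L)))))
      keep <- logical(length(cand))
      last <- -minGap - 1L
      for (j in seq_along(cand)) {          # greedy left-to-right spacing
        if (cand[j] - last > minGap) { keep[j] <- TRUE ; last <- cand[j] }
      }
      kept <- cand[keep]
    }
    if (length(kept) < ni) {
      capacityError(sprintf("could not place %d spaced variants on contig %d",
                            ni, i))
    }
    out[[i]] <- sample(kept, ni)  # subsample to the exact count
  }
  out
}

## draw REF/ALT alleles for one position given the local reference sequence
drawAlleles <- function(contigSeq, pos, isIndel, tstvRatio, sizeRange) {
  refBase <- substr(contigSeq, pos, pos)
  if (!isIndel) {
    if (stats::runif(1L) < tstvRatio / (1 + tstvRatio)) {
      alt <- TRANSITION[[refBase]]
    } else {
      alt <- sample(TRANSVERSIONS[[refBase]], 1L)
    }
    return(c(refBase, alt))
  }
  size <- if (sizeRange[1L] == sizeRange[2L]) sizeRange[1L] else
    sample(sizeRange[1L]:sizeRange[2L], 1L)
  if (stats::runif(1L) < 0.5) {  # deletion, VCF anchored at the base before
    c(substr(contigSeq, pos, pos + size), refBase)
  } else {                       # insertion
    ins <- paste(sample(DNA_BASES, size, replace = TRUE), collapse = "")
    c(refBase, paste0(refBase, ins))
  }
}

#' Plant background and clone-specific variants into a reference
#'
#' Creates the ground truth of a simulated clonal cohort. Background
#' variants are heterozygous in every sample (the deep shared
#' heterozygosity of a clonally propagated cultivar against its reference
#' assembly); clone-specific variants are present, with identical genotype,
#' in all replicates of exactly one clone and reference elsewhere. SNV
#' substitution types follow the design's Ts/Tv ratio in expectation;
#' InDels are planted VCF-style (anchor base retained, left-aligned,
#' non-overlapping by a minimum-spacing rule).
#'
#' @param design a [CohortDesign-class].
#' @param reference a [Biostrings::DNAStringSet], e.g. from
#'   [generateReference()].
#' @return a truth-table `data.frame` with columns `contig`, `pos`, `ref`,
#'   `alt`, `origin` (`"background"` or `"clone_specific"`), `clone` (NA
#'   for background), followed by one alt-dosage column (0/1/2) per sample;
#'   sample ids are kept in `attr(x, "sample_ids")`.
#' @examples
#' d <- CohortDesign(c("A", "B"), replicates = 2, genomeLength = 20000,
#'                   backgroundHetRate = 0.001, cloneSpecific = 5, seed = 1)
#' ref <- generateReference(20000, seed = 1)
#' truth <- plantCohort(d, ref)
#' table(truth$origin)
#' @export
plantCohort <- function(design, reference) {
  stopifnot(is(design, "CohortDesign"), is(reference, "DNAStringSet"))
  samples <- designSamples(design)
  contigLens <- Biostrings::width(reference)
  contigNames <- names(reference)
  refStrings <- as.character(reference)
  nBack <- as.integer(round(sum(contigLens) * design@backgroundHetRate))
  nSpec <- design@cloneSpecificCount[design@clones]
  nTot <- nBack + sum(nSpec)
  minGap <- design@indelSizeRange[2L]

  withr::with_seed(design@seed, {
    posByContig <- sampleSpacedPositions(contigLens, nTot, minGap)
    contig <- rep(contigNames, lengths(posByContig))
    pos <- unlist(posByContig, use.names = FALSE)
    ord <- sample.int(length(pos))  # random assignment to origins
    contig <- contig[ord]; pos <- pos[ord]
    origin <- c(rep("background", nBack),
                rep("clone_specific", sum(nSpec)))
    clone <- c(rep(NA_character_, nBack),
               rep(design@clones, nSpec))
    isIndel <- stats::runif(nTot) < design@indelFraction
    ref <- character(nTot); alt <- character(nTot)
    for (i in seq_len(nTot)) {
      al <- drawAlleles(refStrings[[contig[i]]], pos[i], isIndel[i],
                        design@tstvRatio, design@indelSizeRange)
      ## plant the canonical (left-aligned, trimmed) representation so
      ## truth keys are directly comparable with normalised calls
      nm <- normalizeOne(pos[i], al[1L], al[2L], refStrings[[contig[i]]])
      pos[i] <- nm$pos; ref[i] <- nm$ref; alt[i] <- nm$alt
    }
    if (anyDuplicated(siteKey(contig, pos, ref, alt))) {
      capacityError("variant positions collide after left-alignment; use a larger genome or fewer variants")
    }
    geno <- matrix(0L, nrow = nTot, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
    geno[origin == "background", ] <- 1L
    specIdx <- which(origin == "clone_specific")
    gSpec <- ifelse(stats::runif(length(specIdx)) <
                      design@hetFractionSpecific, 1L, 2L)
    for (k in seq_along(specIdx)) {
      i <- specIdx[k]
      geno[i, samples$clone_id == clone[i]] <- gSpec[k]
    }
    truth <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                        origin = origin, clone = clone,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(geno))
    o <- order(truth$contig, truth$pos)
    truth <- truth[o, , drop = FALSE]
    rownames(truth) <- NULL
    attr(truth, "sample_ids") <- samples$sample_id
    truth
  })
}

#' Sample ids of a truth table
#' @param truth a truth table from [plantCohort()].
#' @return character vector of sample ids.
#' @export
truthSamples <- function(truth) attr(truth, "sample_ids")

#' Site keys of truth variants, optionally per origin/clone
#' @param truth a truth table from [plantCohort()].
#' @param clone if given, restrict to that clone's specific variants.
#' @return character vector of site keys.
#' @export
truthKeys <- function(truth, clone = NULL) {
  sel <- if (is.null(clone)) rep(TRUE, nrow(truth)) else
    truth$origin == "clone_specific" & truth$clone %in% clone
  siteKey(truth$contig[sel], truth$pos[sel], truth$ref[sel], truth$alt[sel])
}

dosageToGT <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  gt
}

gtToDosage <- function(gt) {
  d <- rep(NA_integer_, length(gt))
  d[gt == "0/0"] <- 0L; d[gt == "0/1" | gt == "1/0"] <- 1L
  d[gt == "1/1"] <- 2L
  d
}

#' Simulate noisy multi-sample variant calls from a truth table
#'
#' Emulates caller output at the VCF level: each truly present genotype is
#' dropped (set to missing `./.`) independently per replicate with
#' probability `dropoutRate`; spurious singleton heterozygous calls are
#' injected at `falsePositiveRate` per site per replicate; site QUAL is
#' drawn from the design's two-component model, with false positives biased
#' low so that a conventional Q > 100 filter removes most of them.
#'
#' @param truth a truth table from [plantCohort()].
#' @param design the same [CohortDesign-class] used to plant it.
#' @param reference optional [Biostrings::DNAStringSet]; when supplied,
#'   false-positive records use the actual reference base, otherwise a
#'   random base.
#' @return a variant-records `data.frame` (see [readVcfRecords()] for the
#'   shape): columns `contig`, `pos`, `ref`, `alt`, `qual`, plus one GT
#'   column per sample (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`), sorted by
#'   position; sample ids in `attr(x, "sample_ids")`.
#' @examples
#' d <- CohortDesign(c("A", "B"), replicates = 2, genomeLength = 20000,
#'                   backgroundHetRate = 0.001, cloneSpecific = 5,
#'                   dropoutRate = 0, falsePositiveRate = 0, seed = 1)
#' ref <- generateReference(20000, seed = 1)
#' calls <- simulateCalls(plantCohort(d, ref), d, ref)
#' head(calls)
#' @export
simulateCalls <- function(truth, design, reference = NULL) {
  stopifnot(is(design, "CohortDesign"))
  samples <- truthSamples(truth)
  qm <- design@qualModel
  withr::with_seed(design@seed + 1L, {
    n <- nrow(truth)
    geno <- as.matrix(truth[, samples, drop = FALSE])
    if (n > 0L && design@dropoutRate > 0) {
      present <- !is.na(geno) & geno > 0L
      drop <- present &
        matrix(stats::runif(length(geno)) < design@dropoutRate,
               nrow = n)
      geno[drop] <- NA_integer_
    }
    qual <- if (n > 0L)
      pmax(1, round(stats::rnorm(n, qm$trueMean, qm$trueSd), 2)) else numeric()
    rec <- data.frame(contig = truth$contig, pos = truth$pos,
                      ref = truth$ref, alt = truth$alt, qual = qual,
                      stringsAsFactors = FALSE)
    gt <- matrix(dosageToGT(geno), nrow = n,
                 dimnames = list(NULL, samples))

    ## spurious singleton calls, positions disjoint from the truth
    if (design@falsePositiveRate > 0) {
      contigLens <- fpContigLengths(truth, design, reference)
      nFp <- stats::rbinom(length(samples), size = sum(contigLens),
                           prob = design@falsePositiveRate)
      tot <- sum(nFp)
      if (tot > 0L) {
        fp <- drawFalsePositives(tot, contigLens, truth, reference)
        fpQual <- pmax(1, round(stats::rnorm(tot, qm$falseMean, qm$falseSd), 2))
        fpGt <- matrix("0/0", nrow = tot, ncol = length(samples),
                       dimnames = list(NULL, samples))
        owner <- rep(seq_along(samples), nFp)
        fpGt[cbind(seq_len(tot), owner)] <- "0/1"
        rec <- rbind(rec, data.frame(contig = fp$contig, pos = fp$pos,
                                     ref = fp$ref, alt = fp$alt,
                                     qual = fpQual, stringsAsFactors = FALSE))
        gt <- rbind(gt, fpGt)
      }
    }
    o <- order(rec$contig, rec$pos, rec$ref, rec$alt)
    out <- cbind(rec[o, , drop = FALSE],
                 as.data.frame(gt[o, , drop = FALSE]))
    rownames(out) <- NULL
    attr(out, "sample_ids") <- samples
    out
  })
}

fpContigLengths <- function(truth, design, reference) {
  if (!is.null(reference)) {
    return(setNames(Biostrings::width(reference), names(reference)))
  }
  contigs <- unique(truth$contig)
  if (length(contigs) == 0L) contigs <- "contig_1"
  setNames(rep(floor(design@genomeLength / length(contigs)),
               length(contigs)), contigs)
}

drawFalsePositives <- function(tot, contigLens, truth, reference) {
  contigs <- names(contigLens)
  ci <- sample(seq_along(contigs), tot, replace = TRUE,
               prob = contigLens / sum(contigLens))
  pos <- integer(tot); ref <- character(tot); alt <- character(tot)
  truthKey <- paste(truth$contig, truth$pos)
  for (k in seq_len(tot)) {
    repeat {
      p <- sample.int(contigLens[ci[k]] - 1L, 1L) + 1L
      if (!(paste(contigs[ci[k]], p) %in% truthKey)) break
    }
    pos[k] <- p
    refBase <- if (!is.null(reference)) {
      substr(as.character(reference[[contigs[ci[k]]]]), p, p)
    } else sample(DNA_BASES, 1L)
    ref[k] <- refBase
    alt[k] <- sample(setdiff(DNA_BASES, refBase), 1L)
  }
  list(contig = contigs[ci], pos = pos, ref = ref, alt = alt)
}

#' Write a truth table as TSV
#'
#' Genotypes are exported as GT strings (`0/0`, `0/1`, `1/1`) so the file is
#' directly comparable with the simulated VCF.
#'
#' @param truth a truth table from [plantCohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  samples <- truthSamples(truth)
  out <- truth[, c("contig", "pos", "ref", "alt", "origin", "clone")]
  for (s in samples) out[[s]] <- dosageToGT(truth[[s]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate amplicon reads for one marker and genotype
#'
#' Reads are full-length copies of the two allele sequences of the marker's
#' amplicon: a heterozygous template yields allele A with probability
#' `alleleBias` per read (0.5 = unbiased PCR), a homozygous template yields
#' a single allele. Substitution errors are applied independently per base.
#' The drawn per-allele counts are returned alongside the reads as ground
#' truth for allele-counting.
#'
#' @param marker one marker: a single row of [markers()] output (as a list
#'   or one-row data.frame) carrying `seq_a` and `seq_b`.
#' @param genotype `"hom_a"`, `"het"` or `"hom_b"` (`"hom_a"` is
#'   homozygous for allele A, i.e. the reference amplicon).
#' @param depth number of reads (>= 0).
#' @param alleleBias probability a heterozygous read comes from allele A.
#' @param perBaseError substitution error rate per base.
#' @param seed integer seed.
#' @return list with `reads` (character vector, shuffled) and `counts`
#'   (named integer, `a`/`b` drawn allele counts).
#' @export
simulateAmpliconReads <- function(marker, genotype, depth,
                                  alleleBias = 0.5, perBaseError = 0,
                                  seed = 1L) {
  marker <- as.list(marker)
  if (is.null(marker$seq_a) || is.na(marker$seq_a) ||
      is.null(marker$seq_b) || is.na(marker$seq_b)) {
    configError("marker has no resolvable allele sequences (seq_a/seq_b)")
  }
  genotype <- match.arg(genotype, c("hom_a", "het", "hom_b"))
  if (depth < 0) invalidDesign("depth must be >= 0")
  if (depth == 0) {
    return(list(reads = character(), counts = c(a = 0L, b = 0L)))
  }
  withr::with_seed(seed, {
    nA <- switch(genotype,
                 hom_a = as.integer(depth),
                 hom_b = 0L,
                 het = stats::rbinom(1L, depth, alleleBias))
    nB <- as.integer(depth) - nA
    reads <- c(rep(marker$seq_a, nA), rep(marker$seq_b, nB))
    reads <- reads[sample.int(length(reads))]
    if (perBaseError > 0) reads <- mutateReads(reads, perBaseError)
    list(reads = reads, counts = c(a = nA, b = nB))
  })
}

## independent per-base substitution errors; only reads that draw >=1 error
## are touched
mutateReads <- function(reads, rate) {
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  for (i in which(nerr > 0L)) {
    p <- sample.int(lens[i], nerr[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (j in p) chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1L)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}
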