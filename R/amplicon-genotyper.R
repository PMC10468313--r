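## From amplicon reads to allele counts, to genotype calls, to a clone
## identification: the decision procedure in which a single positive
## heterozygous marker identifies its clone.

hammingPlusLength <- function(read, allele) {
  n1 <- nchar(read); n2 <- nchar(allele)
  n <- min(n1, n2)
  a <- utf8ToInt(substr(read, 1L, n))
  b <- utf8ToInt(substr(allele, 1L, n))
  sum(a != b) + abs(n1 - n2)
}

#' Count amplicon reads per marker allele
#'
#' Assigns each read to one of the marker's two alleles. For an SNV marker
#' the base at the variant offset decides (a read showing neither allele
#' base is unassigned); for an InDel marker each read is compared against
#' both allele sequences (mismatches over the shared prefix plus the length
#' difference) and takes the closer allele if within `maxMismatches`, ties
#' and poor matches counting as unassigned.
#'
#' @param reads character vector of amplicon reads (same orientation as
#'   the allele sequences).
#' @param marker one marker row (list or one-row data.frame) with `seq_a`,
#'   `seq_b`, and for SNVs `position`/`amp_start` or differing bases.
#' @param maxMismatches maximum mismatches for an assignment (default 5).
#' @return list with `marker_id`, `count_a`, `count_b`, `unassigned`,
#'   `depth` (= a + b + unassigned).
#' @examples
#' mk <- list(marker_id = "m", variant_type = "SNV",
#'            seq_a = "ACGTA", seq_b = "ACTTA")
#' countAlleles(c("ACGTA", "ACTTA", "ACGTA"), mk)
#' @export
countAlleles <- function(reads, marker, maxMismatches = 5L) {
  marker <- as.list(marker)
  if (is.null(marker$seq_a) || is.null(marker$seq_b) ||
      is.na(marker$seq_a) || is.na(marker$seq_b)) {
    configError("marker has no resolvable allele sequences (seq_a/seq_b)")
  }
  seqA <- marker$seq_a; seqB <- marker$seq_b
  n <- length(reads)
  if (n == 0L) {
    return(list(marker_id = marker$marker_id %||% NA_character_,
                count_a = 0L, count_b = 0L, unassigned = 0L, depth = 0L))
  }
  isSnv <- nchar(seqA) == nchar(seqB)
  if (isSnv) {
    diffs <- which(utf8ToInt(seqA) != utf8ToInt(seqB))
    if (!length(diffs)) configError("SNV marker alleles are identical")
    off <- diffs[1L]
    base <- substr(reads, off, off)
    a <- sum(base == substr(seqA, off, off))
    b <- sum(base == substr(seqB, off, off))
    un <- n - a - b
  } else {
    a <- b <- un <- 0L
    for (r in reads) {
      da <- hammingPlusLength(r, seqA)
      db <- hammingPlusLength(r, seqB)
      if (da < db && da <= maxMismatches) a <- a + 1L
      else if (db < da && db <= maxMismatches) b <- b + 1L
      else un <- un + 1L
    }
  }
  list(marker_id = marker$marker_id %||% NA_character_,
       count_a = as.integer(a), count_b = as.integer(b),
       unassigned = as.integer(un), depth = n)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Call a genotype from two allele counts
#'
#' Depth below `minDepth` gives `no_call`. Otherwise the minor-allele
#' fraction (over assigned reads) decides: at or above
#' `minMinorFraction` the call is `het`; at or below `maxMinorForHom` it
#' is homozygous for the major allele; in between lies an explicit
#' ambiguous zone that also yields `no_call`. Swapping the two counts maps
#' `hom_a` and `hom_b` onto each other and fixes `het`/`no_call`.
#'
#' @param counts result of [countAlleles()], or a numeric vector of the
#'   two allele counts.
#' @param minDepth minimum assigned depth (default 20).
#' @param minMinorFraction minor fraction at/above which the call is het
#'   (default 0.20).
#' @param maxMinorForHom minor fraction at/below which the call is
#'   homozygous (default 0.05).
#' @return one of `"hom_a"`, `"het"`, `"hom_b"`, `"no_call"`.
#' @examples
#' callGenotype(c(100, 100))  # het
#' callGenotype(c(190, 10))   # hom_a
#' @export
callGenotype <- function(counts, minDepth = 20L, minMinorFraction = 0.20,
                         maxMinorForHom = 0.05) {
  if (!(maxMinorForHom >= 0 && maxMinorForHom < minMinorFraction &&
        minMinorFraction <= 0.5)) {
    invalidDesign(
      "thresholds must satisfy 0 <= maxMinorForHom < minMinorFraction <= 0.5")
  }
  if (is.list(counts)) counts <- c(counts$count_a, counts$count_b)
  stopifnot(length(counts) == 2L, all(counts >= 0))
  depth <- sum(counts)
  if (depth < minDepth) return("no_call")
  minor <- min(counts) / depth
  if (minor >= minMinorFraction) return("het")
  if (minor <= maxMinorForHom) {
    return(if (counts[1L] >= counts[2L]) "hom_a" else "hom_b")
  }
  "no_call"
}

#' Read an allele-counts table
#'
#' @param path TSV with columns `sample_id`, `marker_id`, `count_a`,
#'   `count_b` and optionally `unassigned`.
#' @return data.frame.
#' @export
readCountsTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker_id", "count_a", "count_b")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    parseError(paste0("counts table lacks column(s): ",
                      paste(miss, collapse = ", ")))
  }
  if (!"unassigned" %in% colnames(d)) d$unassigned <- 0L
  d
}

#' Call genotypes for a whole counts table
#'
#' @param counts data.frame from [readCountsTable()].
#' @param panel a [MarkerPanel-class]; every counts row must reference a
#'   panel marker, and (sample, marker) pairs must be unique.
#' @param minDepth,minMinorFraction,maxMinorForHom see [callGenotype()].
#' @return the counts with `genotype` and `allele_fraction` (minor
#'   fraction, NA at zero depth) columns added.
#' @export
genotypeCounts <- function(counts, panel, minDepth = 20L,
                           minMinorFraction = 0.20, maxMinorForHom = 0.05) {
  unknown <- setdiff(unique(counts$marker_id), markers(panel)$marker_id)
  if (length(unknown)) {
    consistencyError(paste0("counts reference unknown marker(s): ",
                            paste(unknown, collapse = ", ")))
  }
  key <- paste(counts$sample_id, counts$marker_id)
  if (anyDuplicated(key)) {
    consistencyError("duplicate (sample_id, marker_id) rows in counts")
  }
  counts$genotype <- vapply(seq_len(nrow(counts)), function(i) {
    callGenotype(c(counts$count_a[i], counts$count_b[i]), minDepth,
                 minMinorFraction, maxMinorForHom)
  }, character(1L))
  tot <- counts$count_a + counts$count_b
  counts$allele_fraction <- ifelse(tot > 0,
                                   pmin(counts$count_a, counts$count_b) / tot,
                                   NA_real_)
  counts
}

#' Identify clones from per-marker genotype calls
#'
#' A marker is positive for its clone when the sample's call is
#' heterozygous (every validated clonal marker is heterozygous in its
#' clone). Positives for exactly one clone assign that clone; no positives
#' give `unassigned` (a clone without validated markers can never be
#' positively identified); positives for two or more clones give
#' `ambiguous`, with all conflicting markers listed -- ambiguity is
#' reported, never tie-broken.
#'
#' @param calls data.frame with `sample_id`, `marker_id`, `genotype` (and
#'   optionally `allele_fraction`), e.g. from [genotypeCounts()].
#' @param panel a [MarkerPanel-class].
#' @return data.frame with one row per sample: `sample_id`,
#'   `assigned_clone` (clone, `"unassigned"` or `"ambiguous"`),
#'   `n_positive_markers`, `evidence` (semicolon-joined
#'   `marker=genotype@fraction`), `conflicts`.
#' @export
identifyClones <- function(calls, panel) {
  pm <- markers(panel)
  unknown <- setdiff(unique(calls$marker_id), pm$marker_id)
  if (length(unknown)) {
    consistencyError(paste0("calls reference unknown marker(s): ",
                            paste(unknown, collapse = ", ")))
  }
  cloneOf <- setNames(pm$clone_id, pm$marker_id)
  rows <- lapply(split(calls, calls$sample_id), function(sc) {
    pos <- sc[sc$genotype == "het", , drop = FALSE]
    posClones <- unique(unname(cloneOf[pos$marker_id]))
    frac <- if ("allele_fraction" %in% colnames(sc))
      sprintf("@%.3f", pos$allele_fraction) else ""
    evidence <- paste0(pos$marker_id, "=het",
                       if (nrow(pos)) frac else character())
    if (length(posClones) == 1L) {
      assigned <- posClones
      conflicts <- ""
    } else if (length(posClones) == 0L) {
      assigned <- "unassigned"
      conflicts <- ""
    } else {
      assigned <- "ambiguous"
      conflicts <- paste(
        sprintf("%s(%s)", pos$marker_id, cloneOf[pos$marker_id]),
        collapse = ";")
    }
    data.frame(sample_id = sc$sample_id[1L], assigned_clone = assigned,
               n_positive_markers = nrow(pos),
               evidence = paste(evidence, collapse = ";"),
               conflicts = conflicts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
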