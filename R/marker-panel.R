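## Marker panels: select amplicon-compatible diagnostic loci from
## clone-exclusive variants and read/write/summarise marker tables in the
## six-column schema of a validated clonal marker list.

MARKER_COLS <- c("cultivar", "clone_id", "marker_id", "variant_type",
                 "allele_a", "allele_b", "contig", "position",
                 "length_a", "length_b")

newMarkerPanel <- function(df) {
  for (col in setdiff(MARKER_COLS, colnames(df))) df[[col]] <- NA
  obj <- new("MarkerPanel", markers = df)
  err <- validObject(obj, test = TRUE)
  if (!isTRUE(err)) parseError(paste(err, collapse = "; "))
  obj
}

#' Select amplicon marker candidates from clone-exclusive variants
#'
#' Turns heterozygous clone-exclusive variants into amplicon marker
#' candidates. Each candidate gets a window of `targetLen` bp centred on
#' the variant; both allele lengths (the REF-allele amplicon and, for an
#' InDel, the ALT-allele amplicon) must fall within `[minLen, maxLen]` --
#' the practical size range for a two-step PCR amplicon panel -- and the
#' window must lie fully on its contig. As an automatable stand-in for
#' visual read-mapping inspection, a candidate is also skipped when another
#' variant falls inside its window (`"flank_variant"`). Candidates are
#' ranked by site QUAL (descending), ties by position; skipped variants are
#' returned with a reason in `attr(x, "skipped")`.
#'
#' @param cohort a [CloneCohort-class] (supplies genotypes and QUAL).
#' @param sets a [CloneVariantSets-class] with nonempty exclusive sets for
#'   at least one clone.
#' @param reference [Biostrings::DNAStringSet] covering the cohort contigs.
#' @param minLen,maxLen admissible amplicon allele length range in bp
#'   (defaults 141 and 487).
#' @param targetLen target amplicon length in bp (default 200).
#' @param cultivar cultivar label for the marker table; default from the
#'   cohort's `colData$cultivar` or `"NN"`.
#' @return a [MarkerPanel-class]; markers carry window coordinates
#'   (`amp_start`, `amp_end`, 1-based inclusive) and the two allele
#'   sequences `seq_a` (REF) / `seq_b` (ALT).
#' @export
selectCandidates <- function(cohort, sets, reference,
                             minLen = 141L, maxLen = 487L,
                             targetLen = 200L, cultivar = NULL) {
  stopifnot(is(cohort, "CloneCohort"), is(sets, "CloneVariantSets"),
            is(reference, "DNAStringSet"))
  if (all(lengths(exclusiveSites(sets)) == 0L)) {
    invalidDesign("no clone has exclusive variants to select from")
  }
  if (is.null(cultivar)) {
    cultivar <- if ("cultivar" %in% colnames(colData(cohort)))
      as.character(colData(cohort)$cultivar[1L]) else "NN"
  }
  keys <- siteKeys(cohort)
  m <- dosage(cohort)
  cl <- cloneAssignments(cohort)
  rd <- rowData(cohort)
  contig <- as.character(seqnames(cohort))
  pos <- GenomicRanges::start(rowRanges(cohort))
  seqs <- as.character(reference)
  contigLens <- setNames(Biostrings::width(reference), names(reference))

  rows <- list(); skipped <- list()
  for (cc in cloneNames(sets)) {
    for (key in exclusiveSites(sets)[[cc]]) {
      i <- match(key, keys)
      reason <- NULL
      focal <- m[i, cl == cc]
      if (!all(!is.na(focal) & focal == 1L)) {
        reason <- "not_heterozygous"
      } else {
        refA <- rd$ref[i]; altA <- rd$alt[i]
        refLen <- nchar(refA)
        ampStart <- pos[i] - (targetLen - refLen) %/% 2L
        ampEnd <- ampStart + targetLen - 1L
        lenA <- targetLen
        lenB <- targetLen - (nchar(refA) - nchar(altA))
        if (ampStart < 1L || ampEnd > contigLens[[contig[i]]]) {
          reason <- "edge"
        } else if (lenA < minLen || lenA > maxLen ||
                   lenB < minLen || lenB > maxLen) {
          reason <- "length"
        } else {
          others <- which(contig == contig[i] & pos >= ampStart &
                            pos <= ampEnd)
          if (length(setdiff(others, i))) reason <- "flank_variant"
        }
      }
      if (!is.null(reason)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(clone_id = cc, site = key, reason = reason,
                     stringsAsFactors = FALSE)
        next
      }
      cseq <- seqs[[contig[i]]]
      seqA <- substr(cseq, ampStart, ampEnd)
      seqB <- paste0(substr(cseq, ampStart, pos[i] - 1L), altA,
                     substr(cseq, pos[i] + refLen, ampEnd))
      vt <- classifyVariant(refA, altA)
      rows[[length(rows) + 1L]] <- data.frame(
        cultivar = cultivar, clone_id = cc, marker_id = NA_character_,
        variant_type = vt,
        allele_a = if (vt == "SNV") refA else NA_character_,
        allele_b = if (vt == "SNV") altA else NA_character_,
        contig = contig[i], position = pos[i],
        length_a = lenA,
        length_b = if (vt == "SNV") NA_integer_ else lenB,
        amp_start = ampStart, amp_end = ampEnd,
        seq_a = seqA, seq_b = seqB, qual = rd$qual[i],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cultivar = character(), clone_id = character(),
               marker_id = character(), variant_type = character(),
               allele_a = character(), allele_b = character(),
               contig = character(), position = integer(),
               length_a = integer(), length_b = integer(),
               amp_start = integer(), amp_end = integer(),
               seq_a = character(), seq_b = character(), qual = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$clone_id, -ifelse(is.na(df$qual), -Inf, df$qual),
                   df$contig, df$position), , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(df)), df$clone_id, FUN = seq_along)
    df$marker_id <- sprintf("%s%s_%d", df$cultivar, df$clone_id, idx)
    rownames(df) <- NULL
  }
  skippedDf <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(clone_id = character(), site = character(),
               reason = character(), stringsAsFactors = FALSE)
  panel <- newMarkerPanel(df)
  attr(panel@markers, "skipped") <- NULL
  attr(panel, "skipped") <- skippedDf
  panel
}

#' Skipped candidates of a selection run
#' @param panel a [MarkerPanel-class] from [selectCandidates()].
#' @return data.frame `clone_id`, `site`, `reason`.
#' @export
skippedCandidates <- function(panel) attr(panel, "skipped")

stripThousands <- function(x) gsub(",", "", x, fixed = TRUE)

#' Load a marker table
#'
#' Reads a TSV in the six-column validated-marker schema: cultivar, clone
#' id, marker id, DNA variant (`"InDel"` or `"SNV X/Y"`), scaffold/start
#' position (`"<scaffold>/<pos>"`; thousands separators tolerated), allele
#' length (`"<a>/<b>"` for InDel, one length for SNV).
#'
#' @param path TSV file, e.g. the packaged
#'   `system.file("extdata", "table5_markers.tsv", package = "ampliClone")`.
#' @return a [MarkerPanel-class].
#' @examples
#' p <- loadMarkerTable(system.file("extdata", "table5_markers.tsv",
#'                                  package = "ampliClone"))
#' length(p)
#' @export
loadMarkerTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cultivar", "clone_id", "marker_id", "dna_variant",
            "scaffold_start_position", "allele_length")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    parseError(paste0("marker table lacks column(s): ",
                      paste(miss, collapse = ", ")))
  }
  n <- nrow(d)
  out <- data.frame(cultivar = d$cultivar, clone_id = d$clone_id,
                    marker_id = d$marker_id,
                    variant_type = rep(NA_character_, n),
                    allele_a = rep(NA_character_, n),
                    allele_b = rep(NA_character_, n),
                    contig = rep(NA_character_, n),
                    position = rep(NA_integer_, n),
                    length_a = rep(NA_integer_, n),
                    length_b = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    dv <- trimws(d$dna_variant[i])
    if (identical(dv, "InDel")) {
      out$variant_type[i] <- "InDel"
    } else if (grepl("^SNV ", dv)) {
      al <- strsplit(sub("^SNV ", "", dv), "/", fixed = TRUE)[[1L]]
      if (length(al) != 2L || !all(al %in% DNA_BASES)) {
        parseError(sprintf("marker %s: malformed SNV alleles '%s'",
                           d$marker_id[i], dv))
      }
      out$variant_type[i] <- "SNV"
      out$allele_a[i] <- al[1L]; out$allele_b[i] <- al[2L]
    } else {
      parseError(sprintf("marker %s: unrecognised DNA variant '%s'",
                         d$marker_id[i], dv))
    }
    loc <- d$scaffold_start_position[i]
    cut <- regexpr("/[^/]*$", loc)  # split on the last slash
    if (cut < 2L) {
      parseError(sprintf("marker %s: malformed locus '%s'",
                         d$marker_id[i], loc))
    }
    out$contig[i] <- substr(loc, 1L, cut - 1L)
    posStr <- stripThousands(substr(loc, cut + 1L, nchar(loc)))
    pos <- suppressWarnings(as.integer(posStr))
    if (is.na(pos)) {
      parseError(sprintf("marker %s: malformed position '%s'",
                         d$marker_id[i], loc))
    }
    out$position[i] <- pos
    lens <- strsplit(stripThousands(d$allele_length[i]), "/",
                     fixed = TRUE)[[1L]]
    lens <- suppressWarnings(as.integer(lens))
    if (anyNA(lens) || !length(lens) %in% 1:2 ||
        (out$variant_type[i] == "InDel" && length(lens) != 2L) ||
        (out$variant_type[i] == "SNV" && length(lens) != 1L)) {
      parseError(sprintf("marker %s: malformed allele length '%s'",
                         d$marker_id[i], d$allele_length[i]))
    }
    out$length_a[i] <- lens[1L]
    if (length(lens) == 2L) out$length_b[i] <- lens[2L]
  }
  newMarkerPanel(out)
}

#' Write a marker table
#'
#' Inverse of [loadMarkerTable()]: emits the six-column schema.
#'
#' @param panel a [MarkerPanel-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeMarkerTable <- function(panel, path) {
  m <- markers(panel)
  dv <- ifelse(m$variant_type == "SNV",
               paste0("SNV ", m$allele_a, "/", m$allele_b), "InDel")
  al <- ifelse(is.na(m$length_b), as.character(m$length_a),
               paste0(m$length_a, "/", m$length_b))
  out <- data.frame(cultivar = m$cultivar, clone_id = m$clone_id,
                    marker_id = m$marker_id, dna_variant = dv,
                    scaffold_start_position = paste0(m$contig, "/",
                                                     m$position),
                    allele_length = al, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export candidate amplicon windows as BED
#'
#' 0-based half-open windows for external primer design.
#'
#' @param panel a [MarkerPanel-class] with window coordinates.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
writeCandidateBed <- function(panel, path) {
  m <- markers(panel)
  if (!"amp_start" %in% colnames(m) || all(is.na(m$amp_start))) {
    invalidDesign("panel has no amplicon windows (loaded, not selected?)")
  }
  bed <- data.frame(m$contig, m$amp_start - 1L, m$amp_end, m$marker_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an evaluated-clone roster
#'
#' @param path TSV with columns `cultivar`, `clone_id` and optionally
#'   `n_replicates`, e.g. the packaged
#'   `system.file("extdata", "table1_design.tsv", package = "ampliClone")`.
#' @return data.frame of evaluated clones.
#' @export
loadRoster <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("cultivar", "clone_id") %in% colnames(d))) {
    parseError("roster needs columns cultivar and clone_id")
  }
  if ("n_replicates" %in% colnames(d)) {
    d$n_replicates <- as.integer(d$n_replicates)
  }
  d
}

truncate1 <- function(x) trunc(x * 10) / 10

#' Summarise a marker panel against a roster of evaluated clones
#'
#' Direct tallies of a panel: totals by cultivar, clone and variant type,
#' the number of distinct clones carrying at least one marker, amplicon
#' allele-length extrema/mean, mean InDel size (allele-length difference),
#' and the clone-coverage percentage (clones with >= 1 marker over the
#' roster, truncated -- not rounded -- to one decimal). The headline mean
#' markers per covered clone is reported both unrounded and rounded to the
#' nearest integer.
#'
#' @param panel a [MarkerPanel-class].
#' @param roster data.frame of evaluated clones (see [loadRoster()]).
#' @return list with `n_markers`, `n_snv`, `n_indel`, `by_cultivar`,
#'   `by_clone`, `n_clones_with_markers`, `clone_coverage_pct`,
#'   `allele_length_min`/`max`/`mean`, `mean_indel_size`,
#'   `mean_markers_per_clone` and `mean_markers_per_clone_rounded`.
#' @examples
#' p <- loadMarkerTable(system.file("extdata", "table5_markers.tsv",
#'                                  package = "ampliClone"))
#' r <- loadRoster(system.file("extdata", "table1_design.tsv",
#'                             package = "ampliClone"))
#' summarizePanel(p, r)$clone_coverage_pct
#' @export
summarizePanel <- function(panel, roster) {
  m <- markers(panel)
  rosterKey <- paste(roster$cultivar, roster$clone_id)
  if (nrow(m)) {
    mk <- paste(m$cultivar, m$clone_id)
    missing <- unique(mk[!(mk %in% rosterKey)])
    if (length(missing)) {
      consistencyError(paste0("marker clone(s) absent from the roster: ",
                              paste(missing, collapse = ", ")))
    }
  }
  lens <- c(m$length_a, m$length_b)
  lens <- lens[!is.na(lens)]
  indel <- m$variant_type == "InDel"
  covered <- unique(paste(m$cultivar, m$clone_id))
  byCultivar <- if (nrow(m)) table(m$cultivar) else table(character())
  byClone <- if (nrow(m)) table(paste(m$cultivar, m$clone_id)) else
    table(character())
  nCov <- length(covered)
  list(
    n_markers = nrow(m),
    n_snv = sum(m$variant_type == "SNV"),
    n_indel = sum(indel),
    by_cultivar = byCultivar,
    by_clone = byClone,
    n_clones_with_markers = nCov,
    n_evaluated_clones = nrow(roster),
    n_replicate_genomes = if ("n_replicates" %in% colnames(roster))
      sum(roster$n_replicates) else NA_integer_,
    clone_coverage_pct = if (nrow(roster))
      truncate1(100 * nCov / nrow(roster)) else 0,
    allele_length_min = if (length(lens)) min(lens) else NA_integer_,
    allele_length_max = if (length(lens)) max(lens) else NA_integer_,
    allele_length_mean = if (length(lens)) mean(lens) else NA_real_,
    mean_indel_size = if (any(indel))
      mean(abs(m$length_a[indel] - m$length_b[indel])) else NA_real_,
    mean_markers_per_clone = if (nCov) nrow(m) / nCov else 0,
    mean_markers_per_clone_rounded = if (nCov)
      as.integer(round(nrow(m) / nCov)) else 0L
  )
}
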