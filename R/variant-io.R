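## VCF-level I/O and record-level operations. Records travel as a plain
## data.frame -- columns contig, pos, ref, alt, qual, then one GT column per
## sample -- and are assembled into a CloneCohort by buildMatrix().

RECORD_META <- c("contig", "pos", "ref", "alt", "qual")

recordSamples <- function(records) {
  s <- attr(records, "sample_ids")
  if (!is.null(s)) s else setdiff(colnames(records), RECORD_META)
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.2 file (through FORMAT/GT; QUAL and GT are the only
#' fields interpreted). Multi-allelic rows are split into one record per
#' ALT allele, with per-sample genotypes re-expressed as the dosage of that
#' ALT; row order is preserved. A QUAL of `"."` becomes `NA`.
#'
#' @param path VCF file.
#' @return records `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual` and one GT column (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`) per
#'   sample; sample ids in `attr(x, "sample_ids")`.
#' @examples
#' d <- CohortDesign("A", replicates = 1, genomeLength = 5000,
#'                   backgroundHetRate = 0.002, cloneSpecific = 0,
#'                   dropoutRate = 0, falsePositiveRate = 0)
#' ref <- generateReference(5000)
#' calls <- simulateCalls(plantCohort(d, ref), d, ref)
#' f <- tempfile(fileext = ".vcf")
#' writeVcfRecords(calls, f)
#' rec <- readVcfRecords(f)
#' nrow(rec) == nrow(calls)
#' @export
readVcfRecords <- function(path) {
  if (!file.exists(path)) parseError(paste0("no such file: ", path))
  head_lines <- readLines(path, n = 10000L)
  chromLine <- grep("^#CHROM\t", head_lines)
  if (!length(chromLine)) {
    parseError(sprintf(
      "malformed VCF header in '%s': no #CHROM line within the first %d lines",
      path, length(head_lines)))
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  samples <- setdiff(colnames(v@gt), "FORMAT")
  if (nrow(fix) == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- character()
    attr(out, "sample_ids") <- samples
    return(out)
  }
  gtField <- function(i) {
    if (length(samples) == 0L) return(character())
    raw <- v@gt[i, samples]
    fmt <- strsplit(v@gt[i, "FORMAT"], ":", fixed = TRUE)[[1L]]
    gi <- match("GT", fmt)
    if (is.na(gi)) {
      parseError(sprintf("record %d has no GT in FORMAT", i))
    }
    vapply(strsplit(raw, ":", fixed = TRUE),
           function(x) x[gi], character(1L))
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    gtRaw <- gtField(i)
    alleleLists <- strsplit(gtRaw, "[/|]")
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    sub <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      gt <- vapply(alleleLists, function(al) {
        if (any(al == ".") || any(is.na(al))) return("./.")
        dosageToGT(sum(al == as.character(k)))
      }, character(1L))
      rec <- data.frame(contig = fix[i, "CHROM"],
                        pos = as.integer(fix[i, "POS"]),
                        ref = fix[i, "REF"], alt = alts[k],
                        qual = qual, stringsAsFactors = FALSE)
      for (s in seq_along(samples)) rec[[samples[s]]] <- gt[s]
      sub[[k]] <- rec
    }
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sample_ids") <- samples
  out
}

#' Write variant records as a VCF 4.2 file
#'
#' @param records a records `data.frame` (see [readVcfRecords()]).
#' @param path output file.
#' @param contigLengths optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeVcfRecords <- function(records, path, contigLengths = NULL) {
  samples <- recordSamples(records)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ampliClone_%s",
                   as.character(utils::packageVersion("ampliClone"))))
  if (!is.null(contigLengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigLengths), as.integer(contigLengths)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  qual <- ifelse(is.na(records$qual), ".",
                 sub("\\.?0+$", "", sprintf("%.2f", records$qual)))
  body <- paste(records$contig, records$pos, ".", records$ref, records$alt,
                qual, ".", ".", "GT", sep = "\t")
  if (length(samples)) {
    gts <- do.call(paste, c(unname(records[samples]), list(sep = "\t")))
    body <- paste(body, gts, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify variants as SNV, InDel or other
#'
#' Single-base REF and ALT is an SNV; a length difference is an InDel;
#' equal-length multi-base substitutions are "other" and excluded from
#' SNV/InDel tallies.
#'
#' @param ref,alt allele vectors, or a records `data.frame` as `ref` (then
#'   `alt` is ignored).
#' @return character vector in `{"SNV","InDel","other"}`.
#' @examples
#' classifyVariant("G", "A")        # SNV
#' classifyVariant("CAG", "C")      # InDel
#' classifyVariant("AT", "GC")      # other
#' @export
classifyVariant <- function(ref, alt = NULL) {
  if (is.data.frame(ref)) { alt <- ref$alt; ref <- ref$ref }
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(nr != na, "InDel", "other"))
}

## normalize one variant: trim shared suffix (left-extending from the
## reference when an allele would empty), then trim shared prefix. This is
## the standard left-alignment, so equivalent representations of the same
## edit collapse to one canonical record.
normalizeOne <- function(pos, ref, alt, contigSeq) {
  if (substr(contigSeq, pos, pos + nchar(ref) - 1L) != ref) {
    referenceMismatch(sprintf(
      "REF '%s' does not match the reference at %d", ref, pos))
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      if ((nr == 1L || na == 1L) && pos == 1L) break  # cannot extend left
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- substr(contigSeq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant records against a reference
#'
#' Trims shared suffix then prefix and left-aligns InDels, so that
#' exclusivity comparisons are independent of how the caller represented
#' an edit. Idempotent; SNVs pass through unchanged.
#'
#' @param records a records `data.frame`.
#' @param reference [Biostrings::DNAStringSet] covering every contig named
#'   in `records`.
#' @return the records with canonical `pos`, `ref`, `alt`.
#' @export
normalizeVariant <- function(records, reference) {
  stopifnot(is(reference, "DNAStringSet"))
  if (nrow(records) == 0L) return(records)
  missing <- setdiff(unique(records$contig), names(reference))
  if (length(missing)) {
    referenceMismatch(paste0("reference does not cover contig(s): ",
                             paste(missing, collapse = ", ")))
  }
  seqs <- as.character(reference)
  for (i in seq_len(nrow(records))) {
    nm <- normalizeOne(records$pos[i], records$ref[i], records$alt[i],
                       seqs[[records$contig[i]]])
    records$pos[i] <- nm$pos
    records$ref[i] <- nm$ref
    records$alt[i] <- nm$alt
  }
  records
}

#' Filter records on site quality
#'
#' Keeps records whose QUAL is strictly greater than the threshold (the
#' conventional Q > 100 site filter for clonal variant calls); records with
#' missing QUAL are dropped.
#'
#' @param records a records `data.frame`.
#' @param threshold QUAL threshold (default 100).
#' @return the surviving subset, order preserved.
#' @export
qualityFilter <- function(records, threshold = 100) {
  keep <- !is.na(records$qual) & records$qual > threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- attr(records, "sample_ids")
  out
}

#' Read a sample-to-clone design table
#'
#' @param path TSV with columns `sample_id`, `clone_id` and optionally
#'   `cultivar` and `exclude` (logical; pre-declared outlier replicates).
#' @return a `data.frame`; excluded samples are dropped.
#' @export
readDesignTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("sample_id", "clone_id") %in% colnames(d))) {
    parseError("design table needs columns sample_id and clone_id")
  }
  if ("exclude" %in% colnames(d)) {
    d <- d[!(toupper(d$exclude) %in% c("TRUE", "T", "1", "YES")), ,
           drop = FALSE]
    d$exclude <- NULL
  }
  d
}

#' Assemble a genotype matrix from joint or per-sample records
#'
#' With a single (joint-genotyped) records data.frame, cells take the VCF
#' genotypes directly. With a named list of per-sample records, rows are
#' the union of sites; a site absent from a sample's file is recorded as
#' missing by default (the per-sample-calling interpretation), or as
#' dosage 0 with `missingAsZero = TRUE`.
#'
#' @param x a records `data.frame` (joint) or a named list of per-sample
#'   records (one GT column each, or none -- presence then implies a
#'   heterozygous call).
#' @param design data.frame mapping `sample_id` to `clone_id` (see
#'   [readDesignTable()]); every sample must be mapped.
#' @param missingAsZero for the per-sample merge: record absent
#'   site/sample combinations as dosage 0 instead of missing.
#' @return a [CloneCohort-class], sites sorted by (contig, position).
#' @export
buildMatrix <- function(x, design, missingAsZero = FALSE) {
  if (!all(c("sample_id", "clone_id") %in% colnames(design))) {
    invalidDesign("design must have sample_id and clone_id columns")
  }
  if (anyDuplicated(design$sample_id)) {
    invalidDesign("sample names must be unique")
  }
  if (is.data.frame(x)) {
    samples <- recordSamples(x)
    keys <- siteKey(x$contig, x$pos, x$ref, x$alt)
    checkMergeConflicts(x, keys)
    mat <- vapply(samples, function(s) gtToDosage(x[[s]]),
                  integer(nrow(x)))
    mat <- matrix(mat, nrow = nrow(x), ncol = length(samples),
                  dimnames = list(keys, samples))
    meta <- x[, RECORD_META, drop = FALSE]
  } else {
    samples <- names(x)
    if (is.null(samples) || any(samples == "")) {
      invalidDesign("per-sample records must be a named list")
    }
    allMeta <- do.call(rbind, lapply(x, function(r) {
      r[, RECORD_META, drop = FALSE]
    }))
    allKeys <- siteKey(allMeta$contig, allMeta$pos, allMeta$ref, allMeta$alt)
    keep <- !duplicated(allKeys)
    meta <- allMeta[keep, , drop = FALSE]
    keys <- allKeys[keep]
    checkMergeConflicts(meta, keys)
    fill <- if (missingAsZero) 0L else NA_integer_
    mat <- matrix(fill, nrow = length(keys), ncol = length(samples),
                  dimnames = list(keys, samples))
    for (s in samples) {
      r <- x[[s]]
      k <- siteKey(r$contig, r$pos, r$ref, r$alt)
      if (anyDuplicated(k)) {
        consistencyError(sprintf("duplicate site keys in sample '%s'", s))
      }
      gcols <- setdiff(colnames(r), RECORD_META)
      d <- if (length(gcols) >= 1L) gtToDosage(r[[gcols[1L]]]) else
        rep(1L, nrow(r))
      mat[match(k, keys), s] <- d
    }
  }
  unmapped <- setdiff(samples, design$sample_id)
  if (length(unmapped)) {
    invalidDesign(paste0("samples not in design table: ",
                         paste(unmapped, collapse = ", ")))
  }
  cloneOf <- setNames(design$clone_id, design$sample_id)
  o <- order(meta$contig, meta$pos, meta$ref, meta$alt)
  meta <- meta[o, , drop = FALSE]
  mat <- mat[o, , drop = FALSE]
  cd <- DataFrame(sample_id = samples,
                  clone_id = unname(cloneOf[samples]),
                  row.names = samples)
  if ("cultivar" %in% colnames(design)) {
    cv <- setNames(design$cultivar, design$sample_id)
    cd$cultivar <- unname(cv[samples])
  }
  rr <- GRanges(meta$contig,
                IRanges(start = meta$pos, width = nchar(meta$ref)))
  mcols(rr) <- DataFrame(ref = meta$ref, alt = meta$alt,
                         qual = if ("qual" %in% colnames(meta))
                           meta$qual else NA_real_)
  se <- SummarizedExperiment(assays = list(dosage = mat),
                             rowRanges = rr, colData = cd)
  new("CloneCohort", se)
}

checkMergeConflicts <- function(meta, keys) {
  if (anyDuplicated(keys)) {
    consistencyError("duplicate site keys (contig,pos,ref,alt) in input")
  }
  ## full keys are unique here, so a duplicated (contig,pos,alt) triple can
  ## only mean two different REF representations of the same site
  pa <- paste(meta$contig, meta$pos, meta$alt)
  if (anyDuplicated(pa)) {
    consistencyError(
      "conflicting REF alleles at the same position for the same ALT")
  }
  invisible(TRUE)
}

#' Export a cohort's dosage matrix as TSV
#'
#' @param cohort a [CloneCohort-class].
#' @param path output file; rows are site keys, columns samples.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(cohort, path) {
  m <- dosage(cohort)
  out <- data.frame(site = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
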