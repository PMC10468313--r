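test_that("VCF read/write round-trips records semantically", {
  d <- smallDesign(cloneSpecific = 25L, seed = 8L)
  out <- makeCohort(d)
  f <- tempfile(fileext = ".vcf")
  writeVcfRecords(out$calls, f,
                  stats::setNames(Biostrings::width(out$reference),
                                  names(out$reference)))
  rec <- readVcfRecords(f)
  expect_identical(rec$contig, out$calls$contig)
  expect_identical(rec$pos, out$calls$pos)
  expect_identical(rec$ref, out$calls$ref)
  expect_identical(rec$alt, out$calls$alt)
  expect_equal(rec$qual, out$calls$qual)
  for (s in truthSamples(out$truth)) {
    expect_identical(rec[[s]], out$calls[[s]])
  }
})

test_that("readVcfRecords handles headers, QUAL '.', and multi-allelics", {
  f <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", sep = "\t"))

  writeLines(hdr, f)
  expect_equal(nrow(readVcfRecords(f)), 0L)   # header-only VCF

  writeLines(c(hdr,
    "scaffold_356\t1788235\t.\tG\tA\t250\t.\t.\tGT\t0/1\t0/0",
    "c1\t10\t.\tA\tG,T\t.\t.\t.\tGT\t1/2\t./.",
    "c1\t50\t.\tT\tC\t99.5\t.\t.\tGT\t1|1\t0/1"), f)
  rec <- readVcfRecords(f)
  expect_equal(nrow(rec), 4L)                 # multi-allelic row split
  expect_identical(classifyVariant(rec[1, ]), "SNV")
  expect_identical(rec$contig[1], "scaffold_356")
  expect_equal(rec$pos[1], 1788235L)
  expect_true(is.na(rec$qual[2]))
  # per-ALT dosage of the 1/2 genotype is one for each alternate
  expect_identical(rec$s1[2:3], c("0/1", "0/1"))
  expect_identical(rec$s2[2:3], c("./.", "./."))
  expect_identical(rec$s1[4], "1/1")          # phased genotype parsed

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "no chrom line here"), bad)
  expect_error(readVcfRecords(bad), class = "ampliCloneParseError")
})

test_that("classifyVariant partitions records by allele lengths", {
  expect_identical(classifyVariant("G", "A"), "SNV")
  # allele lengths 180 vs 190 -> a 10-bp InDel
  expect_identical(classifyVariant(strrep("A", 11), "A"), "InDel")
  expect_identical(classifyVariant("AT", "GC"), "other")
  ref <- c("A", "ACGT", "AT", "C", "G")
  alt <- c("G", "A", "GC", "CTT", "T")
  cls <- classifyVariant(ref, alt)
  expect_equal(sum(cls == "SNV") + sum(cls == "InDel") +
                 sum(cls == "other"), length(ref))
})

test_that("normalizeVariant trims and left-aligns to the brute-force form", {
  seqs <- Biostrings::DNAStringSet(c(c1 = "TTACACACACGGTTGACCAGTCAGGTTACA"))
  cseq <- as.character(seqs[[1]])
  rec <- function(pos, ref, alt) {
    data.frame(contig = "c1", pos = pos, ref = ref, alt = alt, qual = 500,
               stringsAsFactors = FALSE)
  }

  # already-minimal SNV unchanged
  r <- normalizeVariant(rec(12L, "G", "C"), seqs)
  expect_identical(r[, c("pos", "ref", "alt")],
                   rec(12L, "G", "C")[, c("pos", "ref", "alt")])

  # right-shifted 2-bp deletion in the ACAC repeat equals the global-diff
  # oracle's left-aligned representation
  shifted <- rec(8L, "CAC", "C")
  got <- normalizeVariant(shifted, seqs)
  want <- globalDiffNormalize(8L, "CAC", "C", cseq)
  expect_equal(got$pos, want$pos)
  expect_identical(got$ref, want$ref)
  expect_identical(got$alt, want$alt)
  expect_equal(got$pos, 2L)  # leftmost anchor of the repeat run

  # shared-suffix trim: CAG>CG at pos 5 becomes a 1-bp deletion
  tri <- normalizeVariant(rec(5L, substr(cseq, 5, 7), # "CAC" here
                              paste0(substr(cseq, 5, 5),
                                     substr(cseq, 7, 7))), seqs)
  expect_equal(nchar(tri$ref) - nchar(tri$alt), 1L)

  # idempotence and haplotype preservation on random indels
  applyEdit <- function(pos, ref, alt) {
    paste0(substr(cseq, 1, pos - 1), alt,
           substr(cseq, pos + nchar(ref), nchar(cseq)))
  }
  set.seed(42)
  for (i in 1:25) {
    pos <- sample(2:25, 1)
    refLen <- sample(1:4, 1)
    ref <- substr(cseq, pos, pos + refLen - 1)
    alt <- if (runif(1) < 0.5) substr(ref, 1, 1) else
      paste0(ref, sample(c("A", "C", "G", "T"), 1))
    if (ref == alt) next
    r1 <- normalizeVariant(rec(pos, ref, alt), seqs)
    r2 <- normalizeVariant(r1, seqs)
    expect_identical(r1, r2)
    expect_identical(applyEdit(r1$pos, r1$ref, r1$alt),
                     applyEdit(pos, ref, alt))
    want <- globalDiffNormalize(pos, ref, alt, cseq)
    expect_equal(r1$pos, want$pos)
    expect_identical(r1$ref, want$ref)
    expect_identical(r1$alt, want$alt)
  }

  expect_error(normalizeVariant(rec(3L, "GGG", "G"), seqs),
               class = "ampliCloneReferenceMismatch")
})

test_that("qualityFilter keeps strictly greater QUAL and is monotone", {
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric())
  expect_equal(nrow(qualityFilter(empty)), 0L)

  rec <- data.frame(contig = "c", pos = 1:4, ref = "A", alt = "G",
                    qual = c(99, 100, 101, NA))
  kept <- qualityFilter(rec, 100)
  expect_equal(kept$qual, 101)      # strict inequality; NA dropped

  d <- smallDesign(genomeLength = 50000, cloneSpecific = 50L, seed = 12L,
                   backgroundHetRate = 0.005)
  d@qualModel <- list(trueMean = 120, trueSd = 40, falseMean = 60,
                      falseSd = 30)
  out <- makeCohort(d)
  calls <- out$calls
  for (thr in c(50, 100, 150)) {
    got <- qualityFilter(calls, thr)
    oracle <- 0L                     # brute-force scan
    for (i in seq_len(nrow(calls))) {
      if (!is.na(calls$qual[i]) && calls$qual[i] > thr) oracle <- oracle + 1L
    }
    expect_equal(nrow(got), oracle)
    expect_true(all(rownames(got) %in% rownames(calls)))
  }
  expect_true(nrow(qualityFilter(calls, 150)) <=
                nrow(qualityFilter(calls, 100)))
})

test_that("buildMatrix assembles joint and per-sample inputs correctly", {
  # joint records: cells equal VCF genotypes
  d <- smallDesign(cloneSpecific = 10L, seed = 14L)
  out <- makeCohort(d)
  m <- dosage(out$cohort)
  samples <- truthSamples(out$truth)
  for (s in samples) {
    expect_identical(unname(m[, s]),
                     ampliClone:::gtToDosage(out$calls[[s]]))
  }
  expect_identical(rownames(m), siteKeys(out$cohort))

  # per-sample merge with disjoint sites: off-diagonal cells missing
  r1 <- data.frame(contig = "c1", pos = 10L, ref = "A", alt = "G",
                   qual = 500, s1 = "0/1", stringsAsFactors = FALSE)
  r2 <- data.frame(contig = "c1", pos = 20L, ref = "C", alt = "T",
                   qual = 500, s2 = "1/1", stringsAsFactors = FALSE)
  des <- data.frame(sample_id = c("s1", "s2"), clone_id = c("X", "Y"))
  cc <- buildMatrix(list(s1 = r1, s2 = r2), des)
  expect_equal(dim(dosage(cc)), c(2L, 2L))
  expect_identical(unname(dosage(cc)[, "s1"]), c(1L, NA_integer_))
  expect_identical(unname(dosage(cc)[, "s2"]), c(NA_integer_, 2L))
  cc0 <- buildMatrix(list(s1 = r1, s2 = r2), des, missingAsZero = TRUE)
  expect_identical(unname(dosage(cc0)[, "s1"]), c(1L, 0L))

  # conflicting REF at one position is a merge conflict
  r3 <- data.frame(contig = "c1", pos = 10L, ref = "AT", alt = "G",
                   qual = 500, s2 = "0/1", stringsAsFactors = FALSE)
  expect_error(buildMatrix(list(s1 = r1, s2 = r3), des),
               class = "ampliCloneConsistencyError")
  expect_error(buildMatrix(list(s1 = r1, s2 = r2),
                           data.frame(sample_id = "s1", clone_id = "X")),
               class = "ampliCloneInvalidDesign")
})

test_that("the full study design yields one matrix column per replicate", {
  roster <- loadRoster(fixturePath("table1_design.tsv"))
  expect_equal(sum(roster$n_replicates), 46L)
  design <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_r%d", roster$cultivar[i],
                                   roster$clone_id[i],
                                   seq_len(roster$n_replicates[i])),
               clone_id = paste0(roster$cultivar[i], roster$clone_id[i]),
               cultivar = roster$cultivar[i], stringsAsFactors = FALSE)
  }))
  rec <- data.frame(contig = "c1", pos = 100L, ref = "A", alt = "G",
                    qual = 500, stringsAsFactors = FALSE)
  for (s in design$sample_id) rec[[s]] <- "0/1"
  attr(rec, "sample_ids") <- design$sample_id
  cohort <- buildMatrix(rec, design)
  expect_equal(ncol(cohort), 46L)
  expect_equal(length(cloneNames(cohort)), 18L)
})
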