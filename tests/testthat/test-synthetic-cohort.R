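test_that("generateReference honours length, contigs, GC and seed", {
  ref <- generateReference(10000, nContigs = 1L, gcFraction = 0.345,
                           seed = 1L)
  expect_equal(sum(Biostrings::width(ref)), 10000)
  expect_identical(names(ref), "contig_1")
  freq <- Biostrings::alphabetFrequency(ref, baseOnly = TRUE)[1L, ]
  gc <- (freq[["C"]] + freq[["G"]]) / 10000
  half <- 2.576 * sqrt(0.345 * 0.655 / 10000)  # binomial 99% interval
  expect_lt(abs(gc - 0.345), half)

  # seed determinism, byte-identical FASTA
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(generateReference(2000, 2L, 0.5, seed = 7L), f1)
  Biostrings::writeXStringSet(generateReference(2000, 2L, 0.5, seed = 7L), f2)
  expect_identical(readLines(f1), readLines(f2))
  ref2 <- generateReference(2001, nContigs = 2L, seed = 3L)
  expect_equal(Biostrings::width(ref2), c(1001L, 1000L))

  expect_error(generateReference(500), class = "ampliCloneInvalidDesign")
  expect_error(generateReference(5000, nContigs = 0),
               class = "ampliCloneInvalidDesign")
  expect_error(generateReference(5000, gcFraction = 1),
               class = "ampliCloneInvalidDesign")
})

test_that("CohortDesign validates its invariants", {
  expect_error(CohortDesign(c("A", "A")), class = "ampliCloneInvalidDesign")
  expect_error(CohortDesign("A", replicates = 0L),
               class = "ampliCloneInvalidDesign")
  expect_error(CohortDesign("A", genomeLength = 100),
               class = "ampliCloneInvalidDesign")
  expect_error(CohortDesign("A", dropoutRate = 1.5),
               class = "ampliCloneInvalidDesign")
  d <- CohortDesign(c("A", "B"), replicates = c(A = 1L, B = 3L),
                    genomeLength = 5000)
  expect_identical(designSamples(d)$sample_id,
                   c("A_r1", "B_r1", "B_r2", "B_r3"))
})

test_that("plantCohort plants exact counts with the right structure", {
  ref <- generateReference(20000, seed = 2L)

  # zero clone-specific counts leave only background
  d0 <- smallDesign(cloneSpecific = c(A = 0L, B = 0L), seed = 2L)
  t0 <- plantCohort(d0, ref)
  expect_true(all(t0$origin == "background"))

  d <- smallDesign(cloneSpecific = c(A = 5L, B = 3L), seed = 2L)
  truth <- plantCohort(d, ref)
  spec <- truth[truth$origin == "clone_specific", ]
  expect_equal(sum(spec$clone == "A"), 5L)
  expect_equal(sum(spec$clone == "B"), 3L)
  expect_false(anyDuplicated(truthKeys(truth)) > 0L)

  # exclusivity by construction: non-ref in all focal replicates, ref
  # elsewhere (direct scan)
  samples <- truthSamples(truth)
  cloneOf <- sub("_r\\d+$", "", samples)
  for (i in seq_len(nrow(spec))) {
    g <- unlist(spec[i, samples])
    expect_true(all(g[cloneOf == spec$clone[i]] > 0L))
    expect_true(all(g[cloneOf != spec$clone[i]] == 0L))
  }

  # background variants are heterozygous in every sample
  back <- truth[truth$origin == "background", samples]
  expect_true(all(back == 1L))

  # capacity: more variants than spaced positions available
  expect_error(
    plantCohort(smallDesign(genomeLength = 1000, cloneSpecific = 2000L),
                generateReference(1000)),
    class = "ampliCloneCapacityError")
})

test_that("planted variant composition tracks the design in expectation", {
  d <- CohortDesign(c("A", "B"), replicates = 2L, genomeLength = 6e5,
                    backgroundHetRate = 0.005, cloneSpecific = 1000L,
                    indelFraction = 0.3, tstvRatio = 2.1,
                    hetFractionSpecific = 0.94, dropoutRate = 0,
                    falsePositiveRate = 0, seed = 11L)
  ref <- generateReference(6e5, seed = 11L)
  truth <- plantCohort(d, ref)
  n <- nrow(truth)

  cls <- classifyVariant(truth$ref, truth$alt)
  pIndel <- mean(cls == "InDel")
  expect_lt(abs(pIndel - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  # Ts/Tv of planted SNVs within 3 SE of the design ratio
  snv <- cls == "SNV"
  pTs <- 2.1 / 3.1
  ts <- sum((truth$ref[snv] == "A" & truth$alt[snv] == "G") |
            (truth$ref[snv] == "G" & truth$alt[snv] == "A") |
            (truth$ref[snv] == "C" & truth$alt[snv] == "T") |
            (truth$ref[snv] == "T" & truth$alt[snv] == "C"))
  expect_lt(abs(ts / sum(snv) - pTs), 3 * sqrt(pTs * (1 - pTs) / sum(snv)))

  # heterozygous fraction of clone-specific variants
  spec <- truth$origin == "clone_specific"
  g <- ifelse(truth$clone[spec] == "A", truth$A_r1[spec], truth$B_r1[spec])
  pHet <- mean(g == 1L)
  expect_lt(abs(pHet - 0.94), 3 * sqrt(0.94 * 0.06 / sum(spec)))

  # deletions never overlap the next variant's position
  refLen <- nchar(truth$ref)
  byContig <- split(seq_len(n), truth$contig)
  for (idx in byContig) {
    ends <- truth$pos[idx] + refLen[idx] - 1L
    expect_true(all(ends[-length(idx)] < truth$pos[idx][-1L]))
  }
})

test_that("simulateCalls reproduces truth in the noiseless limit", {
  d <- smallDesign(cloneSpecific = 8L, seed = 4L)
  ref <- generateReference(20000, seed = 4L)
  truth <- plantCohort(d, ref)
  calls <- simulateCalls(truth, d, ref)
  samples <- truthSamples(truth)
  expect_equal(nrow(calls), nrow(truth))
  for (s in samples) {
    expect_identical(ampliClone:::gtToDosage(calls[[s]]),
                     unname(truth[[s]]))
  }
  # same seed twice -> identical VCF bytes
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  writeVcfRecords(simulateCalls(truth, d, ref), f1)
  writeVcfRecords(simulateCalls(truth, d, ref), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dropout removes calls at the configured binomial rate", {
  d <- CohortDesign("A", replicates = 1L, genomeLength = 2e5,
                    backgroundHetRate = 0.005, cloneSpecific = 0L,
                    dropoutRate = 0.3, falsePositiveRate = 0, seed = 9L)
  ref <- generateReference(2e5, seed = 9L)
  truth <- plantCohort(d, ref)
  n <- nrow(truth)
  expect_equal(n, 1000L)  # 0.005/bp on 200 kbp
  calls <- simulateCalls(truth, d, ref)
  nMissing <- sum(calls$A_r1 == "./.")
  half <- 2.576 * sqrt(n * 0.3 * 0.7)  # binomial 99% interval
  expect_lt(abs(nMissing - 0.3 * n), half)
})

test_that("false positives are low-QUAL singletons", {
  d <- CohortDesign(c("A", "B"), replicates = 2L, genomeLength = 1e5,
                    backgroundHetRate = 0.001, cloneSpecific = 0L,
                    dropoutRate = 0, falsePositiveRate = 2e-3, seed = 6L)
  ref <- generateReference(1e5, seed = 6L)
  truth <- plantCohort(d, ref)
  calls <- simulateCalls(truth, d, ref)
  callKeys <- ampliClone:::siteKey(calls$contig, calls$pos,
                                   calls$ref, calls$alt)
  fp <- calls[!(callKeys %in% truthKeys(truth)), ]
  expect_gt(nrow(fp), 0L)
  samples <- truthSamples(truth)
  carriers <- rowSums(fp[, samples] != "0/0")
  expect_true(all(carriers == 1L))                 # singletons
  expect_lt(mean(fp$qual), 150)                    # biased low
  expect_gt(mean(calls$qual[callKeys %in% truthKeys(truth)]), 500)
})

test_that("simulateAmpliconReads returns reads matching its drawn counts", {
  mk <- list(marker_id = "m1", seq_a = "ACGTACGTACGTACGTAAAT",
             seq_b = "ACGTACGTTCGTACGTAAAT")  # SNV at offset 9

  z <- simulateAmpliconReads(mk, "het", depth = 0)
  expect_identical(z$reads, character())
  expect_identical(unname(z$counts), c(0L, 0L))

  s <- simulateAmpliconReads(mk, "het", depth = 200, alleleBias = 0.5,
                             perBaseError = 0, seed = 3L)
  ac <- countAlleles(s$reads, mk)
  expect_identical(ac$count_a, unname(s$counts["a"]))
  expect_identical(ac$count_b, unname(s$counts["b"]))
  expect_identical(ac$unassigned, 0L)

  h <- simulateAmpliconReads(mk, "hom_a", depth = 100, perBaseError = 0,
                             seed = 5L)
  expect_true(all(h$reads == mk$seq_a))
  expect_identical(unname(h$counts), c(100L, 0L))

  # determinism
  s2 <- simulateAmpliconReads(mk, "het", depth = 200, alleleBias = 0.5,
                              perBaseError = 0.01, seed = 3L)
  s3 <- simulateAmpliconReads(mk, "het", depth = 200, alleleBias = 0.5,
                              perBaseError = 0.01, seed = 3L)
  expect_identical(s2$reads, s3$reads)

  expect_error(simulateAmpliconReads(list(marker_id = "x"), "het", 10),
               class = "ampliCloneConfigError")
})
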