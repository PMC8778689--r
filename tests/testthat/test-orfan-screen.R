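mkHits <- function(ids) {
  if (!length(ids)) {
    f <- tempfile()
    writeLines(character(), f)
    return(readHitTable(f))
  }
  data.frame(queryId = ids, subjectId = "ref", pctIdentity = 90,
             alnLen = 100, mismatches = 10, gapOpens = 0, qStart = 1,
             qEnd = 100, sStart = 1, sEnd = 100, evalue = 1e-50,
             bitscore = 200, stringsAsFactors = FALSE)
}

test_that("homology removal keeps exactly the unmatched contigs", {
  set.seed(51)
  contigs <- Biostrings::DNAStringSet(
    setNames(replicate(3, randomDna(100)), c("c1", "c2", "c3")))
  expect_equal(names(removeHomologous(contigs, mkHits("c2"))),
               c("c1", "c3"))
  expect_equal(names(removeHomologous(contigs, mkHits(character()))),
               c("c1", "c2", "c3"))
  expect_length(removeHomologous(contigs, mkHits(c("c1", "c2", "c3"))), 0L)
  expect_warning(removeHomologous(contigs, mkHits("nope")), "unknown")
})

## a contig with a planted forward ORF of a given aa length
plantedContig <- function(lenNt, orfAa, seed) {
  set.seed(seed)
  vir <- generateVirome(viromeConfig(seed = seed, nHost = 0, elements = list(
    elementSpec("orfan_like", length = lenNt, id = "x",
                features = list(orfAa = orfAa)))))
  vir$contigs
}

test_that("the verdict flags reflect each criterion independently", {
  ctg <- plantedContig(1200L, 200L, seed = 52)
  good <- evaluateOrfan(ctg, list(nSense = 100L, nAntisense = 15L))
  expect_true(good$passed)
  expect_equal(good$antisenseRatio, 0.15)

  short <- plantedContig(900L, 200L, seed = 53)
  v <- evaluateOrfan(short, list(nSense = 100L, nAntisense = 15L))
  expect_false(v$lenOk)
  expect_false(v$passed)

  # boundary: "over 1 kb" is strict
  atBoundary <- plantedContig(1000L, 200L, seed = 54)
  expect_false(evaluateOrfan(atBoundary,
                             list(nSense = 100L, nAntisense = 15L))$lenOk)

  oneStrand <- evaluateOrfan(ctg, list(nSense = 100L, nAntisense = 0L))
  expect_false(oneStrand$bothStrandsOk)
  expect_false(oneStrand$passed)

  lowRatio <- evaluateOrfan(ctg, list(nSense = 100L, nAntisense = 5L))
  expect_true(lowRatio$bothStrandsOk)
  expect_false(lowRatio$ratioOk)

  noReads <- evaluateOrfan(ctg, list(nSense = 0L, nAntisense = 0L))
  expect_false(noReads$bothStrandsOk)
  expect_true(is.na(noReads$antisenseRatio))
})

test_that("sense is defined by the longest ORF, so verdicts are orientation
           invariant", {
  ctg <- plantedContig(1400L, 250L, seed = 55)
  rc <- Biostrings::reverseComplement(ctg)
  names(rc) <- names(ctg)
  counts <- list(nSense = 120L, nAntisense = 30L)
  fwd <- evaluateOrfan(ctg, counts)
  # the same physical reads now count against the flipped contig strands
  rev <- evaluateOrfan(rc, list(nSense = 30L, nAntisense = 120L))
  expect_equal(fwd$passed, rev$passed)
  expect_equal(fwd$antisenseRatio, rev$antisenseRatio)
  expect_equal(rev$senseStrand, "-")
})

test_that("antisense-dominant contigs pass the lower-bound ratio rule", {
  ctg <- plantedContig(1200L, 200L, seed = 56)
  v <- evaluateOrfan(ctg, list(nSense = 40L, nAntisense = 90L))
  expect_true(v$ratioOk)
  expect_true(v$passed)
})

test_that("raising any threshold never increases the passing set", {
  config <- defaultViromeConfig(seed = 57)
  vir <- generateVirome(config)
  reads <- simulateReads(vir$contigs, vir$truth, config)
  idx <- buildKmerIndex(vir$contigs, 21)
  counts <- countStrands(idx, reads)
  hits <- emitHitTable(vir$truth)
  base <- orfanParams()
  suppressMessages({
    n0 <- sum(screenOrfans(vir$contigs, hits, counts, base)$passed)
    stricter <- list(
      orfanParams(minContigLen = 1400),
      orfanParams(minProteinLen = 400),
      orfanParams(minStrandRatio = 0.3))
    for (p in stricter)
      expect_lte(sum(screenOrfans(vir$contigs, hits, counts, p)$passed), n0)
    # ratio 1.0 keeps only antisense-dominant contigs
    v1 <- screenOrfans(vir$contigs, hits, counts,
                       orfanParams(minStrandRatio = 1))
    expect_true(all(v1$antisenseRatio[v1$passed] >= 1))
  })
})

test_that("a DNA-positive ORFan is flagged genomic and leaves the viral
           pool", {
  ctg <- plantedContig(1200L, 200L, seed = 58)
  v <- evaluateOrfan(ctg, list(nSense = 100L, nAntisense = 20L),
                     dnaPositive = TRUE)
  expect_true(v$passed)          # the sequence filters still pass
  expect_true(v$genomicOrigin)   # but the element is genome-encoded
  expect_false(v$viralCandidate)
  rna <- evaluateOrfan(ctg, list(nSense = 100L, nAntisense = 20L),
                       dnaPositive = FALSE)
  expect_true(rna$viralCandidate)
})

test_that("screening an empty contig set yields an empty report", {
  suppressMessages(
    v <- screenOrfans(Biostrings::DNAStringSet(), mkHits(character()),
                      list(nSense = 0L, nAntisense = 0L)))
  expect_equal(nrow(v), 0L)
})
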