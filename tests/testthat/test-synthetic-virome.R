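test_that("identical configurations and seeds reproduce byte-identical
           output", {
  c1 <- defaultViromeConfig(seed = 71)
  v1 <- generateVirome(c1)
  v2 <- generateVirome(defaultViromeConfig(seed = 71))
  expect_identical(as.character(v1$contigs), as.character(v2$contigs))
  expect_identical(as.data.frame(v1$truth), as.data.frame(v2$truth))
  r1 <- simulateReads(v1$contigs, v1$truth, c1)
  r2 <- simulateReads(v2$contigs, v2$truth, c1)
  expect_identical(as.character(r1), as.character(r2))

  v3 <- generateVirome(defaultViromeConfig(seed = 72))
  expect_false(identical(as.character(v1$contigs),
                         as.character(v3$contigs)))
})

test_that("every emitted contig appears exactly once in the manifest", {
  vir <- generateVirome(defaultViromeConfig(seed = 73))
  expect_identical(names(vir$contigs), vir$truth$contigId)
  expect_false(anyDuplicated(vir$truth$contigId) > 0)
  expect_equal(Biostrings::width(vir$contigs),
               vir$truth$lengthNt)
})

test_that("mito-like elements split under the standard code but not the
           mitochondrial one", {
  vir <- generateVirome(viromeConfig(seed = 74, nHost = 0, elements = list(
    elementSpec("mito_mono", id = "m1"))))
  feat <- S4Vectors::metadata(vir$truth)$features[["m1"]]
  mold <- findOrfs(vir$contigs[["m1"]], "mold_mitochondrial", minAa = 150)
  expect_equal(c(mold$start[1], mold$end[1]), unname(feat$orf))
  std <- findOrfs(vir$contigs[["m1"]], "standard", minAa = 150)
  # the TGA tryptophan truncates the standard-code reading
  expect_true(nrow(std) == 0 || std$proteinLen[1] < mold$proteinLen[1])
})

test_that("bipartite elements emit linked RNA1/RNA2 segments", {
  vir <- generateVirome(viromeConfig(seed = 75, nHost = 0, elements = list(
    elementSpec("partiti_bipartite", id = "p1"))))
  expect_setequal(vir$truth$contigId, c("p1_RNA1", "p1_RNA2"))
  feats <- S4Vectors::metadata(vir$truth)$features
  expect_equal(feats[["p1_RNA1"]]$segment, "RNA1")
  expect_equal(feats[["p1_RNA2"]]$segment, "RNA2")
})

test_that("mutateToIdentity plants an exact substitution count", {
  set.seed(76)
  base <- randomDna(1000)
  m <- mutateToIdentity(base, 90, seed = 77)
  diffs <- sum(strsplit(base, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diffs, 100L)
  expect_equal(nchar(m), 1000L)

  expect_identical(mutateToIdentity(base, 100, seed = 78), base)
  expect_error(mutateToIdentity(base, 20, seed = 79), "noise floor")
})

test_that("simulated reads honour the planted strand fractions", {
  config <- viromeConfig(seed = 80, nHost = 1, hostLen = c(1500L, 1500L),
                         elements = list(
                           elementSpec("orfan_like", antisenseFrac = 0,
                                       id = "e0")),
                         depth = 300)
  vir <- generateVirome(config)
  reads <- simulateReads(vir$contigs, vir$truth, config)
  mc <- S4Vectors::mcols(reads)
  fromE0 <- mc$truthStrand[mc$sourceContig == "e0"]
  expect_true(all(fromE0 == "sense"))
  # error-free reads are exact (anti-)substrings of their source contig
  i <- which(mc$sourceContig == "e0")[1]
  expect_true(grepl(as.character(reads[[i]]),
                    as.character(vir$contigs[["e0"]]), fixed = TRUE))
})

test_that("reads round-trip through FASTQ with their truth tags", {
  config <- viromeConfig(seed = 81, nHost = 2, elements = list(), depth = 20)
  vir <- generateVirome(config)
  reads <- simulateReads(vir$contigs, vir$truth, config)
  f <- tempfile(fileext = ".fastq")
  writeReads(reads, f)
  back <- readReads(f)
  expect_identical(as.character(back), as.character(reads))
  expect_identical(S4Vectors::mcols(back)$truthStrand,
                   S4Vectors::mcols(reads)$truthStrand)
})

test_that("the hit table covers hosts and known viruses but never ORFans", {
  vir <- generateVirome(defaultViromeConfig(seed = 82))
  hits <- emitHitTable(vir$truth)
  orfans <- vir$truth$contigId[vir$truth$kind == "orfan_like"]
  expect_length(intersect(hits$queryId, orfans), 0L)
  others <- setdiff(vir$truth$contigId, orfans)
  expect_setequal(hits$queryId, others)

  # all-host fixture: every contig is hit
  hostOnly <- generateVirome(viromeConfig(seed = 83, nHost = 5,
                                          elements = list()))
  expect_setequal(emitHitTable(hostOnly$truth)$queryId,
                  hostOnly$truth$contigId)
})

test_that("infeasible element specifications are rejected", {
  expect_error(
    generateVirome(viromeConfig(seed = 84, nHost = 0, elements = list(
      elementSpec("satellite_toxin", length = 200L, id = "bad")))),
    "268")
})
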