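mkContigs <- function(...) Biostrings::DNAStringSet(c(...))

test_that("the index covers both strands and rejects bad input", {
  set.seed(11)
  ctg <- mkContigs(c1 = randomDna(60))
  idx <- buildKmerIndex(ctg, k = 21)
  expect_equal(kmerSize(idx), 21L)
  expect_equal(indexedContigs(idx), "c1")
  # a forward k-mer and its reverse complement index opposite strands
  fwd <- substr(as.character(ctg[[1]]), 1, 21)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(assignRead(idx, fwd)$strand, "+")
  expect_equal(assignRead(idx, rc)$strand, "-")

  expect_error(buildKmerIndex(Biostrings::AAStringSet(c(p = "MKV"))))
  expect_error(buildKmerIndex(ctg, k = 20), "odd")
})

test_that("exact reads assign to their contig with the right orientation", {
  set.seed(12)
  ctg <- mkContigs(c1 = randomDna(500), c2 = randomDna(500))
  idx <- buildKmerIndex(ctg, k = 21)
  frag <- substr(as.character(ctg[["c1"]]), 101, 200)
  a <- assignRead(idx, frag)
  expect_equal(a$status, "assigned")
  expect_equal(a$contig, "c1")
  expect_equal(a$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  b <- assignRead(idx, rc)
  expect_equal(b$contig, "c1")
  expect_equal(b$strand, "-")
})

test_that("ties are ambiguous and weak or short reads are unassigned", {
  set.seed(13)
  shared <- randomDna(120)
  ctg <- mkContigs(c1 = shared, c2 = shared)  # identical contigs: always tie
  idx <- buildKmerIndex(ctg, k = 21)
  expect_equal(assignRead(idx, substr(shared, 1, 80))$status, "ambiguous")

  lone <- mkContigs(c1 = randomDna(200))
  idx2 <- buildKmerIndex(lone, k = 21)
  expect_equal(assignRead(idx2, randomDna(80))$status, "unassigned")
  expect_warning(short <- assignRead(idx2, "ACGT"), "shorter than k")
  expect_equal(short$status, "unassigned")

  emptyIdx <- buildKmerIndex(mkContigs(), k = 21)
  expect_equal(assignRead(emptyIdx, randomDna(50))$status, "unassigned")
})

test_that("strand counts are conserved and match planted strand totals", {
  set.seed(14)
  ctg <- mkContigs(c1 = randomDna(800))
  idx <- buildKmerIndex(ctg, k = 21)
  s <- as.character(ctg[[1]])
  starts <- sample(1:(800 - 99), 120, replace = TRUE)
  frags <- substring(s, starts, starts + 99)
  anti <- c(rep(TRUE, 20), rep(FALSE, 100))
  frags[anti] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(frags[anti])))
  reads <- Biostrings::DNAStringSet(setNames(frags, sprintf("r%03d", 1:120)))
  counts <- countStrands(idx, reads)
  expect_equal(unname(senseCounts(counts)["c1"]), 100)
  expect_equal(unname(antisenseCounts(counts)["c1"]), 20)
  df <- as.data.frame(counts)
  expect_equal(sum(df$nSense) + sum(df$nAntisense) +
                 df$nAmbiguous[1] + df$nUnassigned[1], 120)
})

test_that("reverse-complementing every read swaps the strand tallies", {
  set.seed(15)
  ctg <- mkContigs(c1 = randomDna(600), c2 = randomDna(700))
  idx <- buildKmerIndex(ctg, k = 21)
  frags <- character(60)
  for (i in 1:60) {
    src <- sample(names(ctg), 1)
    s <- as.character(ctg[[src]])
    st <- sample(seq_len(nchar(s) - 79), 1)
    frag <- substr(s, st, st + 79)
    if (runif(1) < 0.3)
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    frags[i] <- frag
  }
  reads <- Biostrings::DNAStringSet(setNames(frags, sprintf("r%02d", 1:60)))
  flipped <- Biostrings::reverseComplement(reads)
  names(flipped) <- names(reads)
  a <- countStrands(idx, reads)
  b <- countStrands(idx, flipped)
  expect_equal(senseCounts(a), antisenseCounts(b))
  expect_equal(antisenseCounts(a), senseCounts(b))
})

test_that("recovered antisense fraction sits inside the binomial interval", {
  config <- viromeConfig(seed = 99, nHost = 0, elements = list(
    elementSpec("orfan_like", antisenseFrac = 0.2, id = "e1")),
    depth = 2000)
  vir <- generateVirome(config)
  reads <- simulateReads(vir$contigs, vir$truth, config)
  idx <- buildKmerIndex(vir$contigs, 21)
  counts <- countStrands(idx, reads)
  nS <- unname(senseCounts(counts)["e1"])
  nA <- unname(antisenseCounts(counts)["e1"])
  n <- nS + nA
  # 99% binomial interval for the planted antisense fraction
  lo <- qbinom(0.005, n, 0.2) / n
  hi <- qbinom(0.995, n, 0.2) / n
  expect_gte(nA / n, lo)
  expect_lte(nA / n, hi)
  # truth tags produce a diagonal confusion matrix on error-free reads
  cm <- strandConfusion(counts)
  expect_equal(sum(cm["sense", "antisense"], cm["antisense", "sense"]), 0)
})
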