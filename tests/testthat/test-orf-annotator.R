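test_that("findOrfs matches worked micro-examples under both codes", {
  one <- findOrfs("ATGAAATAA", minAa = 1)
  expect_equal(one$protein, "MK")
  expect_equal(c(one$start, one$end), c(1L, 9L))

  std <- findOrfs("ATGTGATAA", "standard", minAa = 2)
  expect_equal(nrow(std), 0L)  # TGA terminates immediately
  mold <- findOrfs("ATGTGATAA", "mold_mitochondrial", minAa = 2)
  expect_equal(mold$protein, "MW")  # TGA reads through as Trp
})

test_that("findOrfs equals the brute-force oracle on random sequences", {
  set.seed(21)
  for (rep in 1:12) {
    L <- sample(100:2000, 1)
    s <- randomDna(L)
    for (code in c("standard", "mold_mitochondrial")) {
      got <- as.data.frame(findOrfs(s, code, minAa = 1))
      got <- got[order(got$start, got$end, got$strand),
                 c("start", "end", "strand", "proteinLen")]
      rownames(got) <- NULL
      want <- bruteForceOrfs(s, code, minAa = 1)
      rownames(want) <- NULL
      expect_equal(got, want, info = paste("rep", rep, code))
    }
  }
})

test_that("ORFs of the reverse complement are coordinate-mirrored", {
  set.seed(22)
  s <- randomDna(900)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- as.data.frame(findOrfs(s, minAa = 1))
  b <- as.data.frame(findOrfs(rc, minAa = 1))
  L <- nchar(s)
  mirrored <- data.frame(start = L - b$end + 1L, end = L - b$start + 1L,
                         strand = ifelse(b$strand == "+", "-", "+"),
                         proteinLen = b$proteinLen)
  key <- function(d) do.call(paste, d[order(d$start, d$end, d$strand),
                                      c("start", "end", "strand",
                                        "proteinLen")])
  expect_equal(key(a[c("start", "end", "strand", "proteinLen")]),
               key(mirrored))
})

test_that("slippage overlaps are located with frame shift and RNA alphabet", {
  # toy: two ORFs overlapping by 3 nt in the same frame layout
  orfA <- list(contigId = "c", start = 1L, end = 9L, strand = "+", frame = 1L)
  orfB <- list(contigId = "c", start = 7L, end = 15L, strand = "+",
               frame = 1L)
  ov <- detectSlippageOverlap(orfA, orfB, "ATGAAATGAAATAAG")
  expect_equal(c(ov$overlapStart, ov$overlapEnd), c(7L, 9L))
  expect_equal(nchar(ov$overlapSeq), 3L)

  disjoint <- list(contigId = "c", start = 11L, end = 15L, strand = "+",
                   frame = 2L)
  expect_null(detectSlippageOverlap(orfA, disjoint, "ATGAAATGAAATAAG"))

  other <- list(contigId = "d", start = 1L, end = 9L, strand = "+",
                frame = 1L)
  expect_error(detectSlippageOverlap(orfA, other, "ATGAAATGAAATAAG"),
               "different contigs")

  # generated bicistronic element: planted AUGA overlap in the -1 frame
  vir <- generateVirome(viromeConfig(seed = 5, nHost = 0, elements = list(
    elementSpec("toti_bicistronic", id = "t1"))))
  feat <- S4Vectors::metadata(vir$truth)$features[["t1"]]
  orfs <- findOrfs(vir$contigs[["t1"]], "standard", minAa = 150)
  i1 <- which(orfs$start == feat$orf1[1] & orfs$end == feat$orf1[2])
  i2 <- which(orfs$start == feat$orf2[1] & orfs$end == feat$orf2[2])
  ov2 <- detectSlippageOverlap(orfs[i1, ], orfs[i2, ], vir$contigs[["t1"]])
  expect_equal(ov2$overlapSeq, "AUGA")
  expect_equal(ov2$frameshift, -1L)
  expect_equal(c(ov2$overlapStart, ov2$overlapEnd), unname(feat$slippage))
})

test_that("motif scan finds GDD exactly and flags incomplete series", {
  p <- paste0(strrep("A", 50), "GDD", strrep("A", 50))
  hits <- scanRdrpMotifs(p)
  gdd <- hits[hits$motifId == "GDD", ]
  expect_equal(gdd$start, 51L)
  expect_equal(gdd$matchedSeq, "GDD")
  expect_true(S4Vectors::metadata(hits)$incompleteSeries)
})

test_that("motif scan recovers the planted series on a mito-like element", {
  vir <- generateVirome(viromeConfig(seed = 6, nHost = 0, elements = list(
    elementSpec("mito_mono", id = "m1"))))
  feat <- S4Vectors::metadata(vir$truth)$features[["m1"]]
  hits <- scanRdrpMotifs(feat$protein)
  core <- hits[hits$motifId %in% c("I", "II", "III", "IV", "V", "VI"), ]
  expect_equal(nrow(core), 6L)
  expect_false(is.unsorted(core$start, strictly = TRUE))
  expect_false(S4Vectors::metadata(hits)$incompleteSeries)
  expect_equal(core$start[core$motifId == "IV"],
               unname(feat$motifStarts[["IV"]]))
  # the GDD core sits inside motif IV
  expect_true((feat$motifStarts[["IV"]] + 3L) %in%
                hits$start[hits$motifId == "GDD"])
})

test_that("motif scan positions shift by exactly a prepended prefix", {
  vir <- generateVirome(viromeConfig(seed = 7, nHost = 0, elements = list(
    elementSpec("mito_mono", id = "m1"))))
  p <- S4Vectors::metadata(vir$truth)$features[["m1"]]$protein
  base <- scanRdrpMotifs(p)
  shifted <- scanRdrpMotifs(paste0(strrep("P", 17), p))
  # proline prefix matches no pattern class, so every hit moves by 17
  for (id in base$motifId) {
    expect_equal(shifted$start[shifted$motifId == id][1],
                 base$start[base$motifId == id][1] + 17L, info = id)
  }
})

test_that("K2 preprotoxin checklist passes constructed positives and names
           failing cleavage sites", {
  vir <- generateVirome(viromeConfig(seed = 8, nHost = 0, elements = list(
    elementSpec("satellite_toxin", id = "s1"))))
  p <- S4Vectors::metadata(vir$truth)$features[["s1"]]$protein
  rep <- validateK2Preprotoxin(p)
  expect_true(all(rep$features$pass))

  # lysine -> glutamic acid at the first KR site
  mut <- p
  substr(mut, 220, 220) <- "E"
  rep2 <- validateK2Preprotoxin(mut, reference = p)
  kex1 <- rep2$features[grepl("kex1", rep2$features$feature), ]
  expect_false(kex1$pass)
  expect_match(kex1$detail, "ER")  # the observed dipeptide is named
  expect_equal(rep2$substitutions,
               data.frame(position = 220L, referenceAa = "K",
                          observedAa = "E", stringsAsFactors = FALSE))

  # truncated proteins get partial reports, not errors
  rep3 <- validateK2Preprotoxin(substr(p, 1, 100))
  later <- rep3$features[!grepl("hydrophobic", rep3$features$feature), ]
  expect_true(all(is.na(later$pass)))
  expect_match(later$detail[1], "not evaluable")

  expect_error(validateK2Preprotoxin("ACGT123"), "protein")
})

test_that("premature stops are reported by first-nt position in the region", {
  ps <- detectPrematureStop("ATGAAATAGAAATAA", c(1, 15))
  expect_equal(ps$positions, 7L)
  expect_true(ps$defective)

  clean <- detectPrematureStop("ATGAAATAA", c(1, 9))
  expect_false(clean$defective)
  expect_length(clean$positions, 0L)

  expect_warning(detectPrematureStop("ATGAAATAGA", c(1, 10)), "multiple of 3")

  # satellite element with a planted stop at nt 232 of its toxin ORF
  vir <- generateVirome(viromeConfig(seed = 9, nHost = 0, elements = list(
    elementSpec("satellite_toxin", id = "s1",
                features = list(prematureStopNt = 232L)))))
  feat <- S4Vectors::metadata(vir$truth)$features[["s1"]]
  ps2 <- detectPrematureStop(vir$contigs[["s1"]], feat$orf)
  expect_true(ps2$defective)
  expect_equal(ps2$positions, 232L)
})

test_that("generated coding regions without planted stops are never
           defective", {
  vir <- generateVirome(defaultViromeConfig(seed = 31))
  feats <- S4Vectors::metadata(vir$truth)$features
  for (id in names(feats)) {
    feat <- feats[[id]]
    if (is.null(feat$orf) || !is.null(feat$prematureStopNt)) next
    code <- vir$truth$geneticCode[match(id, vir$truth$contigId)]
    ps <- detectPrematureStop(vir$contigs[[id]], feat$orf, code)
    expect_false(ps$defective, info = id)
  }
})
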