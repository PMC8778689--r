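#' Parameters of the ORFan replication screen
#'
#' @param minContigLen Minimum contig length in nt; contigs must be strictly
#'   longer ("over 1 kb"). Default 1000.
#' @param minProteinLen Minimum length of the longest encoded protein in
#'   amino acids (~15 kDa), stop excluded. Default 150.
#' @param minStrandRatio Floor on the antisense/sense read ratio — the
#'   replication-intermediate signature ("around 1/10"). Default 0.1.
#' @param evalueMax Homology e-value cutoff used when filtering the hit
#'   table. Default 1e-5.
#' @return A validated list of class `OrfanParams`.
#' @export
orfanParams <- function(minContigLen = 1000L, minProteinLen = 150L,
                        minStrandRatio = 0.1, evalueMax = 1e-5) {
  stopifnot(minContigLen > 0, minProteinLen > 0,
            minStrandRatio > 0, minStrandRatio <= 1, evalueMax >= 0)
  structure(list(minContigLen = as.integer(minContigLen),
                 minProteinLen = as.integer(minProteinLen),
                 minStrandRatio = minStrandRatio,
                 evalueMax = evalueMax),
            class = "OrfanParams")
}

#' Remove contigs with database homology
#'
#' Keeps exactly the contigs with no hit at `evalue <= evalueMax` in the
#' supplied homology table — the survivors are the candidate ORFan pool.
#' Hit rows whose query id does not match any contig are ignored with a
#' warning.
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param hits A hit table from [readHitTable()].
#' @param evalueMax E-value cutoff.
#' @return The subset of `contigs` without qualifying hits.
#' @export
removeHomologous <- function(contigs, hits, evalueMax = 1e-5) {
  stopifnot(methods::is(contigs, "DNAStringSet"))
  if (length(contigs) == 0L) return(contigs)
  stopifnot(!is.null(names(contigs)))
  qualifying <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  unknown <- setdiff(unique(qualifying$queryId), names(contigs))
  if (length(unknown))
    warning("hit table references unknown contig id(s): ",
            paste(head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  contigs[!(names(contigs) %in% qualifying$queryId)]
}

.strandCountsFor <- function(counts, contigId) {
  if (methods::is(counts, "StrandCounts")) {
    i <- match(contigId, counts@counts$contigId)
    if (is.na(i)) return(c(nSense = 0L, nAntisense = 0L))
    return(c(nSense = counts@counts$nSense[i],
             nAntisense = counts@counts$nAntisense[i]))
  }
  stopifnot(all(c("nSense", "nAntisense") %in% names(counts)))
  c(nSense = as.integer(counts[["nSense"]]),
    nAntisense = as.integer(counts[["nAntisense"]]))
}

#' Evaluate one contig against the ORFan screen criteria
#'
#' Applies the length, ORF-size and strand-signature rules. The contig is
#' oriented so that the strand carrying its longest ORF defines "sense"
#' (assembler contig orientation is arbitrary; the signature targets a
#' coding RNA), then the antisense/sense read ratio is computed. A contig
#' passes when it is longer than `minContigLen`, encodes a protein of at
#' least `minProteinLen` aa, has reads on both strands, and its ratio
#' reaches `minStrandRatio` (antisense-dominant ratios above 1 also pass).
#' The ratio is undefined (NA) when the sense count is zero.
#'
#' An optional `dnaPositive` flag records the nucleic-acid verification
#' outcome (signal on total nucleic acid, not only cDNA): a DNA-positive
#' contig is flagged as of genomic origin and excluded from the viral pool
#' even when the sequence filters pass.
#'
#' @param contig A single named [Biostrings::DNAStringSet] element (or
#'   `DNAString` plus `contigId`).
#' @param counts A [StrandCounts] (or a list with `nSense`/`nAntisense` for
#'   this contig), with strands relative to the stored contig orientation.
#' @param params An [orfanParams()] list.
#' @param orfs Optional precomputed [findOrfs()] table for this contig
#'   (standard code, `minAa = 1`); computed when `NULL`.
#' @param dnaPositive Optional logical: `TRUE` if the contig sequence was
#'   also detected as DNA.
#' @param contigId Contig id (defaults to the sequence name).
#' @return A one-row [S4Vectors::DataFrame] with the verdict flags
#'   (`lenOk`, `orfOk`, `bothStrandsOk`, `ratioOk`, `passed`,
#'   `genomicOrigin`, `viralCandidate`), the `antisenseRatio` and the
#'   longest ORF length in aa.
#' @export
evaluateOrfan <- function(contig, counts, params = orfanParams(),
                          orfs = NULL, dnaPositive = NA,
                          contigId = NULL) {
  if (methods::is(contig, "DNAStringSet")) {
    stopifnot(length(contig) == 1L)
    if (is.null(contigId)) contigId <- names(contig)[1L]
    dna <- contig[[1L]]
  } else dna <- .asDnaString(contig)
  if (is.null(contigId)) contigId <- "seq"
  if (is.null(orfs))
    orfs <- findOrfs(dna, "standard", minAa = 1L, contigId = contigId)
  n <- .strandCountsFor(counts, contigId)
  lenOk <- length(dna) > params$minContigLen
  if (nrow(orfs)) {
    longestLen <- orfs$proteinLen[1L]
    senseStrand <- orfs$strand[1L]
  } else {
    longestLen <- 0L
    senseStrand <- "+"
  }
  orfOk <- longestLen >= params$minProteinLen
  nSense <- if (senseStrand == "+") n[["nSense"]] else n[["nAntisense"]]
  nAnti <- if (senseStrand == "+") n[["nAntisense"]] else n[["nSense"]]
  bothOk <- nSense > 0L && nAnti > 0L
  ratio <- if (nSense > 0L) nAnti / nSense else NA_real_
  ratioOk <- !is.na(ratio) && ratio >= params$minStrandRatio
  passed <- lenOk && orfOk && bothOk && ratioOk
  genomic <- isTRUE(dnaPositive)
  S4Vectors::DataFrame(
    contigId = contigId, hasHomology = FALSE, lenOk = lenOk, orfOk = orfOk,
    bothStrandsOk = bothOk, ratioOk = ratioOk, antisenseRatio = ratio,
    longestOrfLen = longestLen, senseStrand = senseStrand,
    dnaPositive = dnaPositive, genomicOrigin = genomic,
    passed = passed, viralCandidate = passed && !genomic)
}

#' Screen a contig set for ORFan replication candidates
#'
#' The full triage: contigs with database homology are removed, and each
#' survivor is evaluated with [evaluateOrfan()]. Summary counts are reported
#' via `message()`.
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param hits A hit table from [readHitTable()].
#' @param counts A [StrandCounts] over the same contig set.
#' @param params An [orfanParams()] list.
#' @param dnaPositive Optional named logical vector (by contig id) with
#'   nucleic-acid verification outcomes.
#' @return A [S4Vectors::DataFrame], one verdict row per surviving contig,
#'   sorted by contig id.
#' @export
screenOrfans <- function(contigs, hits, counts, params = orfanParams(),
                         dnaPositive = NULL) {
  survivors <- removeHomologous(contigs, hits, params$evalueMax)
  ids <- sort(names(survivors))
  rows <- lapply(ids, function(id) {
    dp <- if (!is.null(dnaPositive) && id %in% names(dnaPositive))
      dnaPositive[[id]] else NA
    evaluateOrfan(survivors[id], counts, params, dnaPositive = dp)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    evaluateOrfan(Biostrings::DNAStringSet(c(x = "ACGT")),
                  list(nSense = 0L, nAntisense = 0L))[0L, ]
  message("ORFan screen: ", length(contigs), " contig(s), ",
          length(survivors), " candidate(s) without homology, ",
          sum(out$passed), " passed")
  out
}
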