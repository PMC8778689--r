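#' KmerIndex: a stranded k-mer index over a contig set
#'
#' Maps every k-mer of every contig, on both strands, to its
#' (contig, strand) occurrences. A read k-mer found under strand `+` supports
#' a sense placement on that contig; found under `-` (i.e. it equals the
#' reverse complement of a contig k-mer) it supports an antisense placement.
#' Palindromic k-mers are indexed on both strands and therefore never decide
#' orientation on their own.
#'
#' @slot k Odd integer k-mer size (>= 11).
#' @slot occ A `data.table` keyed by `kmer` with columns
#'   `kmer`, `contig`, `strand`.
#' @slot contigs Character vector of indexed contig ids.
#' @aliases KmerIndex
#' @exportClass KmerIndex
setClass("KmerIndex",
         representation(k = "integer", occ = "ANY", contigs = "character"))

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 11L ||
      object@k %% 2L == 0L)
    msg <- c(msg, "k must be a single odd integer >= 11")
  occ <- object@occ
  if (!inherits(occ, "data.table") ||
      !all(c("kmer", "contig", "strand") %in% names(occ)))
    msg <- c(msg, "occ must be a data.table with kmer/contig/strand")
  else {
    if (nrow(occ) && !all(nchar(occ$kmer) == object@k))
      msg <- c(msg, "all indexed k-mers must have length k")
    if (nrow(occ) && !all(occ$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn KmerIndex k-mer size
#' @param x,object A `KmerIndex`.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @describeIn KmerIndex k-mer size accessor
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)

#' @describeIn KmerIndex indexed contig ids
#' @export
setGeneric("indexedContigs", function(x) standardGeneric("indexedContigs"))

#' @describeIn KmerIndex contig id accessor
#' @export
setMethod("indexedContigs", "KmerIndex", function(x) x@contigs)

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k =", object@k, "|", length(object@contigs),
      "contig(s) |", nrow(object@occ), "k-mer occurrence(s)\n")
})

#' StrandCounts: per-contig sense/antisense read tallies
#'
#' The central statistic of the replication-intermediate screen: for each
#' contig, the number of reads assigned to its forward (`+`, sense) and
#' reverse (`-`, antisense) strand, plus global tallies of ambiguous and
#' unassigned reads. Conservation holds by construction:
#' `sum(assigned) + ambiguous + unassigned == total reads`.
#'
#' @slot counts A [S4Vectors::DataFrame] with columns `contigId`, `nSense`,
#'   `nAntisense` (one row per indexed contig).
#' @slot nAmbiguous,nUnassigned,nReads Integer global tallies.
#' @slot confusion Optional truth-vs-assigned strand confusion matrix (when
#'   reads carry a `truthStrand` tag), else `NULL`.
#' @aliases StrandCounts
#' @exportClass StrandCounts
setClass("StrandCounts",
         representation(counts = "DataFrame", nAmbiguous = "integer",
                        nUnassigned = "integer", nReads = "integer",
                        confusion = "ANY"))

setValidity("StrandCounts", function(object) {
  msg <- character()
  cc <- object@counts
  if (!all(c("contigId", "nSense", "nAntisense") %in% names(cc)))
    msg <- c(msg, "counts must have contigId/nSense/nAntisense")
  else if (nrow(cc) && any(cc$nSense < 0 | cc$nAntisense < 0))
    msg <- c(msg, "counts must be non-negative")
  if (object@nAmbiguous < 0 || object@nUnassigned < 0)
    msg <- c(msg, "global tallies must be non-negative")
  tot <- sum(cc$nSense) + sum(cc$nAntisense) +
    object@nAmbiguous + object@nUnassigned
  if (tot != object@nReads)
    msg <- c(msg, "assigned + ambiguous + unassigned must equal total reads")
  if (length(msg)) msg else TRUE
})

#' @describeIn StrandCounts sense-strand read counts, named by contig
#' @export
setGeneric("senseCounts", function(x) standardGeneric("senseCounts"))

#' @describeIn StrandCounts sense count accessor
#' @param x,object A `StrandCounts`.
#' @export
setMethod("senseCounts", "StrandCounts",
          function(x) setNames(x@counts$nSense, x@counts$contigId))

#' @describeIn StrandCounts antisense-strand read counts, named by contig
#' @export
setGeneric("antisenseCounts", function(x) standardGeneric("antisenseCounts"))

#' @describeIn StrandCounts antisense count accessor
#' @export
setMethod("antisenseCounts", "StrandCounts",
          function(x) setNames(x@counts$nAntisense, x@counts$contigId))

#' @describeIn StrandCounts truth-vs-assigned confusion matrix (or NULL)
#' @export
setGeneric("strandConfusion", function(x) standardGeneric("strandConfusion"))

#' @describeIn StrandCounts confusion accessor
#' @export
setMethod("strandConfusion", "StrandCounts", function(x) x@confusion)

#' @describeIn StrandCounts coerce the per-contig table to a data.frame
#' @export
setMethod("as.data.frame", "StrandCounts", function(x, ...) {
  df <- as.data.frame(x@counts)
  df$nAmbiguous <- x@nAmbiguous
  df$nUnassigned <- x@nUnassigned
  df
})

setMethod("show", "StrandCounts", function(object) {
  cat("StrandCounts:", nrow(object@counts), "contig(s),",
      object@nReads, "read(s)\n")
  cat("  assigned:", sum(object@counts$nSense) + sum(object@counts$nAntisense),
      "| ambiguous:", object@nAmbiguous,
      "| unassigned:", object@nUnassigned, "\n")
  if (nrow(object@counts)) {
    print(utils::head(as.data.frame(object@counts), 5L))
    if (nrow(object@counts) > 5L) cat("  ...\n")
  }
})

#' GlobalAlignment: a pairwise global alignment with affine gaps
#'
#' @slot aAligned,bAligned Equal-length aligned strings (gaps as `-`);
#'   removing the gaps recovers the input sequences.
#' @slot score Optimal Needleman-Wunsch score under the affine gap model.
#' @slot params Scoring descriptor (list).
#' @aliases GlobalAlignment
#' @exportClass GlobalAlignment
setClass("GlobalAlignment",
         representation(aAligned = "character", bAligned = "character",
                        score = "numeric", params = "list"))

setValidity("GlobalAlignment", function(object) {
  if (nchar(object@aAligned) != nchar(object@bAligned))
    "aligned strings must have equal length" else TRUE
})

#' @describeIn GlobalAlignment alignment score
#' @param x,object A `GlobalAlignment`.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @describeIn GlobalAlignment score accessor
#' @export
setMethod("alignmentScore", "GlobalAlignment", function(x) x@score)

#' @describeIn GlobalAlignment the two aligned strings
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @describeIn GlobalAlignment aligned string accessor
#' @export
setMethod("alignedSeqs", "GlobalAlignment",
          function(x) c(a = x@aAligned, b = x@bAligned))

setMethod("show", "GlobalAlignment", function(object) {
  cat("GlobalAlignment (score ", object@score, ")\n", sep = "")
  a <- object@aAligned; b <- object@bAligned
  if (nchar(a) > 60) {
    a <- paste0(substr(a, 1, 57), "...")
    b <- paste0(substr(b, 1, 57), "...")
  }
  cat("  a: ", a, "\n  b: ", b, "\n", sep = "")
})

#' Classification: an ICTV demarcation verdict for a candidate virus
#'
#' @slot candidateId Candidate identifier.
#' @slot verdict One of `variant_of_known_species`, `new_species_candidate`,
#'   `new_genus_candidate`, `unresolved`.
#' @slot rulesApplied The demarcation rules consulted (data.frame).
#' @slot bestReference Reference id of the closest relative on the decisive
#'   marker (NA when unresolved).
#' @slot note Free-text note (e.g. genus placement caveats).
#' @aliases Classification
#' @exportClass Classification
setClass("Classification",
         representation(candidateId = "character", verdict = "character",
                        rulesApplied = "data.frame",
                        bestReference = "character", note = "character"))

setValidity("Classification", function(object) {
  ok <- object@verdict %in% c("variant_of_known_species",
                              "new_species_candidate",
                              "new_genus_candidate", "unresolved")
  if (!ok) "invalid verdict" else TRUE
})

#' @describeIn Classification the verdict label
#' @param x,object A `Classification`.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @describeIn Classification verdict accessor
#' @export
setMethod("verdict", "Classification", function(x) x@verdict)

setMethod("show", "Classification", function(object) {
  cat("Classification:", object@candidateId, "->", object@verdict, "\n")
  if (nrow(object@rulesApplied)) {
    cat("  rules applied:\n")
    print(object@rulesApplied[, c("taxonScope", "marker", "threshold",
                                  "relation")])
  }
  if (!is.na(object@bestReference))
    cat("  best reference:", object@bestReference, "\n")
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})
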