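.defaultScoring <- function(alphabet) {
  if (alphabet == "nucleotide")
    list(match = 2, mismatch = -3, gapOpen = -5, gapExtend = -2)
  else
    list(matrix = "BLOSUM62", gapOpen = -11, gapExtend = -1)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.substitutionMatrix <- function(scoring, chars) {
  if (!is.null(scoring$matrix)) {
    m <- if (is.character(scoring$matrix) &&
             identical(scoring$matrix, "BLOSUM62")) .blosum62()
    else scoring$matrix
    missing <- setdiff(chars, rownames(m))
    if (length(missing))
      stop("residue(s) not covered by the substitution matrix: ",
           paste(missing, collapse = ", "))
    return(m[chars, chars, drop = FALSE])
  }
  n <- length(chars)
  m <- matrix(scoring$mismatch, n, n, dimnames = list(chars, chars))
  diag(m) <- scoring$match
  m
}

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch alignment under an affine gap model (a gap of
#' length L costs `gapOpen + L * gapExtend`) with a deterministic traceback:
#' on score ties the diagonal is preferred, then up, then left. Defaults:
#' nucleotide match +2 / mismatch -3, gap open -5 / extend -2; protein
#' BLOSUM62 with gap open -11 / extend -1.
#'
#' @param a,b Sequences (`XString`, single-record `XStringSet`, or
#'   character). Empty sequences are an error.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param scoring Optional list overriding the defaults: either
#'   `match`/`mismatch` or `matrix` (a named substitution matrix or
#'   `"BLOSUM62"`), plus `gapOpen` and `gapExtend`.
#' @return A [GlobalAlignment].
#' @examples
#' aln <- globalAlign("ACGT", "AGGT")
#' alignmentScore(aln)
#' pDistanceIdentity(aln)$pctIdentity  # 75
#' @export
globalAlign <- function(a, b, alphabet = c("nucleotide", "protein"),
                        scoring = NULL) {
  alphabet <- match.arg(alphabet)
  toChar <- function(x) {
    if (methods::is(x, "XStringSet")) {
      stopifnot(length(x) == 1L)
      x <- x[[1L]]
    }
    if (methods::is(x, "XString")) x <- as.character(x)
    stopifnot(is.character(x), length(x) == 1L)
    x <- toupper(x)
    if (alphabet == "nucleotide") x <- gsub("U", "T", x, fixed = TRUE)
    x
  }
  sa <- toChar(a); sb <- toChar(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  sc <- .defaultScoring(alphabet)
  if (!is.null(scoring)) sc[names(scoring)] <- scoring
  va <- strsplit(sa, "")[[1L]]
  vb <- strsplit(sb, "")[[1L]]
  chars <- sort(unique(c(va, vb)))
  sub <- .substitutionMatrix(sc, chars)
  res <- .nwAlignCpp(match(va, chars) - 1L, match(vb, chars) - 1L,
                     unname(sub), sc$gapOpen, sc$gapExtend)
  gapA <- res$opsA == 0L
  gapB <- res$opsB == 0L
  alnA <- character(length(gapA)); alnB <- alnA
  alnA[!gapA] <- va; alnA[gapA] <- "-"
  alnB[!gapB] <- vb; alnB[gapB] <- "-"
  methods::new("GlobalAlignment",
               aAligned = paste(alnA, collapse = ""),
               bAligned = paste(alnB, collapse = ""),
               score = res$score,
               params = c(list(alphabet = alphabet), sc))
}

#' Percent identity by the p-distance method
#'
#' Computes identity over a pairwise alignment with pairwise deletion:
#' columns containing a gap in either sequence are excluded, and
#' `pctIdentity = 100 * nIdentical / nCompared`. The p-distance itself is
#' `1 - nIdentical / nCompared`.
#'
#' @param aln A [GlobalAlignment] (or any list with `aAligned`/`bAligned`).
#' @return A list with `nCompared`, `nIdentical`, `pctIdentity` and
#'   `defined` (`FALSE` when no gap-free columns exist, in which case
#'   `pctIdentity` is `NA`).
#' @export
pDistanceIdentity <- function(aln) {
  if (methods::is(aln, "GlobalAlignment")) {
    a <- aln@aAligned; b <- aln@bAligned
  } else {
    a <- aln$aAligned; b <- aln$bAligned
  }
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  keep <- va != "-" & vb != "-"
  nCompared <- sum(keep)
  nIdentical <- sum(va[keep] == vb[keep])
  list(nCompared = nCompared, nIdentical = nIdentical,
       pctIdentity = if (nCompared > 0L) 100 * nIdentical / nCompared
                     else NA_real_,
       defined = nCompared > 0L)
}

#' Pairwise p-distance identity matrix
#'
#' Aligns every pair of sequences globally and fills a symmetric percent
#' identity matrix (diagonal exactly 100).
#'
#' @param seqs An `XStringSet` (or named character vector) of >= 2 sequences
#'   with unique ids.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param scoring Optional scoring override, see [globalAlign()].
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
identityMatrix <- function(seqs, alphabet = c("nucleotide", "protein"),
                           scoring = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs)) {
    ids <- names(seqs)
    chars <- seqs
  } else {
    ids <- names(seqs)
    chars <- as.character(seqs)
  }
  stopifnot(length(chars) >= 2L, !is.null(ids))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(chars)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pDistanceIdentity(
        globalAlign(chars[i], chars[j], alphabet, scoring))$pctIdentity
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}

#' Range of off-diagonal identities
#'
#' @param m An identity matrix from [identityMatrix()].
#' @return `c(min = ..., max = ...)` over the off-diagonal entries.
#' @export
identityRange <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("identity range needs at least two sequences")
  off <- m[row(m) != col(m)]
  c(min = min(off), max = max(off))
}

#' Extract a coordinate range from every sequence of a set
#'
#' Trimming to a shared amplicon region before identity analysis is an
#' explicit coordinate-range extraction (1-based, inclusive), never
#' automatic.
#'
#' @param seqs An `XStringSet`.
#' @param start,end 1-based inclusive bounds; `end` beyond a sequence is
#'   clipped.
#' @return The trimmed `XStringSet`.
#' @export
trimRange <- function(seqs, start, end) {
  stopifnot(start >= 1L, end >= start)
  Biostrings::subseq(seqs, start = start,
                     end = pmin(end, Biostrings::width(seqs)))
}
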