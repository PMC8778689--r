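# Independent oracles used by the property tests. These deliberately use
# naive per-position scans / exhaustive recursion, not the vectorised code
# paths of the package.

# Brute-force ORF enumeration: for every ATG on either strand, walk codon by
# codon to the next in-frame stop. Returns forward-strand coordinates.
bruteForceOrfs <- function(seq, geneticCode = "standard", minAa = 1L) {
  stops <- if (geneticCode == "standard") c("TAA", "TAG", "TGA")
           else c("TAA", "TAG")
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (i in seq_len(max(L - 2L, 0L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      while (j + 2L <= L) {
        if (substr(s, j, j + 2L) %in% stops) {
          aaLen <- (j - i) / 3L
          if (aaLen >= minAa) {
            se <- c(i, j + 2L)
            if (strand == "-") se <- c(L - se[2L] + 1L, L - se[1L] + 1L)
            out[[length(out) + 1L]] <- data.frame(
              start = se[1L], end = se[2L], strand = strand,
              proteinLen = aaLen)
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), proteinLen = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# Exhaustive global-alignment score: plain recursion over all alignment
# paths, charging gapOpen + gapExtend when a gap opens and gapExtend when it
# extends. Only feasible for short strings.
bruteForceAlignScore <- function(a, b, match = 2, mismatch = -3,
                                 gapOpen = -5, gapExtend = -2) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      cost <- if (prev == "X") gapExtend else gapOpen + gapExtend
      best <- max(best, cost + rec(i + 1L, j, "X"))
    }
    if (j <= m) {
      cost <- if (prev == "Y") gapExtend else gapOpen + gapExtend
      best <- max(best, cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

infectionTablePath <- function()
  system.file("extdata", "infection_table.tsv", package = "viromeScreen")
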