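#' Build a stranded k-mer index over contigs
#'
#' Indexes every k-mer of every contig on both strands: forward k-mers under
#' strand `+`, k-mers of the reverse complement under strand `-`. A read
#' whose k-mers match the `+` entries of a contig therefore maps in sense
#' orientation; matches to `-` entries indicate antisense placement.
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param k Odd k-mer size (default 21). Must not exceed the shortest read
#'   length used downstream.
#' @return A [KmerIndex].
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGTACGTACGTACGTACGT"))
#' buildKmerIndex(ctg, k = 21)
#' @export
buildKmerIndex <- function(contigs, k = 21L) {
  if (!methods::is(contigs, "DNAStringSet"))
    stop("contigs must be a DNAStringSet (nucleotide records)")
  k <- as.integer(k)
  if (is.na(k) || k < 11L || k %% 2L == 0L)
    stop("k must be an odd integer >= 11")
  if (length(contigs) && is.null(names(contigs)))
    stop("contigs must be named")
  pieces <- vector("list", 2L * length(contigs))
  n <- 0L
  for (i in seq_along(contigs)) {
    fwd <- as.character(contigs[[i]])
    if (nchar(fwd) < k) next
    rev <- as.character(Biostrings::reverseComplement(contigs[[i]]))
    id <- names(contigs)[i]
    starts <- seq_len(nchar(fwd) - k + 1L)
    pieces[[n + 1L]] <- data.table::data.table(
      kmer = substring(fwd, starts, starts + k - 1L), contig = id,
      strand = "+")
    pieces[[n + 2L]] <- data.table::data.table(
      kmer = substring(rev, starts, starts + k - 1L), contig = id,
      strand = "-")
    n <- n + 2L
  }
  occ <- if (n) unique(data.table::rbindlist(pieces[seq_len(n)])) else
    data.table::data.table(kmer = character(), contig = character(),
                           strand = character())
  data.table::setkey(occ, kmer)
  methods::new("KmerIndex", k = k, occ = occ,
               contigs = as.character(names(contigs)))
}

## Count, for each read, how many of its k-mer positions match each
## (contig, strand) occurrence set. Returns a data.table:
## read (integer row of `reads`), contig, strand, hits, total (k-mers/read).
.kmerHits <- function(index, reads) {
  k <- index@k
  widths <- Biostrings::width(reads)
  nk <- pmax(widths - k + 1L, 0L)
  usable <- which(nk > 0L)
  if (!length(usable) || nrow(index@occ) == 0L)
    return(list(hits = data.table::data.table(
      read = integer(), contig = character(), strand = character(),
      hits = integer()), nKmers = nk))
  seqs <- as.character(reads[usable])
  km <- lapply(seq_along(usable), function(j) {
    s <- seqs[j]
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  })
  qry <- data.table::data.table(
    read = rep(usable, lengths(km)), kmer = unlist(km, use.names = FALSE))
  hits <- index@occ[qry, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  hits <- hits[, list(hits = .N), by = c("read", "contig", "strand")]
  list(hits = hits, nKmers = nk)
}

.decideAssignment <- function(frac, contig, strand, minFrac) {
  best <- which.max(frac)
  if (frac[best] < minFrac) return(list(status = "unassigned"))
  if (sum(frac == frac[best]) > 1L) return(list(status = "ambiguous"))
  list(status = "assigned", contig = contig[best], strand = strand[best])
}

#' Assign a single read to a contig and strand
#'
#' The (contig, strand) pair matching the largest fraction of the read's
#' k-mers wins, provided that fraction reaches `minFrac` and strictly exceeds
#' the runner-up. An exact tie between candidates yields `"ambiguous"`; a
#' best fraction below `minFrac` yields `"unassigned"`. No mismatches are
#' tolerated within a k-mer; tolerance comes from requiring only a fraction
#' of k-mers to match.
#'
#' @param index A [KmerIndex].
#' @param read A single-element [Biostrings::DNAStringSet], `DNAString` or
#'   character string.
#' @param minFrac Minimum matching k-mer fraction in (0, 1]; default 0.5.
#' @return A list with `status` (`"assigned"`, `"ambiguous"` or
#'   `"unassigned"`) and, when assigned, `contig` and `strand`.
#' @export
assignRead <- function(index, read, minFrac = 0.5) {
  stopifnot(methods::is(index, "KmerIndex"),
            minFrac > 0, minFrac <= 1)
  if (is.character(read)) read <- Biostrings::DNAStringSet(read)
  if (methods::is(read, "DNAString"))
    read <- Biostrings::DNAStringSet(list(read))
  stopifnot(length(read) == 1L)
  if (Biostrings::width(read)[1L] < index@k) {
    warning("read shorter than k = ", index@k, "; unassigned")
    return(list(status = "unassigned"))
  }
  kh <- .kmerHits(index, read)
  if (nrow(kh$hits) == 0L) return(list(status = "unassigned"))
  frac <- kh$hits$hits / kh$nKmers[1L]
  .decideAssignment(frac, kh$hits$contig, kh$hits$strand, minFrac)
}

#' Count sense and antisense reads per contig
#'
#' Runs [assignRead()] over a read set (vectorised) and tallies, per contig,
#' the reads assigned to its forward (sense) and reverse (antisense) strand.
#' Ambiguous reads are excluded from both strand counts; ambiguous and
#' unassigned reads are tallied globally, so
#' `assigned + ambiguous + unassigned == length(reads)`. When reads carry a
#' `truthStrand` tag in `mcols()` (synthetic fixtures), a truth-vs-assigned
#' confusion matrix is attached.
#'
#' @inheritParams assignRead
#' @param reads A [Biostrings::DNAStringSet] of reads (e.g. from
#'   [readReads()]).
#' @return A [StrandCounts].
#' @export
countStrands <- function(index, reads, minFrac = 0.5) {
  stopifnot(methods::is(index, "KmerIndex"),
            methods::is(reads, "DNAStringSet"),
            minFrac > 0, minFrac <= 1)
  nReads <- length(reads)
  kh <- .kmerHits(index, reads)
  short <- sum(kh$nKmers == 0L)
  if (short > 0L)
    warning(short, " read(s) shorter than k = ", index@k, "; unassigned")
  status <- rep("unassigned", nReads)
  asgContig <- rep(NA_character_, nReads)
  asgStrand <- rep(NA_character_, nReads)
  if (nrow(kh$hits)) {
    hits <- kh$hits
    hits$frac <- hits$hits / kh$nKmers[hits$read]
    byRead <- split(seq_len(nrow(hits)), hits$read)
    for (rn in names(byRead)) {
      rows <- byRead[[rn]]
      d <- .decideAssignment(hits$frac[rows], hits$contig[rows],
                             hits$strand[rows], minFrac)
      i <- as.integer(rn)
      status[i] <- d$status
      if (d$status == "assigned") {
        asgContig[i] <- d$contig
        asgStrand[i] <- d$strand
      }
    }
  }
  contigs <- index@contigs
  nSense <- setNames(integer(length(contigs)), contigs)
  nAnti <- nSense
  isAsg <- status == "assigned"
  if (any(isAsg)) {
    tS <- table(factor(asgContig[isAsg & asgStrand == "+"], levels = contigs))
    tA <- table(factor(asgContig[isAsg & asgStrand == "-"], levels = contigs))
    nSense[] <- as.integer(tS)
    nAnti[] <- as.integer(tA)
  }
  confusion <- NULL
  truth <- S4Vectors::mcols(reads)$truthStrand
  if (!is.null(truth) && any(!is.na(truth))) {
    assignedStrand <- ifelse(isAsg,
                             ifelse(asgStrand == "+", "sense", "antisense"),
                             status)
    confusion <- table(truth = truth, assigned = assignedStrand,
                       useNA = "no")
  }
  methods::new("StrandCounts",
               counts = S4Vectors::DataFrame(
                 contigId = contigs, nSense = unname(nSense),
                 nAntisense = unname(nAnti)),
               nAmbiguous = sum(status == "ambiguous"),
               nUnassigned = sum(status == "unassigned"),
               nReads = nReads,
               confusion = confusion)
}

#' Write strand counts as a TSV
#'
#' @param x A [StrandCounts].
#' @param path Output path. Columns: `contig_id`, `n_sense`, `n_antisense`,
#'   `n_ambiguous`, `n_unassigned` (the last two are global tallies repeated
#'   per row).
#' @return `path`, invisibly.
#' @export
writeStrandCounts <- function(x, path) {
  stopifnot(methods::is(x, "StrandCounts"))
  df <- data.frame(contig_id = x@counts$contigId,
                   n_sense = x@counts$nSense,
                   n_antisense = x@counts$nAntisense,
                   n_ambiguous = x@nAmbiguous,
                   n_unassigned = x@nUnassigned)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
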