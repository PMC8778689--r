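#' Read sequences from a FASTA file
#'
#' Reads a plain or gzip-compressed FASTA file into a Biostrings container.
#' Nucleotide input is canonicalised: residues are uppercased and RNA `U` is
#' stored as `T` (reports that echo genome features, such as slippage sites,
#' render the RNA alphabet for display). The first whitespace-delimited token
#' of each header is the sequence id; the remainder is kept as a description
#' in `mcols()`.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @param alphabet `"nucleotide"` (default) or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] with
#'   `mcols()$description`. An empty file yields an empty set with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b some description", "acgu"), fa)
#' seqs <- readFasta(fa)
#' as.character(seqs)
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(if (alphabet == "nucleotide") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet())
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0L))
    stop("empty sequence record(s) in ", path)
  chars <- toupper(as.character(raw))
  if (alphabet == "nucleotide") {
    chars <- gsub("U", "T", chars, fixed = TRUE)
    out <- Biostrings::DNAStringSet(chars)
  } else {
    out <- Biostrings::AAStringSet(chars)
  }
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to a FASTA file
#'
#' Inverse of [readFasta()]: sequence content round-trips byte-identically up
#' to line wrapping. Descriptions stored in `mcols()` are appended to headers.
#'
#' @param x An `XStringSet` with unique names.
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  stopifnot(!is.null(names(x)), !anyDuplicated(names(x)))
  y <- x
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc) && any(nzchar(desc)))
    names(y) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  Biostrings::writeXStringSet(y, filepath = path, width = width)
  invisible(path)
}

#' Read sequencing reads from a FASTQ file
#'
#' Reads 4-line FASTQ records (plain or gzip). When a header carries a
#' `strand=sense` / `strand=antisense` tag (as written by the synthetic read
#' simulator), the tag is parsed into `mcols()$truthStrand`; reads without the
#' tag get `NA`. A record whose quality string length differs from its
#' sequence length is a format error.
#'
#' @param path Path to a FASTQ file.
#' @return A [Biostrings::DNAStringSet] with `mcols()` columns `truthStrand`
#'   and `qualities`.
#' @export
readReads <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ file ", path, ": not 4-line records",
         call. = FALSE)
  if (length(lines)) {
    seqLen <- nchar(lines[seq(2L, length(lines), by = 4L)])
    qualLen <- nchar(lines[seq(4L, length(lines), by = 4L)])
    if (!all(seqLen == qualLen))
      stop("malformed FASTQ file ", path,
           ": sequence/quality length mismatch at record ",
           which(seqLen != qualLen)[1L], call. = FALSE)
    if (!all(startsWith(lines[seq(1L, length(lines), by = 4L)], "@")))
      stop("malformed FASTQ file ", path, ": header without '@'",
           call. = FALSE)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  quals <- S4Vectors::mcols(raw)$qualities
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  strand <- rep(NA_character_, length(raw))
  strand[grepl("strand=sense", headers, fixed = TRUE)] <- "sense"
  strand[grepl("strand=antisense", headers, fixed = TRUE)] <- "antisense"
  chars <- gsub("U", "T", toupper(as.character(raw)), fixed = TRUE)
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    truthStrand = strand, qualities = quals)
  out
}

.HIT_COLS <- c("queryId", "subjectId", "pctIdentity", "alnLen", "mismatches",
               "gapOpens", "qStart", "qEnd", "sStart", "sEnd", "evalue",
               "bitscore")

#' Read a 12-column tabular homology hit table
#'
#' Parses the tab-separated 12-column hit format written by BLAST/DIAMOND
#' (`outfmt 6`): query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value, bit
#' score. Extra columns are ignored with a warning. Rows with
#' `evalue > evalueMax` are excluded; filtering is monotone in `evalueMax`.
#'
#' @param path Path to the hit table (optionally `.gz`). An empty file means
#'   no contig has homology and yields a zero-row table.
#' @param evalueMax Keep only hits with e-value at or below this cutoff.
#' @return A `data.frame` with columns
#'   `queryId, subjectId, pctIdentity, alnLen, mismatches, gapOpens,
#'    qStart, qEnd, sStart, sEnd, evalue, bitscore`.
#' @export
readHitTable <- function(path, evalueMax = Inf) {
  stopifnot(file.exists(path), is.numeric(evalueMax), evalueMax >= 0)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first[1L])) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)),
      .HIT_COLS))
    return(out)
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 12L)
    stop("hit table ", path, " has ", ncol(tab),
         " columns; 12-column tabular format required")
  if (ncol(tab) > 12L) {
    warning("hit table ", path, ": ignoring ", ncol(tab) - 12L,
            " extra column(s)")
    tab <- tab[, seq_len(12L)]
  }
  names(tab) <- .HIT_COLS
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (anyNA(ev))
    stop("non-numeric e-value in ", path, " at line ",
         which(is.na(ev))[1L], ": '", tab$evalue[which(is.na(ev))[1L]], "'")
  num <- c("pctIdentity", "alnLen", "mismatches", "gapOpens",
           "qStart", "qEnd", "sStart", "sEnd", "bitscore")
  tab[num] <- lapply(tab[num], as.numeric)
  tab$evalue <- ev
  if (any(tab$evalue < 0)) stop("negative e-value in ", path)
  if (any(tab$qStart > tab$qEnd))
    stop("qStart > qEnd in ", path)
  tab[tab$evalue <= evalueMax, , drop = FALSE]
}

#' Best hit per query
#'
#' @param hits A hit table from [readHitTable()].
#' @return One row per query id: the hit with the smallest e-value
#'   (ties broken by bit score, then input order).
#' @export
bestHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$queryId, hits$evalue, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$queryId), , drop = FALSE]
}

#' Read a per-strain infection table
#'
#' Parses a tab-separated matrix whose first column is the strain and whose
#' remaining columns are virus names. Cells are empty (no detection) or
#' `isolate(ct)` where `ct` is the diagnostic real-time PCR threshold cycle.
#' Lines starting with `#` are skipped.
#'
#' @param path Path to the table.
#' @return A [S4Vectors::DataFrame] in long form with columns
#'   `strain`, `virus`, `isolate`, `ct` (one row per detection), plus
#'   `metadata()` entries `strains` (all strains listed in the file) and
#'   `viruses` (all virus columns).
#' @export
readInfectionTable <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("infection table needs a strain column plus >=1 virus column")
  strains <- tab[[1L]]
  if (anyDuplicated(strains))
    stop("duplicate strain row(s): ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  viruses <- names(tab)[-1L]
  rows <- list()
  for (j in seq_along(viruses)) {
    cells <- trimws(tab[[j + 1L]])
    cells[is.na(cells)] <- ""
    filled <- which(nzchar(cells))
    for (i in filled) {
      m <- regmatches(cells[i],
                      regexec("^(.*)\\(([0-9]+\\.?[0-9]*)\\)$", cells[i]))[[1L]]
      if (length(m) != 3L)
        stop("unparseable infection-table cell for strain '", strains[i],
             "', virus '", viruses[j], "': '", cells[i], "'")
      ct <- as.numeric(m[3L])
      if (!is.finite(ct) || ct <= 0)
        stop("threshold cycle must be positive (strain '", strains[i], "')")
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strains[i], virus = viruses[j],
        isolate = trimws(m[2L]), ct = ct, stringsAsFactors = FALSE)
    }
  }
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(), virus = character(),
               isolate = character(), ct = numeric())
  out <- S4Vectors::DataFrame(long)
  S4Vectors::metadata(out) <- list(strains = strains, viruses = viruses)
  out
}
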