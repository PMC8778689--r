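.GENETIC_CODES <- c(standard = "1", mold_mitochondrial = "4")

.codonTable <- function(geneticCode) {
  id <- .GENETIC_CODES[[match.arg(geneticCode, names(.GENETIC_CODES))]]
  Biostrings::getGeneticCode(id)
}

.stopCodons <- function(geneticCode) {
  tab <- .codonTable(geneticCode)
  names(tab)[tab == "*"]
}

.asDnaString <- function(seq) {
  if (is.character(seq)) {
    stopifnot(length(seq) == 1L)
    return(Biostrings::DNAString(gsub("U", "T", toupper(seq), fixed = TRUE)))
  }
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(seq[[1L]])
  }
  if (methods::is(seq, "DNAString")) return(seq)
  stop("expected a nucleotide sequence (DNAString/DNAStringSet/character)")
}

.asProteinString <- function(protein) {
  if (methods::is(protein, "AAStringSet")) {
    stopifnot(length(protein) == 1L)
    protein <- protein[[1L]]
  }
  if (methods::is(protein, "AAString")) protein <- as.character(protein)
  if (!is.character(protein) || length(protein) != 1L)
    stop("expected a protein sequence (AAString/character)")
  p <- toupper(protein)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZJUO*-]", p))
    stop("input does not look like a protein sequence")
  p
}

#' Predict complete open reading frames under a selectable genetic code
#'
#' Enumerates every complete ORF (initiator `ATG` through the next in-frame
#' stop) on both strands and all three frames. Stop codons are defined by the
#' chosen translation table: under `"mold_mitochondrial"` (the standard
#' choice for fungal mitoviruses, which replicate in mitochondria) `TGA`
#' reads through as tryptophan, so only `TAA`/`TAG` terminate. Nested ORFs
#' sharing a stop are all reported, one per in-frame `ATG`.
#'
#' @param seq A nucleotide sequence (`DNAString`, single-record
#'   `DNAStringSet`, or character).
#' @param geneticCode `"standard"` or `"mold_mitochondrial"`.
#' @param minAa Minimum protein length in amino acids (stop excluded).
#' @param contigId Optional id used in the output (defaults to the sequence
#'   name, or `"seq"`).
#' @return A [S4Vectors::DataFrame] sorted by protein length (descending)
#'   with columns `contigId`, `start`, `end` (1-based, inclusive, forward
#'   strand of the stored sequence; the span includes the stop codon),
#'   `strand`, `frame` (1-3 on the scanned strand), `geneticCode`,
#'   `protein` (no stop), `proteinLen`, `complete`.
#' @examples
#' findOrfs("ATGAAATAA", minAa = 1)$protein              # "MK"
#' findOrfs("ATGTGATAA", "mold_mitochondrial", 1)$protein # "MW": TGA = Trp
#' @export
findOrfs <- function(seq, geneticCode = c("standard", "mold_mitochondrial"),
                     minAa = 150L, contigId = NULL) {
  geneticCode <- match.arg(geneticCode)
  stopifnot(minAa >= 1L)
  if (is.null(contigId))
    contigId <- if (!is.null(names(seq)) && length(names(seq)) == 1L)
      names(seq)[1L] else "seq"
  dna <- .asDnaString(seq)
  L <- length(dna)
  codonTab <- .codonTable(geneticCode)
  stops <- .stopCodons(geneticCode)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") as.character(dna) else
      as.character(Biostrings::reverseComplement(dna))
    for (f in 1:3) {
      if (L - f + 1L < 6L) next
      starts <- seq.int(f, L - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      atgIdx <- which(codons == "ATG")
      stopIdx <- which(codons %in% stops)
      if (!length(atgIdx) || !length(stopIdx)) next
      nxt <- stopIdx[findInterval(atgIdx, stopIdx) + 1L]
      ok <- !is.na(nxt)
      atgIdx <- atgIdx[ok]; nxt <- nxt[ok]
      aaLen <- nxt - atgIdx  # codons before the stop, incl. the initiator
      keep <- aaLen >= minAa
      atgIdx <- atgIdx[keep]; nxt <- nxt[keep]; aaLen <- aaLen[keep]
      for (j in seq_along(atgIdx)) {
        cd <- codons[atgIdx[j]:(nxt[j] - 1L)]
        aa <- codonTab[cd]
        aa[is.na(aa)] <- "X"
        sStart <- starts[atgIdx[j]]
        sEnd <- starts[nxt[j]] + 2L
        rows[[length(rows) + 1L]] <- data.frame(
          contigId = contigId,
          start = if (strand == "+") sStart else L - sEnd + 1L,
          end = if (strand == "+") sEnd else L - sStart + 1L,
          strand = strand, frame = f, geneticCode = geneticCode,
          protein = paste(aa, collapse = ""),
          proteinLen = aaLen[j], complete = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contigId = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(),
               geneticCode = character(), protein = character(),
               proteinLen = integer(), complete = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$proteinLen, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}

#' Detect an overlap between two ORFs (candidate ribosomal-slippage region)
#'
#' Totivirus-like genomes express their RdRp as a CP-RdRp fusion through a
#' programmed -1 ribosomal frameshift at a short overlap between the two
#' ORFs. Given two ORFs on the same strand of the same contig, this returns
#' the intersection of their coordinate ranges with its sequence rendered in
#' the RNA alphabet, and the frame shift from the upstream to the downstream
#' ORF (reported as -1, 0 or +1).
#'
#' @param orfA,orfB Single rows of a [findOrfs()] table (or lists with
#'   `contigId`, `start`, `end`, `strand`, `frame`).
#' @param seq The contig the ORFs were predicted on.
#' @return A list with `upstream`, `downstream` (row indices 1/2 meaning
#'   `orfA`/`orfB`), `overlapStart`, `overlapEnd` (forward-strand
#'   coordinates), `overlapSeq` (RNA alphabet, 5'-3' on the coding strand)
#'   and `frameshift`; or `NULL` when the ORFs do not intersect.
#' @export
detectSlippageOverlap <- function(orfA, orfB, seq) {
  a <- as.list(orfA); b <- as.list(orfB)
  if (!identical(a$contigId, b$contigId))
    stop("ORFs come from different contigs: ", a$contigId, " vs ", b$contigId)
  if (!identical(a$strand, b$strand))
    stop("ORFs must lie on the same strand")
  os <- max(a$start, b$start)
  oe <- min(a$end, b$end)
  if (os > oe) return(NULL)
  dna <- .asDnaString(seq)
  frag <- Biostrings::DNAString(substr(as.character(dna), os, oe))
  if (a$strand == "-") frag <- Biostrings::reverseComplement(frag)
  upstreamIsA <- if (a$strand == "+") a$start <= b$start else a$end >= b$end
  up <- if (upstreamIsA) a else b
  dn <- if (upstreamIsA) b else a
  shift <- (dn$frame - up$frame) %% 3L
  if (shift == 2L) shift <- -1L
  list(upstream = if (upstreamIsA) 1L else 2L,
       downstream = if (upstreamIsA) 2L else 1L,
       overlapStart = os, overlapEnd = oe,
       overlapSeq = gsub("T", "U", as.character(frag), fixed = TRUE),
       frameshift = shift)
}

#' Built-in RdRp motif consensus patterns
#'
#' Degenerate consensus expressions for the six conserved motifs (I-VI)
#' characteristic of mitochondrial-virus RdRps, with the hallmark GDD
#' tripeptide forming the core of motif IV. The patterns ship as an editable
#' data file (`inst/extdata/rdrp_motifs.tsv`) so they can be re-derived from
#' any alignment of reference RdRps without touching code.
#'
#' @param file Path to a two-column TSV (`motif_id`, `pattern`); defaults to
#'   the built-in file.
#' @return A data.frame with columns `motifId` and `pattern` (regular
#'   expressions over the amino-acid alphabet).
#' @export
rdrpMotifPatterns <- function(file = system.file("extdata",
                                                 "rdrp_motifs.tsv",
                                                 package = "viromeScreen")) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("motif_id", "pattern") %in% names(tab)))
  data.frame(motifId = tab$motif_id, pattern = tab$pattern,
             stringsAsFactors = FALSE)
}

#' Scan a protein for RdRp motifs and the GDD tripeptide
#'
#' The GDD core is located by exact tripeptide search (all occurrences
#' reported); motifs I-VI are located by the built-in consensus patterns (at
#' most one hit each, the first match). The scan flags an incomplete motif
#' series when fewer than all six motifs are found in increasing position
#' order.
#'
#' @param protein Amino-acid sequence (`AAString` or character), >= 100 aa
#'   recommended.
#' @param patterns Motif pattern table, see [rdrpMotifPatterns()].
#' @return A [S4Vectors::DataFrame] with columns `motifId`, `start`, `end`,
#'   `matchedSeq` (1-based amino-acid positions), and a `metadata()` entry
#'   `incompleteSeries` (TRUE unless all six motifs occur in order).
#' @export
scanRdrpMotifs <- function(protein, patterns = rdrpMotifPatterns()) {
  p <- .asProteinString(protein)
  rows <- list()
  gdd <- gregexpr("GDD", p, fixed = TRUE)[[1L]]
  if (gdd[1L] != -1L)
    for (pos in as.integer(gdd))
      rows[[length(rows) + 1L]] <- data.frame(
        motifId = "GDD", start = pos, end = pos + 2L,
        matchedSeq = substr(p, pos, pos + 2L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    m <- regexpr(patterns$pattern[i], p, perl = TRUE)
    if (m[1L] != -1L) {
      len <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        motifId = patterns$motifId[i], start = as.integer(m),
        end = as.integer(m) + len - 1L,
        matchedSeq = substr(p, as.integer(m), as.integer(m) + len - 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motifId = character(), start = integer(), end = integer(),
               matchedSeq = character(), stringsAsFactors = FALSE)
  out <- S4Vectors::DataFrame(out)
  core <- out[out$motifId %in% c("I", "II", "III", "IV", "V", "VI"), ,
              drop = FALSE]
  ordered <- nrow(core) == 6L && !is.unsorted(core$start, strictly = TRUE)
  S4Vectors::metadata(out) <- list(incompleteSeries = !ordered)
  out
}

## Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Reference feature map of the K2 killer preprotoxin
#'
#' Coordinates (1-based amino-acid windows on the preprotoxin) of the
#' features checked by [validateK2Preprotoxin()]: the hydrophobic
#' amino-terminal region, three potential N-glycosylation sites, and the two
#' dibasic KR cleavage sites recognised by the KEX1 and KEX2 proteases during
#' toxin maturation.
#'
#' @return A list with elements `hydrophobic` (c(27, 45)), `glyc` (list of
#'   4-aa windows starting at 177, 214, 261), `kex1` (c(220, 221)), `kex2`
#'   (c(267, 268)) and `siteResidues` ("KR").
#' @export
k2ToxinReference <- function() {
  list(hydrophobic = c(27L, 45L),
       glyc = list(c(177L, 180L), c(214L, 217L), c(261L, 264L)),
       kex1 = c(220L, 221L), kex2 = c(267L, 268L),
       siteResidues = "KR")
}

#' Validate the K2 preprotoxin feature checklist on a protein
#'
#' Checks the canonical K2 preprotoxin features: mean Kyte-Doolittle
#' hydropathy over the amino-terminal window (aa 27-45) must be positive;
#' each N-glycosylation window must open with an N-X-S/T sequon (X != P); the
#' KEX1 (aa 220-221) and KEX2 (aa 267-268) cleavage windows must read `KR`.
#' Features whose window extends past the end of a truncated protein are
#' marked not evaluable (`NA`). When a reference preprotoxin is supplied,
#' position-wise amino-acid substitutions are listed.
#'
#' @param protein The preprotoxin (`AAString` or character); the full
#'   checklist needs >= 268 aa, shorter proteins get partial reports.
#' @param reference Optional reference preprotoxin for substitution calls.
#' @param sites Feature coordinates, see [k2ToxinReference()].
#' @return A list with `features` (data.frame: `feature`, `pass`, `detail`;
#'   a failed cleavage site names the observed dipeptide) and
#'   `substitutions` (data.frame: `position`, `referenceAa`, `observedAa`).
#' @export
validateK2Preprotoxin <- function(protein, reference = NULL,
                                  sites = k2ToxinReference()) {
  p <- .asProteinString(protein)
  L <- nchar(p)
  feats <- list()
  addFeat <- function(feature, pass, detail)
    feats[[length(feats) + 1L]] <<- data.frame(
      feature = feature, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  hw <- sites$hydrophobic
  if (L >= hw[2L]) {
    aa <- strsplit(substr(p, hw[1L], hw[2L]), "")[[1L]]
    kd <- mean(.KD[aa], na.rm = TRUE)
    addFeat("hydrophobic_27_45", kd > 0,
            sprintf("mean Kyte-Doolittle %.2f", kd))
  } else addFeat("hydrophobic_27_45", NA, "not evaluable (protein too short)")
  for (g in sites$glyc) {
    name <- sprintf("glyc_%d_%d", g[1L], g[2L])
    if (L >= g[1L] + 2L) {
      tri <- substr(p, g[1L], g[1L] + 2L)
      ok <- grepl("^N[^P][ST]$", tri)
      ctx <- if (L >= g[2L]) substr(p, g[1L], g[2L]) else tri
      addFeat(name, ok, sprintf("sequon %s (window %s)", tri, ctx))
    } else addFeat(name, NA, "not evaluable (protein too short)")
  }
  for (site in c("kex1", "kex2")) {
    w <- sites[[site]]
    if (L >= w[2L]) {
      dipep <- substr(p, w[1L], w[2L])
      addFeat(sprintf("%s_%d_%d", site, w[1L], w[2L]),
              dipep == sites$siteResidues,
              sprintf("observed %s", dipep))
    } else addFeat(sprintf("%s_%d_%d", site, w[1L], w[2L]), NA,
                   "not evaluable (protein too short)")
  }
  subs <- data.frame(position = integer(), referenceAa = character(),
                     observedAa = character(), stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    r <- .asProteinString(reference)
    n <- min(nchar(p), nchar(r))
    pa <- strsplit(substr(p, 1L, n), "")[[1L]]
    ra <- strsplit(substr(r, 1L, n), "")[[1L]]
    diff <- which(pa != ra)
    subs <- data.frame(position = diff, referenceAa = ra[diff],
                       observedAa = pa[diff], stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, feats), substitutions = subs)
}

#' Detect premature (internal) stop codons in an ORF region
#'
#' Reads the region codon by codon in the frame defined by its start and
#' reports every in-frame stop strictly before the region's final codon, by
#' the 1-based position of its first nucleotide within the region. A
#' defective coding sequence (e.g. a satellite toxin gene interrupted by a
#' premature stop) has a non-empty position list.
#'
#' @param seq The nucleotide sequence the region lives on.
#' @param orfRegion `c(start, end)`, 1-based inclusive, on the forward strand
#'   of `seq` (reverse-strand regions: pass the reverse complement).
#' @param geneticCode `"standard"` or `"mold_mitochondrial"`.
#' @return A list with `positions` (integer vector, possibly empty) and
#'   `defective` (`TRUE` iff any internal stop).
#' @examples
#' detectPrematureStop("ATGAAATAGAAATAA", c(1, 15))  # stop at 7, defective
#' @export
detectPrematureStop <- function(seq, orfRegion,
                                geneticCode = c("standard",
                                                "mold_mitochondrial")) {
  geneticCode <- match.arg(geneticCode)
  dna <- .asDnaString(seq)
  stopifnot(length(orfRegion) == 2L, orfRegion[1L] >= 1L,
            orfRegion[2L] <= length(dna), orfRegion[1L] <= orfRegion[2L])
  region <- substr(as.character(dna), orfRegion[1L], orfRegion[2L])
  n <- nchar(region)
  if (n %% 3L != 0L) {
    warning("region length not a multiple of 3; ignoring ", n %% 3L,
            " trailing base(s)")
    n <- n - n %% 3L
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(region, starts, starts + 2L)
  stopHits <- which(codons %in% .stopCodons(geneticCode))
  internal <- stopHits[stopHits < length(codons)]
  list(positions = starts[internal], defective = length(internal) > 0L)
}
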