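.NT <- c("A", "C", "G", "T")
.STOPS_STD <- c("TAA", "TAG", "TGA")
## codons sampled for ORF interiors: never terminate under either genetic
## code used here, and never introduce an internal initiator, so the planted
## ORF is the canonical one on its frame
.SAFE_CODONS <- local({
  all <- as.vector(outer(outer(.NT, .NT, paste0), .NT, paste0))
  setdiff(all, c(.STOPS_STD, "ATG"))
})
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

## planted peptide instances of the built-in RdRp motif consensus patterns,
## arranged I..VI with the GDD core inside motif IV
.MOTIF_PEPTIDES <- c(I = "HDKAFILG", II = "GQRLSLDNF", III = "LKADWSTE",
                     IV = "SQNGDDL", V = "KWTSGAQI", VI = "EWGAKLLS")

.randNt <- function(n) paste(sample(.NT, n, replace = TRUE), collapse = "")

.randCodons <- function(n) {
  if (n <= 0L) return(character(0))
  sample(.SAFE_CODONS, n, replace = TRUE)
}

## reverse-translate a protein, sampling synonymous codons but never TGA
## (so the result is stop-free under the standard code too)
.reverseTranslate <- function(protein) {
  tab <- Biostrings::getGeneticCode("1")
  byAa <- split(names(tab), tab)
  vapply(strsplit(protein, "")[[1L]], function(aa) {
    cands <- setdiff(byAa[[aa]], "TGA")
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Specify one synthetic virome element
#'
#' Declares a viral element for [generateVirome()]: its genome architecture
#' (`kind`), length, antisense read fraction (the replication-intermediate
#' signature; host transcripts get a much lower fraction), genetic code, and
#' planted features.
#'
#' @param kind One of `"toti_bicistronic"` (two ORFs overlapping by 4 nt in
#'   the -1 frame with an AUGA slippage site), `"narna_mono"` /
#'   `"mito_mono"` (single RdRp ORF; the mito element uses the
#'   mold-mitochondrial code and carries the RdRp motif series),
#'   `"partiti_bipartite"` (separate RdRp and CP segments),
#'   `"satellite_toxin"` (a killer-preprotoxin ORF with the K2 feature
#'   layout) or `"orfan_like"` (a coding RNA with no database relative).
#' @param length Contig length in nt (for `partiti_bipartite`, the RNA1
#'   length; RNA2 length via `features$rna2Length`). Defaults follow the
#'   architecture: 5878 (toti), 2495 (narna), 2465 (mito), 1689/1321
#'   (partiti), 1165 (satellite), 1500 (orfan).
#' @param antisenseFrac Probability that a simulated read comes from the
#'   antisense strand; default 0.2.
#' @param geneticCode Translation table; `"mold_mitochondrial"` forced for
#'   `mito_mono`.
#' @param hasKnownRelative Whether [emitHitTable()] writes a homology hit
#'   for this element (FALSE models the database blind spot ORFan elements
#'   live in).
#' @param features Optional list: `prematureStopNt` (satellite), `orfAa`,
#'   `rna2Length`, `readthroughTga` (mito; default TRUE).
#' @param id Optional contig id (defaults to `kind` plus a counter).
#' @return A list of class `ElementSpec`.
#' @export
elementSpec <- function(kind = c("toti_bicistronic", "narna_mono",
                                 "mito_mono", "partiti_bipartite",
                                 "satellite_toxin", "orfan_like"),
                        length = NULL, antisenseFrac = 0.2,
                        geneticCode = c("standard", "mold_mitochondrial"),
                        hasKnownRelative = FALSE, features = list(),
                        id = NULL) {
  kind <- match.arg(kind)
  geneticCode <- match.arg(geneticCode)
  if (kind == "mito_mono") geneticCode <- "mold_mitochondrial"
  if (is.null(length))
    length <- switch(kind, toti_bicistronic = 5878L, narna_mono = 2495L,
                     mito_mono = 2465L, partiti_bipartite = 1689L,
                     satellite_toxin = 1165L, orfan_like = 1500L)
  stopifnot(antisenseFrac >= 0, antisenseFrac <= 1)
  structure(list(kind = kind, length = as.integer(length),
                 antisenseFrac = antisenseFrac, geneticCode = geneticCode,
                 hasKnownRelative = hasKnownRelative, features = features,
                 id = id),
            class = "ElementSpec")
}

#' Configure a synthetic virome
#'
#' Bundles the generator settings: host transcript background, viral
#' elements, and read-simulation parameters. Identical configurations with
#' identical seeds produce byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param nHost Number of host mRNA-like contigs (default 50).
#' @param hostLen Host contig length range in nt.
#' @param elements List of [elementSpec()] objects.
#' @param readLen Simulated read length in nt (default 100).
#' @param depth Mean reads per contig (Poisson; default 200).
#' @param hostAntisenseFrac Antisense read fraction for host contigs;
#'   default 0.005 — small but non-zero, modelling antisense transcription
#'   noise, so the both-strands rule (not only the ratio rule) is
#'   exercised.
#' @param errorRate Per-base substitution error rate for reads (default 0:
#'   the screen's contract is tested on exact reads; the rate exists for
#'   robustness experiments).
#' @return A list of class `ViromeConfig`.
#' @export
viromeConfig <- function(seed, nHost = 50L, hostLen = c(1200L, 2500L),
                         elements = list(), readLen = 100L, depth = 200,
                         hostAntisenseFrac = 0.005, errorRate = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            nHost >= 0L, length(hostLen) == 2L, hostLen[1L] <= hostLen[2L],
            readLen > 0L, depth > 0,
            hostAntisenseFrac >= 0, hostAntisenseFrac <= 1,
            errorRate >= 0, errorRate < 1)
  stopifnot(all(vapply(elements, inherits, logical(1), "ElementSpec")))
  structure(list(seed = as.integer(seed), nHost = as.integer(nHost),
                 hostLen = as.integer(hostLen), elements = elements,
                 readLen = as.integer(readLen), depth = depth,
                 hostAntisenseFrac = hostAntisenseFrac,
                 errorRate = errorRate),
            class = "ViromeConfig")
}

#' The default end-to-end validation fixture
#'
#' 50 host contigs, five known-virus contigs (a bicistronic toti-like
#' element, a narna-like and a mito-like monocistronic element, and a
#' bipartite partiti-like element — all with database relatives) and three
#' ORFan-like elements without relatives.
#'
#' @param seed RNG seed (default 42).
#' @return A `ViromeConfig`.
#' @export
defaultViromeConfig <- function(seed = 42L) {
  viromeConfig(
    seed = seed,
    nHost = 50L,
    elements = list(
      elementSpec("toti_bicistronic", hasKnownRelative = TRUE,
                  id = "toti1"),
      elementSpec("narna_mono", hasKnownRelative = TRUE, id = "narna1"),
      elementSpec("mito_mono", hasKnownRelative = TRUE, id = "mito1"),
      elementSpec("partiti_bipartite", hasKnownRelative = TRUE,
                  id = "partiti1"),
      elementSpec("orfan_like", id = "orfan1"),
      elementSpec("orfan_like", id = "orfan2"),
      elementSpec("orfan_like", id = "orfan3")))
}

## ---- element builders ------------------------------------------------
## Each returns list(seqs = named character vector, features = named list)

.buildTotiBicistronic <- function(spec) {
  orf1Aa <- spec$features$orf1Aa %||% 942L  # CP, upstream
  orf2Aa <- spec$features$orf2Aa %||% 882L  # RdRp, downstream
  u5 <- 50L
  orf1Nt <- 3L * (orf1Aa + 1L)
  orf2Nt <- 3L * (orf2Aa + 1L)
  u3 <- spec$length - u5 - orf1Nt - orf2Nt + 4L
  if (u3 < 10L)
    stop("toti_bicistronic element of ", spec$length,
         " nt cannot hold ORFs of ", orf1Aa, " + ", orf2Aa, " aa")
  # ORF1: ATG + interior + GCA + TGA; the terminal ...A-TGA spells the
  # ATGA (AUGA) slippage tetranucleotide once ORF2 starts 4 nt upstream
  # of ORF1's end, in the -1 frame.
  int1 <- .randCodons(orf1Aa - 2L)
  orf1 <- paste0("ATG", paste(int1, collapse = ""), "GCA", "TGA")
  s1 <- u5 + 1L
  e1 <- u5 + orf1Nt
  # ORF2 shares its ATG with ORF1's tail: A[end1-3] T G | codon2 starts at
  # end1 with ORF1's final A, so it must begin with "A".
  int2first <- paste0("A", paste(sample(.NT, 2L, replace = TRUE),
                                 collapse = ""))
  int2 <- .randCodons(orf2Aa - 2L)
  tail2 <- paste0(substr(int2first, 2L, 3L), paste(int2, collapse = ""),
                  "TAA")
  seq <- paste0(.randNt(u5), orf1, tail2, .randNt(u3))
  s2 <- e1 - 3L
  e2 <- s2 + orf2Nt - 1L
  list(seqs = setNames(seq, spec$id),
       features = setNames(list(list(
         orf1 = c(s1, e1), orf2 = c(s2, e2),
         orf1Aa = orf1Aa, orf2Aa = orf2Aa,
         slippage = c(e1 - 3L, e1), slippageSeq = "AUGA")), spec$id))
}

.buildMono <- function(spec) {
  u5 <- 40L
  orfAa <- spec$features$orfAa %||%
    (floor((spec$length - u5 - 30L) / 3L) - 1L)
  orfNt <- 3L * (orfAa + 1L)
  u3 <- spec$length - u5 - orfNt
  if (u3 < 10L || orfAa < 150L)
    stop(spec$kind, " element of ", spec$length, " nt too short")
  feats <- list(orf = c(u5 + 1L, u5 + orfNt), orfAa = orfAa)
  if (spec$kind == "mito_mono") {
    protein <- c("M", sample(.AA20, orfAa - 1L, replace = TRUE))
    # plant the motif series I..VI in order, GDD core inside motif IV
    at <- floor(orfAa * c(0.20, 0.30, 0.40, 0.50, 0.60, 0.70))
    for (k in seq_along(.MOTIF_PEPTIDES)) {
      pep <- strsplit(.MOTIF_PEPTIDES[[k]], "")[[1L]]
      protein[at[k]:(at[k] + length(pep) - 1L)] <- pep
    }
    codons <- .reverseTranslate(paste(protein, collapse = ""))
    if (isTRUE(spec$features$readthroughTga %||% TRUE)) {
      # a TGA-encoded Trp: read through under the mold-mitochondrial code,
      # a premature stop under the standard one
      wPos <- floor(orfAa * 0.85)
      codons[wPos] <- "TGA"
      feats$readthroughTgaNt <- 3L * (wPos - 1L) + 1L  # within the ORF
    }
    orf <- paste0(paste(codons, collapse = ""), "TAA")
    feats$motifStarts <- setNames(at, names(.MOTIF_PEPTIDES))
    feats$protein <- paste(protein, collapse = "")
  } else {
    orf <- paste0("ATG", paste(.randCodons(orfAa - 1L), collapse = ""),
                  "TAA")
  }
  seq <- paste0(.randNt(u5), orf, .randNt(u3))
  list(seqs = setNames(seq, spec$id),
       features = setNames(list(feats), spec$id))
}

.buildPartiti <- function(spec) {
  rna2Len <- spec$features$rna2Length %||% 1321L
  mk <- function(len, segId) {
    u5 <- 40L
    orfAa <- floor((len - u5 - 30L) / 3L) - 1L
    orfNt <- 3L * (orfAa + 1L)
    u3 <- len - u5 - orfNt
    seq <- paste0(.randNt(u5), "ATG",
                  paste(.randCodons(orfAa - 1L), collapse = ""), "TAA",
                  .randNt(u3))
    list(seq = seq, feat = list(orf = c(u5 + 1L, u5 + orfNt),
                                orfAa = orfAa, segment = segId))
  }
  r1 <- mk(spec$length, "RNA1")
  r2 <- mk(rna2Len, "RNA2")
  ids <- paste0(spec$id, c("_RNA1", "_RNA2"))
  list(seqs = setNames(c(r1$seq, r2$seq), ids),
       features = setNames(list(r1$feat, r2$feat), ids))
}

.buildSatelliteToxin <- function(spec) {
  u5 <- 40L
  orfAa <- spec$features$orfAa %||%
    (floor((spec$length - u5 - 30L) / 3L) - 1L)
  if (orfAa < 268L)
    stop("satellite_toxin element of ", spec$length,
         " nt cannot hold the full preprotoxin checklist (needs >= 268 aa)")
  orfNt <- 3L * (orfAa + 1L)
  u3 <- spec$length - u5 - orfNt
  protein <- c("M", sample(.AA20, orfAa - 1L, replace = TRUE))
  protein[27:45] <- sample(c("I", "L", "V", "F", "A"), 19L, replace = TRUE)
  for (g in c(177L, 214L, 261L)) protein[g:(g + 2L)] <- c("N", "A", "S")
  protein[220:221] <- c("K", "R")
  protein[267:268] <- c("K", "R")
  codons <- .reverseTranslate(paste(protein, collapse = ""))
  feats <- list(orf = c(u5 + 1L, u5 + orfNt), orfAa = orfAa,
                toxinSites = TRUE)
  stopNt <- spec$features$prematureStopNt
  if (!is.null(stopNt)) {
    stopifnot(stopNt %% 3L == 1L, stopNt < 3L * orfAa)
    codons[(stopNt - 1L) / 3L + 1L] <- "TAA"
    feats$prematureStopNt <- as.integer(stopNt)
  }
  feats$protein <- paste(protein, collapse = "")
  seq <- paste0(.randNt(u5), paste(codons, collapse = ""), "TAA",
                .randNt(u3))
  list(seqs = setNames(seq, spec$id),
       features = setNames(list(feats), spec$id))
}

.buildElement <- function(spec) {
  switch(spec$kind,
         toti_bicistronic = .buildTotiBicistronic(spec),
         narna_mono = .buildMono(spec),
         mito_mono = .buildMono(spec),
         orfan_like = .buildMono(spec),
         partiti_bipartite = .buildPartiti(spec),
         satellite_toxin = .buildSatelliteToxin(spec))
}

## verify that the emitted contig satisfies its architecture before release
.verifyElement <- function(spec, seqs, features) {
  for (id in names(seqs)) {
    feat <- features[[id]]
    dna <- Biostrings::DNAString(seqs[[id]])
    code <- spec$geneticCode
    if (spec$kind == "toti_bicistronic") {
      orfs <- findOrfs(dna, "standard", minAa = 150L, contigId = id)
      rowOf <- function(span) {
        i <- which(orfs$start == span[1L] & orfs$end == span[2L] &
                     orfs$strand == "+")
        if (length(i)) i[1L] else NA_integer_
      }
      i1 <- rowOf(feat$orf1); i2 <- rowOf(feat$orf2)
      if (is.na(i1) || is.na(i2)) return(FALSE)
      # the longest ORF must be the planted upstream (CP) ORF
      if (i1 != 1L) return(FALSE)
      ov <- detectSlippageOverlap(orfs[i1, ], orfs[i2, ], dna)
      if (is.null(ov) || ov$overlapSeq != "AUGA" ||
          ov$frameshift != -1L) return(FALSE)
    } else if (!is.null(feat$prematureStopNt)) {
      ps <- detectPrematureStop(dna, feat$orf, code)
      if (!ps$defective ||
          !(feat$prematureStopNt %in% ps$positions)) return(FALSE)
    } else {
      orfs <- findOrfs(dna, code, minAa = 1L, contigId = id)
      if (nrow(orfs) == 0L ||
          orfs$start[1L] != feat$orf[1L] ||
          orfs$end[1L] != feat$orf[2L] ||
          orfs$strand[1L] != "+") return(FALSE)
      if (spec$kind == "mito_mono" && !is.null(feat$motifStarts)) {
        sc <- scanRdrpMotifs(feat$protein)
        for (mid in names(feat$motifStarts)) {
          hit <- sc[sc$motifId == mid, , drop = FALSE]
          if (nrow(hit) != 1L ||
              hit$start[1L] != feat$motifStarts[[mid]]) return(FALSE)
        }
        gdd <- sc$start[sc$motifId == "GDD"]
        if (!(feat$motifStarts[["IV"]] + 3L) %in% gdd) return(FALSE)
        if (isTRUE(S4Vectors::metadata(sc)$incompleteSeries)) return(FALSE)
      }
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic virome with a ground-truth manifest
#'
#' Emits host mRNA-like contigs (near-zero antisense read fraction) and
#' viral elements of the declared architectures (substantial antisense
#' fractions), each verified against its architectural invariants before
#' release (the longest ORF is the planted one, the slippage overlap reads
#' AUGA in the -1 frame, planted premature stops are detectable). All coding
#' interiors are sampled stop-free codon by codon, so planted stops are the
#' only internal stops.
#'
#' @param config A [viromeConfig()].
#' @return A list with `contigs` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (a [S4Vectors::DataFrame] manifest: one row per contig with
#'   `contigId`, `kind`, `lengthNt`, `antisenseFrac`, `geneticCode`,
#'   `hasKnownRelative`; planted feature coordinates live in
#'   `metadata(truth)$features`, keyed by contig id).
#' @examples
#' vir <- generateVirome(defaultViromeConfig(seed = 1))
#' table(vir$truth$kind)
#' @export
generateVirome <- function(config) {
  stopifnot(inherits(config, "ViromeConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  seqs <- character(0)
  rows <- list()
  featureMap <- list()
  if (config$nHost > 0L) {
    lens <- sample(seq(config$hostLen[1L], config$hostLen[2L]),
                   config$nHost, replace = TRUE)
    for (i in seq_len(config$nHost)) {
      id <- sprintf("host_%03d", i)
      seqs[id] <- .randNt(lens[i])
      rows[[length(rows) + 1L]] <- data.frame(
        contigId = id, kind = "host", lengthNt = lens[i],
        antisenseFrac = config$hostAntisenseFrac,
        geneticCode = "standard", hasKnownRelative = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  counters <- integer(0)
  for (spec in config$elements) {
    if (is.null(spec$id)) {
      counters[spec$kind] <- (counters[spec$kind] %||% 0L)
      counters[spec$kind] <- ifelse(is.na(counters[spec$kind]), 1L,
                                    counters[spec$kind] + 1L)
      spec$id <- sprintf("%s_%02d", spec$kind, counters[spec$kind])
    }
    built <- NULL
    for (try in 1:20) {
      cand <- .buildElement(spec)
      if (.verifyElement(spec, cand$seqs, cand$features)) {
        built <- cand
        break
      }
    }
    if (is.null(built))
      stop("could not realise element '", spec$id,
           "' satisfying its invariants; check the element spec")
    for (id in names(built$seqs)) {
      if (id %in% names(seqs)) stop("duplicate contig id: ", id)
      seqs[id] <- built$seqs[[id]]
      featureMap[[id]] <- built$features[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        contigId = id, kind = spec$kind, lengthNt = nchar(built$seqs[[id]]),
        antisenseFrac = spec$antisenseFrac,
        geneticCode = spec$geneticCode,
        hasKnownRelative = spec$hasKnownRelative,
        stringsAsFactors = FALSE)
    }
  }
  truth <- S4Vectors::DataFrame(do.call(rbind, rows))
  S4Vectors::metadata(truth) <- list(features = featureMap)
  contigs <- Biostrings::DNAStringSet(seqs)
  stopifnot(identical(names(contigs), truth$contigId))
  list(contigs = contigs, truth = truth)
}

#' Mutate a sequence to a target percent identity
#'
#' Substitution-only mutant: exactly `round((100 - targetPct) * L / 100)`
#' positions, sampled without replacement, are replaced with a different
#' residue. Supports the planted-identity recovery tests: for lengths >=
#' 1000 the ungapped identity to the input is within half a point of the
#' target by construction.
#'
#' @param seq `XString`/character sequence.
#' @param targetPct Target percent identity in (0, 100].
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed RNG seed.
#' @return A character string (the mutant).
#' @export
mutateToIdentity <- function(seq, targetPct,
                             alphabet = c("nucleotide", "protein"), seed) {
  alphabet <- match.arg(alphabet)
  stopifnot(targetPct > 0, targetPct <= 100)
  floorPct <- if (alphabet == "nucleotide") 25 else 5
  if (targetPct < floorPct)
    stop("target identity ", targetPct,
         "% is below the random-alphabet noise floor (", floorPct, "%)")
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
    seq <- as.character(if (methods::is(seq, "XStringSet")) seq[[1L]]
                        else seq)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  nMut <- round((100 - targetPct) * L / 100)
  if (nMut == 0L) return(paste(chars, collapse = ""))
  residues <- if (alphabet == "nucleotide") .NT else .AA20
  pos <- sample(L, nMut)
  for (i in pos)
    chars[i] <- sample(setdiff(residues, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Simulate strand-annotated reads from a contig set
#'
#' Per contig, `Poisson(depth)` single-end reads are drawn at uniform start
#' positions; each read is antisense (reverse complement) with that contig's
#' `antisenseFrac` from the truth manifest. Substitution errors are applied
#' at `errorRate`. Read headers carry the truth strand
#' (`strand=sense`/`strand=antisense`) and source contig.
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param truth The manifest from [generateVirome()].
#' @param config The [viromeConfig()] used for generation.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A [Biostrings::DNAStringSet] of reads with `mcols()` columns
#'   `truthStrand` and `sourceContig`.
#' @export
simulateReads <- function(contigs, truth, config, seed = config$seed + 1L) {
  stopifnot(methods::is(contigs, "DNAStringSet"),
            all(names(contigs) %in% truth$contigId))
  if (any(Biostrings::width(contigs) < config$readLen))
    stop("readLen exceeds the shortest contig")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  readSeqs <- character(0)
  truthStrand <- character(0)
  source <- character(0)
  counter <- 0L
  for (id in names(contigs)) {
    frac <- truth$antisenseFrac[match(id, truth$contigId)]
    L <- Biostrings::width(contigs[id])
    n <- stats::rpois(1L, config$depth)
    if (n == 0L) next
    starts <- sample.int(L - config$readLen + 1L, n, replace = TRUE)
    anti <- stats::runif(n) < frac
    s <- as.character(contigs[[id]])
    frags <- substring(s, starts, starts + config$readLen - 1L)
    if (any(anti))
      frags[anti] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frags[anti])))
    if (config$errorRate > 0) {
      for (j in seq_len(n)) {
        nErr <- stats::rbinom(1L, config$readLen, config$errorRate)
        if (nErr > 0L) {
          cs <- strsplit(frags[j], "")[[1L]]
          at <- sample(config$readLen, nErr)
          for (p in at) cs[p] <- sample(setdiff(.NT, cs[p]), 1L)
          frags[j] <- paste(cs, collapse = "")
        }
      }
    }
    ids <- sprintf("r%06d", counter + seq_len(n))
    counter <- counter + n
    readSeqs[ids] <- frags
    truthStrand <- c(truthStrand,
                     ifelse(anti, "antisense", "sense"))
    source <- c(source, rep(id, n))
  }
  reads <- Biostrings::DNAStringSet(readSeqs)
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
    truthStrand = truthStrand, qualities = Biostrings::BStringSet(
      vapply(Biostrings::width(reads),
             function(w) strrep("I", w), character(1))),
    sourceContig = source)
  reads
}

#' Write reads as FASTQ
#'
#' Headers carry `contig=` and `strand=` tags so the truth strand survives a
#' round trip through [readReads()].
#'
#' @param reads A read set from [simulateReads()].
#' @param path Output path (plain or `.gz`).
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
  mc <- S4Vectors::mcols(reads)
  out <- reads
  hdr <- names(reads)
  if (!is.null(mc$sourceContig))
    hdr <- paste0(hdr, " contig=", mc$sourceContig)
  if (!is.null(mc$truthStrand))
    hdr <- paste0(hdr, " strand=", mc$truthStrand)
  names(out) <- hdr
  quals <- mc$qualities %||% Biostrings::BStringSet(
    vapply(Biostrings::width(reads), function(w) strrep("I", w),
           character(1)))
  Biostrings::writeXStringSet(out, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Emit the homology hit table implied by the truth manifest
#'
#' Host contigs and viral elements with a known database relative get one
#' synthetic hit each (e-value 1e-50); ORFan-like elements get none — they
#' are exactly the records the homology filter cannot remove, which is the
#' screen's blind spot and the reason the strand-ratio signature exists.
#'
#' @param truth The manifest from [generateVirome()].
#' @return A hit table data.frame (12-column dialect, see
#'   [readHitTable()]).
#' @export
emitHitTable <- function(truth) {
  hit <- truth$hasKnownRelative
  ids <- truth$contigId[hit]
  kinds <- truth$kind[hit]
  data.frame(queryId = ids,
             subjectId = paste0("ref_", kinds),
             pctIdentity = 90, alnLen = 300, mismatches = 30, gapOpens = 0,
             qStart = 1, qEnd = 300, sStart = 1, sEnd = 300,
             evalue = 1e-50, bitscore = 500,
             stringsAsFactors = FALSE)
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits A hit table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
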