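## Accession sets for the deposited-record checks. Each file is expected at
## <dir>/<accession>.fasta (single-record FASTA, as downloaded from NCBI).
.LA_CP_SET <- sprintf("OK3770%02d", 6:17)    # L-A CP fragments
.LBC_SET <- sprintf("OK3770%02d", 18:25)     # L-BC fragments

.readAccession <- function(dir, acc, alphabet = "nucleotide") {
  path <- file.path(dir, paste0(acc, ".fasta"))
  if (!file.exists(path)) return(NULL)
  readFasta(path, alphabet)
}

#' Verify sequence-level findings on the deposited GenBank records
#'
#' Runs the package's annotation and identity machinery on the deposited
#' GenBank records and compares the results with the published values:
#' the bicistronic totivirus ORF layout (942 aa CP, 882 aa RdRp) and its
#' AUGA slippage overlap; the 714 aa mitovirus RdRp ORF; the defective
#' satellite toxin ORF with its premature stop at nt 232; the headline
#' pairwise identities (97.7% cryspovirus RdRp nt, 94.75% narnavirus vs
#' 20S, 55.9% vs I329, 96.1% L-BC-La vs its reference) and the identity-range
#' minima of the L-A CP (77.6%) and L-BC (95.5%) fragment sets.
#'
#' The records are user-supplied: download each accession as FASTA and place
#' it at `<dir>/<accession>.fasta`. Checks whose records are missing are
#' reported with status `"missing_record"`.
#'
#' @param dir Directory holding `<accession>.fasta` files.
#' @param tolerance Identity tolerance in percentage points (default 0.3,
#'   absorbing alignment-parameter sensitivity).
#' @return A data.frame with columns `check`, `expected`, `value`, `status`
#'   (`"pass"`, `"fail"` or `"missing_record"`).
#' @export
verifyDepositedRecords <- function(dir, tolerance = 0.3) {
  rows <- list()
  add <- function(check, expected, value) {
    status <- if (is.null(value)) "missing_record"
    else if (is.numeric(expected)) {
      if (is.finite(value) && abs(value - expected) <= tolerance) "pass"
      else "fail"
    } else if (identical(as.character(value), as.character(expected)))
      "pass" else "fail"
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = as.character(expected),
      value = if (is.null(value)) NA_character_ else as.character(value),
      status = status, stringsAsFactors = FALSE)
  }
  idPct <- function(a, b, alphabet = "nucleotide") {
    if (is.null(a) || is.null(b)) return(NULL)
    round(pDistanceIdentity(globalAlign(a[[1L]], b[[1L]],
                                        alphabet))$pctIdentity, 2L)
  }

  # SbTV1: bicistronic layout and slippage site
  sbtv <- .readAccession(dir, "OK412911")
  if (!is.null(sbtv)) {
    orfs <- findOrfs(sbtv[[1L]], "standard", minAa = 300L)
    add("SbTV1_CP_aa", 942, if (nrow(orfs) >= 1L) orfs$proteinLen[1L])
    add("SbTV1_RdRp_aa", 882, if (nrow(orfs) >= 2L) orfs$proteinLen[2L])
    ov <- if (nrow(orfs) >= 2L)
      detectSlippageOverlap(orfs[1L, ], orfs[2L, ], sbtv[[1L]]) else NULL
    add("SbTV1_slippage_seq", "AUGA",
        if (!is.null(ov)) ov$overlapSeq)
  } else {
    add("SbTV1_CP_aa", 942, NULL)
    add("SbTV1_RdRp_aa", 882, NULL)
    add("SbTV1_slippage_seq", "AUGA", NULL)
  }

  # SbMV1: mitovirus RdRp under the mold-mitochondrial code
  sbmv <- .readAccession(dir, "OK412910")
  add("SbMV1_RdRp_aa", 714, if (!is.null(sbmv)) {
    orfs <- findOrfs(sbmv[[1L]], "mold_mitochondrial", minAa = 300L)
    if (nrow(orfs)) orfs$proteinLen[1L]
  })

  # M-lus: defective toxin ORF, premature stop at nt 232 of the K-lus frame
  mlus <- .readAccession(dir, "OK412909")
  add("Mlus_premature_stop_nt", 232, if (!is.null(mlus)) {
    ps <- detectPrematureStop(mlus[[1L]],
                              c(1L, 3L * (length(mlus[[1L]]) %/% 3L)))
    if (ps$defective) ps$positions[1L]
  })

  # ScCV1 RdRp nucleotide identity between the two isolates
  add("ScCV1_RdRp_nt_identity", 97.7,
      idPct(.readAccession(dir, "OK412915"),
            .readAccession(dir, "OK412916")))
  # narnavirus vs 20S reference and vs I329 RdRp
  add("NDA21_vs_20S_nt_identity", 94.75,
      idPct(.readAccession(dir, "OK412912"),
            .readAccession(dir, "AF039063")))
  add("NDA21_vs_I329_RdRp_aa_identity", 55.9,
      idPct(.readAccession(dir, "OK412912_RdRp_aa"),
            .readAccession(dir, "QFU28543"), "protein"))
  # L-BC-La vs its reference
  add("LBCLa_vs_U01060_nt_identity", 96.1,
      idPct(.readAccession(dir, "OK377018"),
            .readAccession(dir, "U01060")))

  # identity-range minima over the deposited fragment sets
  rangeMin <- function(accs) {
    seqs <- lapply(accs, .readAccession, dir = dir)
    if (any(vapply(seqs, is.null, logical(1)))) return(NULL)
    set <- Biostrings::DNAStringSet(
      setNames(vapply(seqs, function(s) as.character(s[[1L]]),
                      character(1)), accs))
    round(identityRange(identityMatrix(set, "nucleotide"))[["min"]], 1L)
  }
  add("LA_CP_min_nt_identity", 77.6, rangeMin(.LA_CP_SET))
  add("LBC_min_nt_identity", 95.5, rangeMin(.LBC_SET))

  do.call(rbind, rows)
}
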