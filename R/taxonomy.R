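## genus-level hypotheses mapped onto the taxon scope the rules use
.SCOPE_ALIASES <- c(narnavirus = "narnavirus", mitovirus = "mitovirus",
                    totivirus = "totivirus", partitivirus = "partitivirus",
                    cryspovirus = "partitivirus")

#' ICTV demarcation rules shipped with the package
#'
#' Loads the threshold table used by [classifyCandidate()]: narnavirus
#' species at 50% RdRp aa identity, mitovirus species at 40% RdRp aa,
#' totivirus species below 50% aa (host specificity is carried as metadata,
#' never decided automatically), partitivirus species at 80% CP aa / 90%
#' RdRp aa, and partitivirus genus demarcation below 24% RdRp aa. "Below"
#' relations are strict (`<`).
#'
#' @param file Path to a rules TSV (columns `taxon_scope`, `marker`,
#'   `threshold`, `relation`, `source_note`); defaults to the built-in file.
#' @return A data.frame with columns `taxonScope`, `marker`, `threshold`,
#'   `relation`, `sourceNote`.
#' @export
demarcationRules <- function(file = system.file("extdata",
                                                "demarcation_rules.tsv",
                                                package = "viromeScreen")) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon_scope", "marker", "threshold", "relation", "source_note")
  stopifnot(all(need %in% names(tab)))
  out <- data.frame(taxonScope = tab$taxon_scope, marker = tab$marker,
                    threshold = as.numeric(tab$threshold),
                    relation = tab$relation, sourceNote = tab$source_note,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$threshold > 0 & out$threshold < 100),
            all(out$relation %in% c("below_means_new_species",
                                    "below_means_new_genus")))
  out
}

#' Classify a candidate virus against ICTV demarcation thresholds
#'
#' Given the candidate's best identities to reference viruses per marker,
#' applies the demarcation rules for its hypothesised genus: if any marker
#' identity reaches its species threshold the candidate is a variant of a
#' known species; otherwise, if a genus-level rule exists and the best RdRp
#' identity falls strictly below its threshold, a new genus is proposed;
#' otherwise a new species. Verdicts are candidate labels, never
#' authoritative taxonomy; the applied rules and their source notes travel
#' with the verdict.
#'
#' @param candidateId Identifier of the candidate virus.
#' @param genusHypothesis Hypothesised genus (e.g. `"narnavirus"`,
#'   `"mitovirus"`, `"totivirus"`, `"cryspovirus"`/`"partitivirus"`).
#' @param bestHits A data.frame with columns `referenceId`, `marker`
#'   (`RdRp_aa`, `CP_aa` or `nt`) and `pctIdentity` in [0, 100].
#' @param rules A rules table, see [demarcationRules()].
#' @param note Optional free-text note carried into the verdict (e.g. a
#'   phylogeny-based genus placement remark).
#' @return A [Classification].
#' @examples
#' classifyCandidate("ScNV-NDA21", "narnavirus",
#'   data.frame(referenceId = "ScNV-20S", marker = "RdRp_aa",
#'              pctIdentity = 98.6))
#' @export
classifyCandidate <- function(candidateId, genusHypothesis, bestHits,
                              rules = demarcationRules(), note = "") {
  stopifnot(is.data.frame(bestHits),
            all(c("referenceId", "marker", "pctIdentity") %in%
                  names(bestHits)),
            all(bestHits$pctIdentity >= 0 & bestHits$pctIdentity <= 100))
  scope <- .SCOPE_ALIASES[tolower(genusHypothesis)]
  mk <- function(verdict, applied, bestRef, extra = "")
    methods::new("Classification", candidateId = candidateId,
                 verdict = verdict, rulesApplied = applied,
                 bestReference = bestRef,
                 note = trimws(paste(note, extra)))
  none <- rules[0L, ]
  if (is.na(scope))
    return(mk("unresolved", none, NA_character_,
              sprintf("no demarcation rules for genus hypothesis '%s'",
                      genusHypothesis)))
  scoped <- rules[rules$taxonScope == scope, , drop = FALSE]
  speciesRules <- scoped[scoped$relation == "below_means_new_species", ,
                         drop = FALSE]
  speciesRules <- speciesRules[speciesRules$marker %in% bestHits$marker, ,
                               drop = FALSE]
  if (nrow(speciesRules) == 0L)
    return(mk("unresolved", none, NA_character_,
              sprintf("no applicable rule for markers {%s} in scope '%s'",
                      paste(unique(bestHits$marker), collapse = ", "),
                      scope)))
  bestByMarker <- vapply(split(bestHits, bestHits$marker),
                         function(d) max(d$pctIdentity), numeric(1))
  bestRefOf <- function(marker) {
    d <- bestHits[bestHits$marker == marker, , drop = FALSE]
    d$referenceId[which.max(d$pctIdentity)]
  }
  for (i in seq_len(nrow(speciesRules))) {
    r <- speciesRules[i, ]
    if (bestByMarker[[r$marker]] >= r$threshold)
      return(mk("variant_of_known_species", speciesRules,
                bestRefOf(r$marker)))
  }
  genusRules <- scoped[scoped$relation == "below_means_new_genus" &
                         scoped$marker %in% bestHits$marker, , drop = FALSE]
  if (nrow(genusRules)) {
    r <- genusRules[1L, ]
    if (bestByMarker[[r$marker]] < r$threshold)
      return(mk("new_genus_candidate", rbind(speciesRules, genusRules),
                bestRefOf(r$marker)))
  }
  decisive <- speciesRules$marker[1L]
  mk("new_species_candidate", rbind(speciesRules, genusRules),
     bestRefOf(decisive))
}

#' Summarise a per-strain infection table
#'
#' Tallies the infection table: strains with at least one detection, strains
#' with detections in at least two distinct virus columns (a helper virus
#' and its satellite count as distinct columns), and per-virus strain
#' counts. Strains with no detections may be absent from the table, so the
#' total tested is supplied separately.
#'
#' @param table A long-form detection table from [readInfectionTable()] (or
#'   a data.frame with `strain` and `virus` columns).
#' @param totalStrains Number of strains tested (default 24).
#' @return A list with `nStrains`, `nInfected`, `nMixed` and
#'   `perVirusCounts` (named integer vector).
#' @export
buildInfectionSummary <- function(table, totalStrains = 24L) {
  tab <- as.data.frame(table)
  stopifnot(all(c("strain", "virus") %in% names(tab)))
  if (anyDuplicated(tab[c("strain", "virus")]))
    stop("duplicate strain/virus detection rows")
  perStrain <- tapply(tab$virus, tab$strain,
                      function(v) length(unique(v)))
  nInfected <- length(perStrain)
  if (nInfected > totalStrains)
    stop("more infected strains than strains tested")
  viruses <- if (methods::is(table, "DataFrame") &&
                 !is.null(S4Vectors::metadata(table)$viruses))
    S4Vectors::metadata(table)$viruses else sort(unique(tab$virus))
  counts <- vapply(viruses, function(v)
    length(unique(tab$strain[tab$virus == v])), integer(1))
  list(nStrains = as.integer(totalStrains),
       nInfected = nInfected,
       nMixed = sum(perStrain >= 2L),
       perVirusCounts = counts)
}
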