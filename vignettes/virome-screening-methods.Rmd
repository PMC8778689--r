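---
title: "Methods: strand-ratio virome triage and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-ratio virome triage and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeScreen)
```

## The screening model

Mycoviruses in a yeast transcriptome assembly fall into two detection
regimes. Viruses with database relatives are found by protein homology
search; `viromeScreen` consumes that search's 12-column hit table as an
input. The residue of interest is everything homology cannot see: ORFan
contigs, which encode proteins with no detectable relatives. For these the
screen relies on a physical property of replication. A replicating RNA —
dsRNA or an ssRNA passing through a double-stranded replicative form —
produces sequencing reads from *both* strands in comparable amounts, while
an ordinary host transcript yields almost exclusively sense reads, with
only a trace of antisense transcription noise.

The filter therefore keeps a contig when all of the following hold:

1. **No homology**: no hit at e-value ≤ `evalueMax` (default `1e-5`).
2. **Length**: contig length strictly greater than `minContigLen`
   (default 1000 nt). The bound is read literally as "over 1 kb"; the
   boundary value 1000 fails.
3. **Coding**: the longest encoded protein is at least `minProteinLen`
   amino acids (default 150 aa, roughly 15 kDa; the mass is treated as a
   gloss on the length criterion, not an independent filter).
4. **Both strands**: at least one read assigned to each strand.
5. **Ratio**: antisense/sense read ratio at least `minStrandRatio`
   (default 0.1). The published heuristic is "around 1/10"; because the
   softening is not quantified, the exact 0.1 sits in a parameter rather
   than a guess at something more precise. The rule is a lower bound only:
   antisense-dominant contigs (ratio > 1) pass.

**Orientation.** Assemblers emit contigs in arbitrary orientation, so
"sense" cannot mean "the stored strand". The screen orients each contig by
its longest ORF: the strand carrying it is the coding (sense) strand, and
the ratio is computed as antisense/sense after that reorientation. This
makes verdicts invariant under reverse-complementing a contig, which the
test suite checks explicitly. The ratio is undefined when the sense count
is zero; such contigs fail the both-strands rule anyway.

**Nucleic-acid verification.** A sequence-level pass cannot distinguish a
replicating RNA from a transcribed genomic locus. The wet-lab
disambiguation — a PCR signal on total nucleic acid, not only on cDNA — is
carried as an optional `dnaPositive` flag per contig: a DNA-positive ORFan
is flagged `genomicOrigin` and excluded from the viral pool
(`viralCandidate = FALSE`) even though `passed` stays `TRUE`, mirroring how
one of three screened ORFans typically resolves to a host locus.

## Strand mapping

The mapper is a deliberately minimal, fully specified contract rather than
a re-implementation of a gapped aligner. Every k-mer of every contig is
indexed on both strands (`k = 21`, odd, default). A read is assigned to the
(contig, strand) pair matching the largest fraction of its k-mers, provided
that fraction reaches `minFrac` (default 0.5) and strictly exceeds the
runner-up; exact ties are *ambiguous* and excluded from both strand counts
(splitting them would blur the very statistic the screen relies on), and
everything else is *unassigned*. No mismatches are tolerated within a
k-mer — tolerance arises from requiring only a fraction of k-mers to match.
Palindromic k-mers index both strands and can therefore never decide
orientation alone. Reads are treated single-end; paired input is mapped
mate-wise with the mate-2 strand flipped (FR convention). Conservation
(`assigned + ambiguous + unassigned = total`) holds by construction and is
asserted in the class validity method.

With error-free reads and `k = 21`, a 100-nt read from a unique region
matches 80/80 k-mers and assignment is exact; the recovered antisense
fraction of a simulated contig lands inside the 99% binomial interval of
the planted fraction, which is how the mapper is validated.

## ORF prediction and annotation

`findOrfs()` enumerates every complete ORF — initiator `ATG` to the next
in-frame stop — on both strands and all three frames. Near-cognate starts
are out of scope, matching the default behaviour of the usual ORF-finding
tools. The genetic code is selectable: under `"mold_mitochondrial"`, the
standard choice for fungal mitoviruses (which replicate in mitochondria),
`TGA` encodes tryptophan and only `TAA`/`TAG` terminate. All coordinates
are 1-based, inclusive, on the forward strand of the stored sequence, and
the reported span includes the stop codon, so a complete ORF satisfies
`proteinLen = (end - start + 1)/3 - 1`. Correctness is established against
a brute-force oracle (per-ATG codon walk) on random sequences up to 2 kb
under both codes.

Three feature analyses sit on top:

- **Slippage overlaps** (`detectSlippageOverlap()`): the intersection of
  two same-strand ORF ranges, its sequence rendered in the RNA alphabet
  (internally all nucleotide data are stored DNA-alphabet, `U`
  normalised to `T`; display of genome features uses RNA), and the frame
  shift reported as −1/0/+1. The bicistronic totivirus architecture places
  a 4-nt `AUGA` overlap in the −1 frame between CP and RdRp.
- **RdRp motifs** (`scanRdrpMotifs()`): the GDD catalytic tripeptide by
  exact search (all occurrences), and motifs I–VI by degenerate consensus
  patterns. The patterns ship as an editable data file
  (`inst/extdata/rdrp_motifs.tsv`) rather than code, because consensus
  expressions are alignment-derived artefacts a curator may wish to
  re-derive; motif IV must contain the GDD core. Fewer than six motifs in
  increasing order raises an `incompleteSeries` flag.
- **K2 preprotoxin checklist** (`validateK2Preprotoxin()`): hydrophobic
  N-terminal window aa 27–45 (mean Kyte–Doolittle hydropathy > 0 — the
  published description says only "hydrophobic", so a sign test on the
  standard scale is the least-committal formalisation), N-glycosylation
  sequons N-X-S/T (X ≠ P) opening each 4-aa window at 177, 214 and 261
  (the 4th position is reported as context), and `KR` dipeptides at the
  KEX1 (220–221) and KEX2 (267–268) cleavage windows. Truncated proteins
  get partial reports with "not evaluable" entries rather than errors, and
  substitutions are listed position-wise against a supplied reference.

`detectPrematureStop()` reports every in-frame stop strictly before a
region's final codon by the 1-based position of its first nucleotide
*within the analysed region* — deposited fragments and full genomes use
different coordinate systems, so positions are always relative to the
input actually analysed.

## Identity statistics

Percent identity uses the p-distance method: over a pairwise global
alignment, columns containing a gap in either sequence are excluded
(pairwise deletion — the default of the software this statistic is
standardly computed with, as opposed to complete deletion) and
`pct = 100 · identical / compared`. The aligner is an affine-gap
Needleman–Wunsch (Gotoh) written in C++ via Rcpp: nucleotide match +2 /
mismatch −3, gap open −5 / extend −2 (a gap of length L costs
`open + L·extend`); protein BLOSUM62 with open −11 / extend −1. The
traceback is deterministic — on ties prefer diagonal, then up, then left —
so `identity(a, b) = identity(b, a)` exactly. Scores are verified against
exhaustive enumeration of all alignments for strings up to length 8, and
against an independent aligner (Biostrings) under the same scoring model
for longer pairs.

Pairwise alignment replaces multiple alignment deliberately: the fragment
sets this statistic is applied to cover the same amplicon region, where
pairwise and multiple alignment agree in practice; multiple alignment is
out of scope. Trimming to a shared region is an explicit coordinate-range
extraction (`trimRange()`), never automatic. Matrices report full
precision; displays round to one decimal, and the planted-identity
recovery tests allow ±1 point to absorb alignment-tie effects on divergent
pairs.

## ICTV demarcation rules

The classification engine consumes a rules table
(`inst/extdata/demarcation_rules.tsv`): per taxon scope, a marker
(`RdRp_aa`, `CP_aa`, `nt`), a threshold, and a relation
(`below_means_new_species` or `below_means_new_genus`). "Below" is strict
(`<`), matching the wording of the published criteria. The verdict logic:
any marker at or above its species threshold ⇒ variant of a known species;
otherwise a genus rule firing (best RdRp identity strictly below the genus
threshold) ⇒ new genus candidate; otherwise ⇒ new species candidate; no
applicable rule ⇒ unresolved, with an explanation. Classification is
monotone in identity. Host specificity, part of the published totivirus
criteria, is not computable from sequence and is carried only as free-text
notes — it never decides a verdict. Where a candidate's genus placement
rests on phylogeny rather than a numeric rule (the totivirus case), the
engine reports a species-level verdict and the note field carries the
genus proposal. Published identities measured by different methods (local
alignment vs p-distance) are pinned to the value reported in each
candidate's primary characterisation.

The infection-table summariser counts a strain as *mixed* when it has
detections in at least two distinct virus columns, so a helper totivirus
plus its satellite M dsRNA counts as a mixed infection — this is the
arithmetic that reproduces the published 13-of-15 tally.

## What the synthetic virome emulates — and what it does not

The generator produces the statistical structure the screen assumes:

- host contigs: uniform random sequence, antisense read fraction 0.005 —
  small but non-zero, so the both-strands rule is exercised and not only
  the ratio rule;
- viral elements: each architecture above, with antisense fraction 0.2 by
  default and lengths defaulting to those typical of the real genomes
  (5878 nt bicistronic toti-like, 2495/2465 nt narna-/mito-like,
  1689 + 1321 nt bipartite partiti-like, 1165 nt toxin satellite);
- reads: per contig `Poisson(depth)` single-end reads (default mean 200,
  length 100 nt) at uniform positions, antisense with the contig's
  planted fraction, error-free by default (`errorRate` exists for
  robustness experiments only — the contract under test is the filter
  logic, not mapper sensitivity);
- a hit table covering hosts and elements with `hasKnownRelative = TRUE`,
  and never the ORFan-like elements — by construction, documenting the
  homology filter's blind spot;
- a truth manifest with planted feature coordinates, verified internally
  before emission (the longest ORF is the planted one, the slippage
  overlap reads `AUGA` in the −1 frame, planted premature stops are
  found); elements failing verification are resampled.

Coding interiors are sampled codon-aware from codons that neither
terminate under either genetic code nor introduce an internal initiator,
so planted stops are the only internal stops and the planted ORF is the
canonical one on its frame. Fixed seeds make all outputs byte-identical.

The generator does **not** emulate: sequencing error profiles or quality
models, indels, coverage bias, chimeric or fragmented assemblies,
paired-end inserts, or homology gradients (hits are binary). Passing tests
therefore demonstrate the correctness of the filter logic and statistics
under clean, well-separated conditions — not the sensitivity of the screen
on degraded real libraries, where mapping ambiguity and assembly artefacts
would erode the strand counts before the filter ever sees them.

## Numerical and engineering choices

- `k = 21`, `minFrac = 0.5`: desk-scale exactness on synthetic data; the
  upstream mapper settings of the original wet-lab pipeline are not part
  of this package's contract.
- Ambiguous reads excluded rather than fractionally split: keeps the
  ratio statistic well-defined.
- Degenerate inputs fail loudly: empty sequences are alignment errors,
  single-label matrices are range errors, duplicate ids are container
  errors, zero comparable alignment columns yield an explicit
  `defined = FALSE` rather than `NaN`.
- Problem sizes in the tests and the acceptance script — 58-contig
  fixtures at depth 200, 2000-read binomial checks, 1.2–1.5 kb identity
  pairs, ≤ 2 kb oracle sequences — are chosen as the smallest sizes at
  which every statistic is comfortably separated from its decision
  boundary.

## Known limitations

- The screen's sensitivity floor is the antisense noise level of real
  libraries; the 0.1 default ratio is a heuristic, not a calibrated
  error rate.
- Identity values on highly divergent proteins depend on alignment
  parameters; a ±0.3-point sensitivity band applies when comparing
  against published values computed with other aligners.
- Sequence-level checks against the deposited GenBank records require the
  records as local FASTA files (`verifyDepositedRecords()`); they are not
  shipped.
- The rule engine encodes numeric demarcation criteria only; phylogenetic
  placement, terminal-sequence analysis and host-range evidence remain
  expert judgements outside its scope.
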