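# viromeScreen

Strand-ratio virome triage for yeast RNA-seq assemblies.

Wine yeasts (*Saccharomyces cerevisiae* and non-*Saccharomyces* species
such as *Starmerella bacillaris*) host dsRNA totiviruses and their
killer-toxin satellites, capsidless narnaviruses and mitoviruses, and
partitiviruses. In a transcriptome assembly these viruses hide among tens of
thousands of host contigs, and the most interesting candidates — ORFans,
contigs encoding proteins with no database homology — cannot be found by
similarity search at all. What does give them away is a
**replication-intermediate signature**: a replicating RNA accumulates reads
on *both* strands, with an antisense/sense ratio well above the faint
antisense noise of ordinary transcription.

`viromeScreen` implements the desk half of such a screen, end to end:

- **Strand mapping** — a stranded k-mer index assigns reads to contigs with
  orientation and tallies per-contig sense/antisense counts (`StrandCounts`).
- **ORFan screen** — homology exclusion from a 12-column hit table, then
  length (> 1 kb), coding (longest ORF ≥ 150 aa) and strand-signature rules:
  reads on both strands and antisense/sense ≥ 0.1, with sense defined by the
  strand carrying the longest ORF.
- **ORF annotation** — ORF prediction under the standard or
  mold-mitochondrial code (`UGA` → Trp for mitoviruses), −1 ribosomal
  slippage overlaps (the totivirus CP–RdRp `AUGA` site), RdRp motifs I–VI
  with the GDD core, the K2 killer-preprotoxin checklist (hydrophobic
  N-terminus, N-X-S/T sequons, KEX1/KEX2 `KR` sites), and premature-stop
  detection for defective satellite ORFs.
- **Identity analysis** — affine-gap Needleman–Wunsch global alignment
  (Rcpp) and p-distance percent identity with pairwise deletion:
  `pct = 100 · n_identical / n_compared` over gap-free columns; full
  pairwise matrices and range summaries.
- **ICTV classification** — a rule engine over shipped demarcation
  thresholds (narnavirus 50% / mitovirus 40% / totivirus 50% RdRp aa;
  partitivirus 80% CP / 90% RdRp aa species and < 24% RdRp aa genus
  cut-offs) producing variant / new-species / new-genus verdicts.
- **Synthetic virome generator** — seeded fixtures with host background and
  viral elements of every architecture above, plus a ground-truth manifest,
  so each stage is testable against planted truth.

## Worked example

```r
library(viromeScreen)

config <- defaultViromeConfig(seed = 42)   # 50 host + 5 virus + 3 ORFan contigs
vir    <- generateVirome(config)
reads  <- simulateReads(vir$contigs, vir$truth, config)

idx      <- buildKmerIndex(vir$contigs, k = 21)
counts   <- countStrands(idx, reads)
verdicts <- screenOrfans(vir$contigs, emitHitTable(vir$truth), counts)
#> ORFan screen: 58 contig(s), 3 candidate(s) without homology, 3 passed
as.data.frame(verdicts[verdicts$passed,
  c("contigId", "longestOrfLen", "antisenseRatio", "passed")])
#>   contigId longestOrfLen antisenseRatio passed
#> 1   orfan1           475      0.2356021   TRUE
#> 2   orfan2           475      0.2500000   TRUE
#> 3   orfan3           475      0.2679739   TRUE
```

The three passing contigs are exactly the planted ORFan elements: each
encodes a 475-aa protein, and roughly one antisense read arrives per four
sense reads — far above the 0.005 antisense noise of the host background.
The bicistronic totivirus-like element shows the expected slippage site:

```r
orfs <- findOrfs(vir$contigs[["toti1"]], "standard", minAa = 300)
detectSlippageOverlap(orfs[1, ], orfs[2, ], vir$contigs[["toti1"]])
#> $overlapStart 2876  $overlapEnd 2879  $overlapSeq "AUGA"  $frameshift -1
```

and the rule engine turns an identity measurement into a verdict:

```r
classifyCandidate("SbMV1", "mitovirus",
  data.frame(referenceId = "SsMV26", marker = "RdRp_aa",
             pctIdentity = 35.97))
#> Classification: SbMV1 -> new_species_candidate
#>   rules applied: mitovirus RdRp_aa 40 below_means_new_species
#>   best reference: SsMV26
```

35.97% sits below the 40% mitovirus species threshold, so the candidate is
proposed as a new species.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/virome-screen.R`:

```sh
Rscript inst/scripts/virome-screen.R simulate --seed 42 --out sim/
Rscript inst/scripts/virome-screen.R map --contigs sim/contigs.fasta \
    --reads sim/reads.fastq --out counts.tsv
Rscript inst/scripts/virome-screen.R orfan --contigs sim/contigs.fasta \
    --hits sim/hits.tsv --counts counts.tsv --out verdicts.tsv
```
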