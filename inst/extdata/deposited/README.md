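# Deposited GenBank records (user-supplied)

`verifyDepositedRecords()` and the corresponding acceptance test look here
for the deposited sequences, one single-record FASTA per accession,
named `<accession>.fasta` (e.g. `OK412911.fasta`). The records are not
shipped with the package; download them from NCBI, e.g.:

    efetch -db nuccore -id OK412911 -format fasta > OK412911.fasta

Nucleotide records: OK377006-OK377025, OK412898-OK412916, and the
references KC677754, JN819511, U01060, KX906605, AF039063.
Protein records (amino-acid FASTA): QFU28543, NP_660177, NP_660178,
AAA47824, BAU19319, ABB02500, ABB02501, AWY10984; plus
`OK412912_RdRp_aa.fasta`, the translated RdRp of OK412912.

Checks with missing files are reported as `missing_record`.
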