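# Degenerate consensus patterns for the six conserved motifs (I-VI) of
# mitochondrial-virus RdRps, one regular expression per motif over the
# amino-acid alphabet. Motif IV carries the hallmark GDD catalytic core.
# Edit or replace this file to re-derive patterns from another alignment.
motif_id	pattern
I	H[DNS].{2}[LIVMF].{2}G
II	G.{3}[ST][LIVMF].{2}[FY]
III	[LIVM].{2}D[FYW].{2}[DE]
IV	[SAG].{2}GDD[LIVMF]
V	[KR].{3}[GA].{2}[LIVM]
VI	[DE][FYW].{2}[KR].{2}[ST]
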