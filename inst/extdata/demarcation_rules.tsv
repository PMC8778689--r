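# ICTV demarcation thresholds used by the classification engine.
# relation: below_means_new_species | below_means_new_genus
# marker:   RdRp_aa | CP_aa | nt
taxon_scope	marker	threshold	relation	source_note
narnavirus	RdRp_aa	50	below_means_new_species	amino acid identity value of 50% as the accepted threshold for species demarcation within the narnavirus genus
mitovirus	RdRp_aa	40	below_means_new_species	RdRp amino acid identity values of 40% as thresholds to discriminate among mitovirus species
totivirus	RdRp_aa	50	below_means_new_species	Totiviridae species demarcation: host specificity and amino acid identity values below 50%
totivirus	CP_aa	50	below_means_new_species	Totiviridae species demarcation: host specificity and amino acid identity values below 50%
partitivirus	CP_aa	80	below_means_new_species	Partitiviridae species demarcation: CP amino acid identity 80%
partitivirus	RdRp_aa	90	below_means_new_species	Partitiviridae species demarcation: RdRp amino acid identity 90%
partitivirus	RdRp_aa	24	below_means_new_genus	Partitiviridae genus demarcation: pairwise RdRp aa identity <24% for viruses from different genera
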