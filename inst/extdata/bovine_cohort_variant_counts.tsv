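quantity	value
total_variants	27414076
n_snp	23655295
n_indel	3758781
y_n_snp	41500
y_length_bp	43300181
genome_length_bp	2759153975
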