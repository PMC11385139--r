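subset	n_variants	across_trait_per_variant_h2
chip	44126	3.409e-06
splice_sites	7308	2.766e-06
mqtl	5179	2.304e-06
utr	28039	1.206e-06
noncoding_related	3189	8.537e-07
young	88195	9.663e-08
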