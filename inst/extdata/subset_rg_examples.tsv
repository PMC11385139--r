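subset	trait_pair	rg
noncoding_related	MY_DD	0.6662
chip	MY_MET	-0.0111
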