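treatment,replicate,n_cultured,n_mii,n_cleaved,n_blastocyst
CONTROL,1,661,483,173,145
DKK1,1,543,446,166,142
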