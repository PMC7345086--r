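aa	classes	noncanonical
Met	I	-
Val	I	-
Ile	I	-
Leu	I	-
Cys	I	SepRS
Glu	I	-
Gln	I	-
Lys	I,II	-
Arg	I	-
Trp	I	-
Tyr	I	-
Ala	II	-
His	II	-
Pro	II	-
Thr	II	-
Ser	II	-
Gly	II	-
Phe	II	-
Asp	II	-
Asn	II	-
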