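locus_tag	amino_acid	anticodon	start	end	length_bp	gc_percent
ZZ1t001	Trp	CCA	73037	73108	72	55.6
ZZ1t002	Pro	TGG	73349	73425	77	50.6
ZZ1t003	Ser	TGA	73639	73733	95	61.1
ZZ1t004	Thr	TGT	73887	73962	76	53.9
ZZ1t005	Cys	GCA	75677	75753	77	57.1
ZZ1t006	Met	CAT	75945	76021	77	54.5
ZZ1t007	Arg	TCT	76027	76102	76	53.9
ZZ1t008	Sup	CTA	76196	76269	74	51.4
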