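let7_targets	let-7 target genes forming the meta-let-7-TG meta-gene	ARID3B	CCNJ	GOLT1B	HIC2	IGF2BP3	IL13	MAP4K4	NF2	PAPPA	SLC6A1	TGFBR1	ZC3H3
bach1_targets	experimentally derived BACH1 target genes forming the meta-BACH1 meta-gene	BMPER	DYM	FBXO42	FRMPD4	HERC3	HS3ST3B1	IL1RAP	IL7	MAGEC1	MYCT1	PDE1C	PRDM1	RCAN3
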