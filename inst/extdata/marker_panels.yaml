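# Editable marker panels for the two-way lineage splits.
# TE vs ICM uses weights +1 (TE) and -1 (ICM); EPI vs PE likewise.
TE: [GATA2, GATA3, DAB2, PTGES, EMP2, TGFBR3, PDGFA, CLDN4]
ICM: [SOX2, NANOG, PRDM14, TDGF1, PDGFRA, GATA4, HNF1B, GDF3]
EPI: [NANOG, PRDM14, SOX2, TDGF1, GDF3, DPPA5, ARGFX, NODAL]
PE: [GATA4, HNF1B, PDGFRA, COL4A1, FGFR2, LAMA4, LINC00261, FRZB]
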