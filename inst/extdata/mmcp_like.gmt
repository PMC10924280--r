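T cell CD4+	curated murine markers	Cd3e	Cd3d	Cd3g	Cd4	Lck	Thy1
T cell CD8+	curated murine markers	Cd8a	Cd8b1	Gzmk	Cd3e	Lag3
NK cell	curated murine markers	Ncr1	Klrb1c	Eomes	Prf1	Klra4
B cell	curated murine markers	Cd19	Ms4a1	Cd79a	Cd79b	Pax5
Memory B cell	curated murine markers	Cd80	Nt5e	Cd38	Cd19
Monocyte	curated murine markers	Ly6c2	Ccr2	Cd14	Vcan
Macrophage	curated murine markers	Adgre1	Mrc1	Cd68	Mertk	Csf1r
Dendritic cell	curated murine markers	Itgax	Flt3	Zbtb46	Clec9a	Siglech
Neutrophil	curated murine markers	Ly6g	S100a8	S100a9	Mpo	Retnlg
Eosinophil	curated murine markers	Siglecf	Prg2	Epx	Il5ra
Basophil	curated murine markers	Mcpt8	Cd200r3	Fcer1a
Mast cell	curated murine markers	Cma1	Mcpt4	Kit	Cpa3
Endothelial cell	curated murine markers	Pecam1	Cdh5	Vwf	Cldn5
Fibroblast	curated murine markers	Col1a1	Col1a2	Pdgfra	Dcn	Fbln1
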