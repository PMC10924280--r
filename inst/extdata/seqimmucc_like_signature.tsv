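gene	B cell	T cell CD4+	T cell CD8+	NK cell	Monocyte	Macrophage	Dendritic cell	Neutrophil	Eosinophil	Mast cell
Cd19	113970.588	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Ms4a1	126225.49	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd79a	138480.392	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd79b	150735.294	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Pax5	162990.196	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Ebf1	175245.098	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd4	2450.98	115107.914	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd3e	2450.98	127098.321	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd3d	2450.98	139088.729	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Il7r	2450.98	151079.137	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Tcf7	2450.98	163069.544	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Lef1	2450.98	175059.952	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd8a	2450.98	2398.082	116197.183	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Cd8b1	2450.98	2398.082	127934.272	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Gzmk	2450.98	2398.082	139671.362	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Klrg1	2450.98	2398.082	151408.451	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Eomes	2450.98	2398.082	163145.54	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Lag3	2450.98	2398.082	174882.629	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Ncr1	2450.98	2398.082	2347.418	117241.379	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Klrb1c	2450.98	2398.082	2347.418	128735.632	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Prf1	2450.98	2398.082	2347.418	140229.885	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Gzmb	2450.98	2398.082	2347.418	151724.138	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Klra4	2450.98	2398.082	2347.418	163218.391	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Il2rb	2450.98	2398.082	2347.418	174712.644	2252.252	2207.506	2164.502	2123.142	2083.333	2044.99
Ly6c2	2450.98	2398.082	2347.418	2298.851	118243.243	2207.506	2164.502	2123.142	2083.333	2044.99
Ccr2	2450.98	2398.082	2347.418	2298.851	129504.505	2207.506	2164.502	2123.142	2083.333	2044.99
Cd14	2450.98	2398.082	2347.418	2298.851	140765.766	2207.506	2164.502	2123.142	2083.333	2044.99
Vcan	2450.98	2398.082	2347.418	2298.851	152027.027	2207.506	2164.502	2123.142	2083.333	2044.99
Fcgr1	2450.98	2398.082	2347.418	2298.851	163288.288	2207.506	2164.502	2123.142	2083.333	2044.99
Itgam	2450.98	2398.082	2347.418	2298.851	174549.55	2207.506	2164.502	2123.142	2083.333	2044.99
Adgre1	2450.98	2398.082	2347.418	2298.851	2252.252	119205.298	2164.502	2123.142	2083.333	2044.99
Mrc1	2450.98	2398.082	2347.418	2298.851	2252.252	130242.826	2164.502	2123.142	2083.333	2044.99
Cd68	2450.98	2398.082	2347.418	2298.851	2252.252	141280.353	2164.502	2123.142	2083.333	2044.99
Mertk	2450.98	2398.082	2347.418	2298.851	2252.252	152317.881	2164.502	2123.142	2083.333	2044.99
Csf1r	2450.98	2398.082	2347.418	2298.851	2252.252	163355.408	2164.502	2123.142	2083.333	2044.99
Apoe	2450.98	2398.082	2347.418	2298.851	2252.252	174392.936	2164.502	2123.142	2083.333	2044.99
Itgax	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	120129.87	2123.142	2083.333	2044.99
Flt3	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	130952.381	2123.142	2083.333	2044.99
Zbtb46	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	141774.892	2123.142	2083.333	2044.99
Clec9a	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	152597.403	2123.142	2083.333	2044.99
Siglech	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	163419.913	2123.142	2083.333	2044.99
Batf3	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	174242.424	2123.142	2083.333	2044.99
Ly6g	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	121019.108	2083.333	2044.99
S100a8	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	131634.82	2083.333	2044.99
S100a9	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	142250.531	2083.333	2044.99
Mpo	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	152866.242	2083.333	2044.99
Retnlg	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	163481.953	2083.333	2044.99
Cxcr2	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	174097.665	2083.333	2044.99
Prg2	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	121875	2044.99
Epx	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	132291.667	2044.99
Il5ra	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	142708.333	2044.99
Ccr3	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	153125	2044.99
Ear2	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	163541.667	2044.99
Siglecf	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	173958.333	2044.99
Cma1	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	122699.387
Mcpt4	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	132924.335
Kit	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	143149.284
Cpa3	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	153374.233
Fcer1a	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	163599.182
Ms4a2	2450.98	2398.082	2347.418	2298.851	2252.252	2207.506	2164.502	2123.142	2083.333	173824.131
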