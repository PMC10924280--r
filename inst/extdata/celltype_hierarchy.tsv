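fine	major
T cell CD4+ naive	T cell CD4+
T cell CD4+ central memory	T cell CD4+
T cell CD4+ effector memory	T cell CD4+
T cell CD4+ effector	T cell CD4+
T cell CD4+ exhausted	T cell CD4+
T cell CD4+ activated	T cell CD4+
T cell CD4+ resting	T cell CD4+
T cell CD4+ proliferating	T cell CD4+
T cell CD4+ tissue-resident	T cell CD4+
T cell CD4+ IFN-stimulated	T cell CD4+
T cell CD8+ naive	T cell CD8+
T cell CD8+ central memory	T cell CD8+
T cell CD8+ effector memory	T cell CD8+
T cell CD8+ effector	T cell CD8+
T cell CD8+ exhausted	T cell CD8+
T cell CD8+ activated	T cell CD8+
T cell CD8+ resting	T cell CD8+
T cell CD8+ proliferating	T cell CD8+
T cell CD8+ tissue-resident	T cell CD8+
T cell CD8+ IFN-stimulated	T cell CD8+
T cell gamma delta naive	T cell gamma delta
T cell gamma delta central memory	T cell gamma delta
T cell gamma delta effector memory	T cell gamma delta
T cell gamma delta effector	T cell gamma delta
T cell gamma delta exhausted	T cell gamma delta
T cell gamma delta activated	T cell gamma delta
T cell gamma delta resting	T cell gamma delta
T cell gamma delta proliferating	T cell gamma delta
T cell gamma delta tissue-resident	T cell gamma delta
T cell gamma delta IFN-stimulated	T cell gamma delta
T cell regulatory naive	T cell regulatory
T cell regulatory central memory	T cell regulatory
T cell regulatory effector memory	T cell regulatory
T cell regulatory effector	T cell regulatory
T cell regulatory exhausted	T cell regulatory
T cell regulatory activated	T cell regulatory
T cell regulatory resting	T cell regulatory
T cell regulatory proliferating	T cell regulatory
T cell regulatory tissue-resident	T cell regulatory
T cell regulatory IFN-stimulated	T cell regulatory
B cell naive	B cell
B cell central memory	B cell
B cell effector memory	B cell
B cell effector	B cell
B cell exhausted	B cell
B cell activated	B cell
B cell resting	B cell
B cell proliferating	B cell
B cell tissue-resident	B cell
B cell IFN-stimulated	B cell
Plasma cell naive	Plasma cell
Plasma cell central memory	Plasma cell
Plasma cell effector memory	Plasma cell
Plasma cell effector	Plasma cell
Plasma cell exhausted	Plasma cell
Plasma cell activated	Plasma cell
Plasma cell resting	Plasma cell
Plasma cell proliferating	Plasma cell
Plasma cell tissue-resident	Plasma cell
Plasma cell IFN-stimulated	Plasma cell
NK cell naive	NK cell
NK cell central memory	NK cell
NK cell effector memory	NK cell
NK cell effector	NK cell
NK cell exhausted	NK cell
NK cell activated	NK cell
NK cell resting	NK cell
NK cell proliferating	NK cell
NK cell tissue-resident	NK cell
NK cell IFN-stimulated	NK cell
Innate lymphoid cell naive	Innate lymphoid cell
Innate lymphoid cell central memory	Innate lymphoid cell
Innate lymphoid cell effector memory	Innate lymphoid cell
Innate lymphoid cell effector	Innate lymphoid cell
Innate lymphoid cell exhausted	Innate lymphoid cell
Innate lymphoid cell activated	Innate lymphoid cell
Innate lymphoid cell resting	Innate lymphoid cell
Innate lymphoid cell proliferating	Innate lymphoid cell
Innate lymphoid cell tissue-resident	Innate lymphoid cell
Innate lymphoid cell IFN-stimulated	Innate lymphoid cell
Monocyte naive	Monocyte
Monocyte central memory	Monocyte
Monocyte effector memory	Monocyte
Monocyte effector	Monocyte
Monocyte exhausted	Monocyte
Monocyte activated	Monocyte
Monocyte resting	Monocyte
Monocyte proliferating	Monocyte
Monocyte tissue-resident	Monocyte
Monocyte IFN-stimulated	Monocyte
Macrophage naive	Macrophage
Macrophage central memory	Macrophage
Macrophage effector memory	Macrophage
Macrophage effector	Macrophage
Macrophage exhausted	Macrophage
Macrophage activated	Macrophage
Macrophage resting	Macrophage
Macrophage proliferating	Macrophage
Macrophage tissue-resident	Macrophage
Macrophage IFN-stimulated	Macrophage
Dendritic cell naive	Dendritic cell
Dendritic cell central memory	Dendritic cell
Dendritic cell effector memory	Dendritic cell
Dendritic cell effector	Dendritic cell
Dendritic cell exhausted	Dendritic cell
Dendritic cell activated	Dendritic cell
Dendritic cell resting	Dendritic cell
Dendritic cell proliferating	Dendritic cell
Dendritic cell tissue-resident	Dendritic cell
Dendritic cell IFN-stimulated	Dendritic cell
Neutrophil naive	Neutrophil
Neutrophil central memory	Neutrophil
Neutrophil effector memory	Neutrophil
Neutrophil effector	Neutrophil
Neutrophil exhausted	Neutrophil
Neutrophil activated	Neutrophil
Neutrophil resting	Neutrophil
Neutrophil proliferating	Neutrophil
Neutrophil tissue-resident	Neutrophil
Neutrophil IFN-stimulated	Neutrophil
Eosinophil naive	Eosinophil
Eosinophil central memory	Eosinophil
Eosinophil effector memory	Eosinophil
Eosinophil effector	Eosinophil
Eosinophil exhausted	Eosinophil
Eosinophil activated	Eosinophil
Eosinophil resting	Eosinophil
Eosinophil proliferating	Eosinophil
Eosinophil tissue-resident	Eosinophil
Eosinophil IFN-stimulated	Eosinophil
Basophil naive	Basophil
Basophil central memory	Basophil
Basophil effector memory	Basophil
Basophil effector	Basophil
Basophil exhausted	Basophil
Basophil activated	Basophil
Basophil resting	Basophil
Basophil proliferating	Basophil
Basophil tissue-resident	Basophil
Basophil IFN-stimulated	Basophil
Mast cell naive	Mast cell
Mast cell central memory	Mast cell
Mast cell effector memory	Mast cell
Mast cell effector	Mast cell
Mast cell exhausted	Mast cell
Mast cell activated	Mast cell
Mast cell resting	Mast cell
Mast cell proliferating	Mast cell
Mast cell tissue-resident	Mast cell
Mast cell IFN-stimulated	Mast cell
Fibroblast naive	Fibroblast
Fibroblast central memory	Fibroblast
Fibroblast effector memory	Fibroblast
Fibroblast effector	Fibroblast
Fibroblast exhausted	Fibroblast
Fibroblast activated	Fibroblast
Fibroblast resting	Fibroblast
Fibroblast proliferating	Fibroblast
Fibroblast tissue-resident	Fibroblast
Fibroblast IFN-stimulated	Fibroblast
Endothelial cell naive	Endothelial cell
Endothelial cell central memory	Endothelial cell
Endothelial cell effector memory	Endothelial cell
Endothelial cell effector	Endothelial cell
Endothelial cell exhausted	Endothelial cell
Endothelial cell activated	Endothelial cell
Endothelial cell resting	Endothelial cell
Endothelial cell proliferating	Endothelial cell
Endothelial cell tissue-resident	Endothelial cell
Endothelial cell IFN-stimulated	Endothelial cell
Hematopoietic progenitor naive	Hematopoietic progenitor
Hematopoietic progenitor central memory	Hematopoietic progenitor
Hematopoietic progenitor effector memory	Hematopoietic progenitor
Hematopoietic progenitor effector	Hematopoietic progenitor
Hematopoietic progenitor exhausted	Hematopoietic progenitor
Hematopoietic progenitor activated	Hematopoietic progenitor
Hematopoietic progenitor resting	Hematopoietic progenitor
Hematopoietic progenitor proliferating	Hematopoietic progenitor
Hematopoietic progenitor tissue-resident	Hematopoietic progenitor
Hematopoietic progenitor IFN-stimulated	Hematopoietic progenitor
Erythroid cell naive	Erythroid cell
Erythroid cell central memory	Erythroid cell
Erythroid cell effector memory	Erythroid cell
Erythroid cell effector	Erythroid cell
Erythroid cell exhausted	Erythroid cell
Erythroid cell activated	Erythroid cell
Erythroid cell resting	Erythroid cell
Erythroid cell proliferating	Erythroid cell
Erythroid cell tissue-resident	Erythroid cell
Erythroid cell IFN-stimulated	Erythroid cell
T cell CD4+	T cell CD4+
T cell CD8+	T cell CD8+
T cell gamma delta	T cell gamma delta
T cell regulatory	T cell regulatory
B cell	B cell
Plasma cell	Plasma cell
NK cell	NK cell
Innate lymphoid cell	Innate lymphoid cell
Monocyte	Monocyte
Macrophage	Macrophage
Dendritic cell	Dendritic cell
Neutrophil	Neutrophil
Eosinophil	Eosinophil
Basophil	Basophil
Mast cell	Mast cell
Fibroblast	Fibroblast
Endothelial cell	Endothelial cell
Hematopoietic progenitor	Hematopoietic progenitor
Erythroid cell	Erythroid cell
Memory B cell	B cell
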