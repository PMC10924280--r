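method	raw	canonical
base_like	CD8 T	T cell CD8+
base_like	CD4 T	T cell CD4+
base_like	NK	NK cell
base_like	B	B cell
base_like	DC	Dendritic cell
base_like	Mono	Monocyte
base_like	Treg	T cell regulatory
mmcp_like	T cell CD8+	T cell CD8+
mmcp_like	T cell CD4+	T cell CD4+
mmcp_like	NK cell	NK cell
mmcp_like	B cell	B cell
cls_human_sig	CD8A+ T cell	T cell CD8+
cls_human_sig	CD4+ T cell	T cell CD4+
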