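gene_id	gene_name	description	gene_log2fc	metabolite_id	metabolite_log2fc	pcc
Gh_D05G1280	PERK13	Proline-rich receptor-like protein kinase	3.61	pme1175	6.54	1
Gh_D05G1280	PERK13	Proline-rich receptor-like protein kinase	3.61	pme1296	7.10	1
Gh_D10G1867	IRK	LRR receptor-like protein kinase	3.52	pmb0981	15.26	1
Gh_D10G1867	IRK	LRR receptor-like protein kinase	3.52	pmb2948	11.31	1
Gh_D10G1867	IRK	LRR receptor-like protein kinase	3.52	pmc0066	13.65	1
Gh_A03G1831	CAO	Signal recognition protein	1.99	pme1175	6.54	1
Gh_A03G1831	CAO	Signal recognition protein	1.99	pme1296	7.10	1
Gh_A07G2239	ABI3	B3 transcription factor	5.70	pmb0981	15.26	1
Gh_A07G2239	ABI3	B3 transcription factor	5.70	pmb2948	11.31	1
Gh_A07G2239	ABI3	B3 transcription factor	5.70	pmc0066	13.65	1
Gh_A08G2488	WRKY2	WRKY transcription factor 2	1.77	pmb0981	15.26	1
Gh_A08G2488	WRKY2	WRKY transcription factor 2	1.77	pmb2948	11.31	1
Gh_A08G2488	WRKY2	WRKY transcription factor 2	1.77	pmc0066	13.65	1
Gh_A11G2618	NFYC2	Nuclear transcription factor	3.07	pmb0981	15.26	1
Gh_A11G2618	NFYC2	Nuclear transcription factor	3.07	pmb2948	11.31	1
Gh_A11G2618	NFYC2	Nuclear transcription factor	3.07	pmc0066	13.65	1
Gh_D04G0086	NFYA3	Nuclear transcription factor	2.29	pmb0981	15.26	1
Gh_D04G0086	NFYA3	Nuclear transcription factor	2.29	pmb2948	11.31	1
Gh_D04G0086	NFYA3	Nuclear transcription factor	2.29	pmc0066	13.65	1
Gh_A06G1368	SERP2	Stress-associated protein	4.36	pme1175	6.54	1
Gh_A06G1368	SERP2	Stress-associated protein	4.36	pme1296	7.10	1
Gh_D04G1347	ARR4	Two-component response regulator	2.55	pme1175	6.54	1
Gh_D04G1347	ARR4	Two-component response regulator	2.55	pme1296	7.10	1
Gh_D12G2180	AIR1	Putative lipid-binding protein	3.55	pme1175	6.54	1
Gh_D12G2180	AIR1	Putative lipid-binding protein	3.55	pme1296	7.10	1
Gh_D12G1336	HMGB7	High mobility group B protein	3.75	pmb0981	15.26	1
Gh_D12G1336	HMGB7	High mobility group B protein	3.75	pmb2948	11.31	1
Gh_D12G1336	HMGB7	High mobility group B protein	3.75	pmc0066	13.65	1
Gh_D11G0232	HMGB13	High mobility group B protein	5.55	pme1175	6.54	1
Gh_D11G0232	HMGB13	High mobility group B protein	5.55	pme1296	7.10	1
Gh_A06G0239	IAA9	Auxin-responsive protein	3.87	pmb2948	11.31	1
Gh_D09G0145	GASA4	Gibberellin-regulated protein	6.53	pmb0981	15.26	1
Gh_D09G0145	GASA4	Gibberellin-regulated protein	6.53	pmb2948	11.31	1
Gh_D09G0145	GASA4	Gibberellin-regulated protein	6.53	pmc0066	13.65	1
Gh_A10G0472	B34	Histone H3.2	3.80	pmb0981	15.26	1
Gh_A10G0472	B34	Histone H3.2	3.80	pmb2948	11.31	1
Gh_A13G1866	B34	Histone H3.2	3.46	pmb2948	11.31	1
Gh_D08G1979	HIS2A	Histone H2AX	4.15	pmb0981	15.26	1
Gh_D08G0034	HIS2A	Histone H2A	3.15	pmb2948	11.31	1
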