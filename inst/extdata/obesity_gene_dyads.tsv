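# Reference dyad counts for a statistical epistasis network over twelve
# obesity candidate genes: N = 2139 gene-membership slots, M = 1241 edges.
# n1 = slots per gene; m11/m10 = observed same-gene and mixed dyads.
# *_ref columns are the reference values as reported (3 d.p.; expectations
# are recomputable from N, M and n1 alone).
gene	n1	m11	m10	m11_expected_ref	m10_expected_ref	dyadicity_ref	heterophilicity_ref	p_dyadicity_ref	p_heterophilicity_ref
FTO	324	21	301	28.399	319.157	0.739	0.943	0.85	0.727
MC4R	187	16	219	9.439	198.109	1.695	1.105	0.074	0.248
KCTD15	178	5	243	8.550	189.444	0.585	1.283	0.855	0.045
TMEM18	222	23	334	13.314	230.971	1.728	1.446	0.047	0.001
NEGR1	295	12	249	23.535	295.234	0.510	0.843	0.978	0.94
SH2B1	32	1	87	0.269	36.593	3.715	2.378	0.232	0.003
FAIM2	106	1	103	3.020	116.957	0.331	0.881	0.91	0.699
SEC16B	165	2	197	7.343	176.772	0.272	1.114	0.979	0.218
ETV5	168	3	173	7.613	179.713	0.394	0.963	0.952	0.596
BDNF	167	1	167	7.523	178.734	0.133	0.934	0.997	0.643
MTCH2	109	1	110	3.195	120.090	0.313	0.916	0.908	0.664
GNPDA2	186	1	125	9.338	197.151	0.107	0.634	1	0.997
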