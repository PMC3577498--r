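gene	score_hi	score_lo	mode
G0047	95.8930070102189	0	literature
G0049	95.5760569804817	0	literature
G0040	93.0675461849433	0	literature
G0042	93.0675461849433	0	literature
G0044	91.0427819946168	0	literature
G0041	89.9298728465424	0	literature
G0048	88.8471681415929	0	literature
G0043	88.4966157846011	0	literature
G0012	50	20.5102957226085	literature
G0046	50	20.5102957226085	literature
G0024	45.1852033080945	0	literature
G0093	45.1852033080945	0	literature
G0017	44.3440375774711	0	literature
G0045	44.3440375774711	0	literature
G0091	39.6203487509596	0	literature
G0116	37.0169252616138	0	literature
G0005	33.3084432505572	0	literature
G0006	32.9821959764998	0	literature
G0001	32.1206152702317	0	literature
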