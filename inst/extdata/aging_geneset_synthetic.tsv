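gene	direction
G0001	up
G0002	up
G0003	up
G0004	up
G0005	up
G0006	up
G0007	up
G0008	up
G0009	up
G0010	up
G0011	up
G0012	up
G0013	up
G0014	up
G0015	up
G0016	up
G0017	up
G0018	up
G0019	up
G0020	up
G0021	up
G0022	up
G0023	up
G0024	up
G0025	up
G0026	up
G0027	up
G0028	up
G0029	up
G0030	up
G0031	up
G0032	up
G0033	up
G0034	up
G0035	up
G0036	up
G0037	up
G0038	up
G0039	up
G0040	up
G0041	up
G0042	up
G0043	up
G0044	up
G0045	up
G0046	up
G0047	up
G0048	up
G0049	up
G0050	up
G0051	up
G0052	up
G0053	up
G0054	up
G0055	up
G0056	up
G0057	up
G0058	up
G0059	up
G0060	up
G0061	up
G0062	up
G0063	up
G0064	up
G0065	up
G0066	up
G0067	up
G0068	up
G0069	up
G0070	up
G0071	up
G0072	up
G0073	up
G0074	up
G0075	up
G0076	up
G0077	up
G0078	up
G0079	up
G0080	up
G0081	up
G0082	up
G0083	up
G0084	up
G0085	up
G0086	up
G0087	up
G0088	down
G0089	down
G0090	down
G0091	down
G0092	down
G0093	down
G0094	down
G0095	down
G0096	down
G0097	down
G0098	down
G0099	down
G0100	down
G0101	down
G0102	down
G0103	down
G0104	down
G0105	down
G0106	down
G0107	down
G0108	down
G0109	down
G0110	down
G0111	down
G0112	down
G0113	down
G0114	down
G0115	down
G0116	down
G0117	down
G0118	down
G0119	down
G0120	down
G0121	down
G0122	down
G0123	down
G0124	down
G0125	down
G0126	down
G0127	down
G0128	down
G0129	down
G0130	down
G0131	down
G0132	down
G0133	down
G0134	down
G0135	down
G0136	down
G0137	down
G0138	down
G0139	down
G0140	down
G0141	down
G0142	down
G0143	down
G0144	down
G0145	down
G0146	down
G0147	down
G0148	down
G0149	down
G0150	down
G0151	down
G0152	down
G0153	down
G0154	down
G0155	down
G0156	down
G0157	down
G0158	down
G0159	down
G0160	down
G0161	down
G0162	down
G0163	down
G0164	down
G0165	down
G0166	down
G0167	down
G0168	down
G0169	down
G0170	down
G0171	down
G0172	down
G0173	down
G0174	down
G0175	down
G0176	down
G0177	down
G0178	down
G0179	down
G0180	down
G0181	down
G0182	down
G0183	down
G0184	down
G0185	down
G0186	down
G0187	down
G0188	down
G0189	down
G0190	down
G0191	down
G0192	down
G0193	down
G0194	down
G0195	down
G0196	down
G0197	down
G0198	down
G0199	down
G0200	down
G0201	down
G0202	down
G0203	down
G0204	down
G0205	down
G0206	down
G0207	down
G0208	down
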