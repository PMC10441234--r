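KEGG_SIM_HIPPO	Hippo-signaling-like toy pathway	SIMG00101	SIMG00102	SIMG00103	SIMG00104	SIMG00105	SIMG00106	SIMG00107	SIMG00108	SIMG00109	SIMG00110	SIMG00111	SIMG00112	SIMG00113	SIMG00114	SIMG00115	SIMG00116	SIMG00117	SIMG00118	SIMG00119	SIMG00120	SIMG00121	SIMG00122	SIMG00123	SIMG00124	SIMG00125	SIMG00126	SIMG00127	SIMG00128	SIMG00129	SIMG00130	SIMG00131	SIMG00132	SIMG00133	SIMG00134	SIMG00135	SIMG00136	SIMG00137	SIMG00138	SIMG00139	SIMG00140
KEGG_SIM_PROLIFERATION	proliferation-like toy pathway	SIMG00201	SIMG00202	SIMG00203	SIMG00204	SIMG00205	SIMG00206	SIMG00207	SIMG00208	SIMG00209	SIMG00210	SIMG00211	SIMG00212	SIMG00213	SIMG00214	SIMG00215	SIMG00216	SIMG00217	SIMG00218	SIMG00219	SIMG00220	SIMG00221	SIMG00222	SIMG00223	SIMG00224	SIMG00225	USP44	TIAL1	MUC12
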