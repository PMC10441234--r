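GO_SIM_KERATINIZATION	keratinization-like toy set	SIMG00001	SIMG00002	SIMG00003	SIMG00004	SIMG00005	SIMG00006	SIMG00007	SIMG00008	SIMG00009	SIMG00010	SIMG00011	SIMG00012	SIMG00013	SIMG00014	SIMG00015	SIMG00016	SIMG00017	SIMG00018	SIMG00019	SIMG00020	SIMG00021	SIMG00022	SIMG00023	SIMG00024	SIMG00025	SIMG00026	SIMG00027	SIMG00028	SIMG00029	SIMG00030
GO_SIM_IMMUNE_RESPONSE	immune-response-like toy set	SIMG00301	SIMG00302	SIMG00303	SIMG00304	SIMG00305	SIMG00306	SIMG00307	SIMG00308	SIMG00309	SIMG00310	SIMG00311	SIMG00312	SIMG00313	SIMG00314	SIMG00315	SIMG00316	SIMG00317	SIMG00318	SIMG00319	SIMG00320	CD27	CSMD1
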