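SYNTHETIC_SHIFTED_SET	genes with a simulated disease shift	SYNGENE01	SYNGENE02	SYNGENE03	SYNGENE04	SYNGENE05	SYNGENE06	SYNGENE07	SYNGENE08	SYNGENE09	SYNGENE10
SYNTHETIC_NULL_SET	genes with no shift	SYNGENE11	SYNGENE12	SYNGENE13	SYNGENE14	SYNGENE15	SYNGENE16	SYNGENE17	SYNGENE18	SYNGENE19	SYNGENE20	SYNGENE21	SYNGENE22	SYNGENE23	SYNGENE24	SYNGENE25
SYNTHETIC_PARTIAL_SET	two matched genes plus two absent ones	SYNGENE26	SYNGENE27	ABSENTGENE1	ABSENTGENE2
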