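gene_id	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12	S13	S14	S15	S16
SYNGENE01	8.317	7.571	8.288	10.266	7.452	7.267	6.914	7.992	9.637	9.959	10.97	8.46	10.469	9.989	9.398	9.977
SYNGENE02	9.027	10.036	7.126	8.303	6.66	9.863	8.376	9.327	10.041	10.05	8.869	8.864	9.242	9.274	10.66	8.984
SYNGENE03	7.41	7.682	7.978	9.028	8.405	7.176	8.147	7.831	10.528	9.051	7.125	9.774	8.759	8.346	8.373	7.986
SYNGENE04	9.155	9.637	9.3	6.712	8.399	9.318	7.886	6.898	8.201	7.103	8.567	9.482	9.521	9.536	8.979	8.278
SYNGENE05	7.365	7.971	8.942	6.867	6.142	9.058	7.336	9.558	8.215	9.905	11.091	9.664	10.455	9.426	9.14	7.669
SYNGENE06	8.167	9.084	7.509	8.418	8.223	8.198	7.059	7.325	10.876	7.369	10.635	8.084	9.7	9.704	9.019	7.083
SYNGENE07	6.473	10.908	9.254	7.365	10.186	9.863	7.332	8.703	9.343	8.993	8.153	6.707	9.859	9.644	8.089	7.913
SYNGENE08	5.618	8.307	8.035	7.956	7.728	7.484	7.793	6.622	8.24	9.25	10.28	7.703	8.079	8.768	8.191	9.414
SYNGENE09	8.103	8.104	7.152	7.178	7.292	8.506	8.997	7.873	9.984	10.153	9.843	8.983	8.777	8.785	9.042	9.611
SYNGENE10	8.917	9.622	6.43	7.796	9.245	7.965	8.35	6.242	8.378	7.883	8.07	8.291	10.717	8.592	8.573	9.467
SYNGENE11	7.785	8.419	9.048	8.74	8.823	5.783	7.26	6.991	9.375	7.856	5.937	7.782	8.067	9.179	8.87	6.911
SYNGENE12	6.91	8.5	8.943	9.514	8.602	8.25	8.099	8.325	7.729	6.924	7.012	9.911	9.364	8.168	7.943	8.976
SYNGENE13	9.45	7.202	7.345	7.79	7.649	7.307	5.495	8.012	8.788	9.697	8.587	7.364	7.059	7.82	6.754	8.754
SYNGENE14	7.431	8.284	7.714	9.589	8.634	7.246	9.074	7.977	7.489	8.055	7.004	8.066	7.056	7.215	7.548	7.461
SYNGENE15	7.409	6.655	8.529	9.311	7.438	9.127	9.203	8.762	9.089	7.058	6.885	7.1	8.949	8.248	8.057	7.565
SYNGENE16	8.368	9.438	7.023	9.283	9.716	6.928	7.478	7.48	5.636	8.02	8.274	6.739	6.521	8.202	6.217	6.591
SYNGENE17	8.146	9.388	8.138	7.511	8.162	7.781	9.581	8.722	7.482	6.832	8.336	7.798	8.867	10.004	8.075	10.388
SYNGENE18	7.031	7.583	5.902	9.101	8.05	5.516	10.802	9.752	7.083	9.211	7.617	9.147	8.254	7.944	7.245	7.926
SYNGENE19	5.098	7.192	9.41	8.988	7.812	9.211	8.559	9.255	7.292	6.843	8.036	7.954	7.793	8.892	8.768	7.486
SYNGENE20	7.422	8.346	8.259	8.162	7.647	8.229	8.165	7.647	7.838	8.081	8.162	7.031	6.887	9.073	7.146	6.777
SYNGENE21	11.02	7.772	9.003	7.735	8.826	8.558	7.119	6.66	7.288	6.411	8.163	7.281	7.265	7.778	7.176	7.627
SYNGENE22	7.482	8.14	6.539	6.588	7.139	7.123	7.484	7.811	7.956	8.799	8.982	8.719	6.167	8.252	9.083	8.324
SYNGENE23	9.108	9.241	8.255	6.777	9.005	9.36	9.444	5.82	8.555	9.324	7.963	6.908	8.1	7.747	8.995	8.856
SYNGENE24	8.804	7.388	7.286	7.638	9.37	7.619	5.346	7.538	7.265	7.704	9.018	6.957	8.751	7.368	7.366	6.883
SYNGENE25	8.772	10.178	7.677	8.859	7.164	9.045	8.711	8.111	6.515	8.992	9.287	9.021	8.688	8.262	7.852	8.335
SYNGENE26	8.223	7.278	6.943	8.339	9.708	7.55	7.08	8.755	7.394	7.042	7.871	7.238	7.45	7.884	8.831	6.707
SYNGENE27	8.489	9.4	8.442	8.614	9.456	8.925	8.078	9.581	9.191	7.965	7.541	8.116	8.696	8.605	8.705	7.992
SYNGENE28	7.914	8.93	8.151	6.965	8.875	6.609	7.987	7.808	9.029	9.329	7.886	7.795	9.113	7.686	6.852	7.238
SYNGENE29	7.995	7.574	7.429	7.788	9.355	10.658	7.551	7.811	7.235	7.384	7.444	8.057	8.43	7.41	5.934	6.613
SYNGENE30	7.797	7.063	6.519	7.272	7.411	8.351	8.304	10.887	8.234	6.735	8.408	7.608	9.161	7.762	8.12	7.29
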