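mirna	hr_LA	p_LA	hr_LB	p_LB	hr_HER2E	p_HER2E	hr_BL	p_BL	psi
hsa-miR-365a-3p	3.308	0.001	2.467	0.044	3.503	0.007	4.851	0.000	14.076
hsa-miR-452-5p	2.311	0.019	3.039	0.012	4.922	0.000	2.367	0.065	12.542
hsa-miR-378a-3p	2.318	0.019	2.910	0.017	3.003	0.020	4.037	0.002	12.210
hsa-miR-215-5p	2.127	0.039	2.636	0.037	2.158	0.101	4.655	0.001	11.399
hsa-miR-103a-3p	3.664	0.000	2.182	0.086	3.713	0.004	1.572	0.376	10.664
hsa-miR-224-5p	3.193	0.001	3.435	0.005	2.372	0.061	1.095	0.996	9.031
hsa-miR-335-3p	2.203	0.035	2.119	0.100	4.142	0.002	2.317	0.068	10.576
hsa-miR-326	2.661	0.010	2.081	0.110	2.455	0.057	3.061	0.014	10.066
hsa-miR-10a-5p	1.344	0.471	1.934	0.157	2.217	0.110	4.203	0.001	8.958
hsa-miR-217	1.848	0.092	4.166	0.001	1.985	0.162	1.346	0.610	8.479
hsa-miR-10b-3p	2.091	0.054	2.098	0.112	1.521	0.443	3.878	0.003	8.976
hsa-miR-378a-5p	2.791	0.004	1.560	0.395	2.076	0.135	2.996	0.017	8.874
hsa-miR-193a-5p	2.372	0.016	1.803	0.215	3.078	0.016	1.922	0.172	8.757
hsa-miR-664a-3p	1.967	0.066	1.411	0.527	1.470	0.494	3.456	0.006	7.210
hsa-miR-30c-2-3p	2.731	0.006	1.847	0.208	2.197	0.118	2.093	0.117	8.419
hsa-miR-511-5p	2.245	0.030	2.316	0.064	1.956	0.176	2.366	0.064	8.549
hsa-miR-143-3p	2.400	0.014	1.841	0.206	1.157	0.901	2.567	0.042	6.802
hsa-miR-10b-5p	1.524	0.272	2.304	0.069	2.374	0.079	2.445	0.056	8.171
hsa-miR-22-3p	2.148	0.038	2.715	0.025	1.099	0.992	1.786	0.237	6.456
hsa-miR-140-3p	1.769	0.141	2.083	0.118	2.270	0.090	2.481	0.051	8.203
hsa-miR-338-3p	2.806	0.005	1.644	0.313	1.885	0.181	1.164	0.879	6.121
hsa-miR-451a	2.035	0.050	1.610	0.330	1.639	0.340	2.812	0.022	7.354
hsa-miR-486-5p	2.263	0.027	1.380	0.554	1.565	0.401	2.603	0.035	6.793
hsa-miR-28-3p	1.966	0.063	2.363	0.063	2.169	0.101	1.499	0.451	7.318
hsa-miR-139-5p	1.709	0.167	1.685	0.293	1.791	0.253	2.641	0.033	7.080
hsa-miR-125b-2-3p	1.869	0.089	1.821	0.223	0.986	0.850	2.683	0.034	6.162
hsa-miR-100-5p	1.868	0.089	1.811	0.235	1.771	0.280	2.311	0.086	7.071
hsa-miR-195-5p	1.547	0.253	1.351	0.608	1.430	0.550	2.642	0.036	5.524
hsa-miR-584-5p	1.623	0.200	1.812	0.218	2.546	0.053	1.442	0.512	6.442
hsa-let-7c-5p	1.835	0.099	1.821	0.223	1.118	0.972	2.224	0.094	5.610
hsa-miR-574-3p	2.434	0.022	1.330	0.624	1.489	0.467	1.304	0.665	4.780
hsa-miR-144-5p	2.184	0.032	1.239	0.747	1.387	0.574	1.822	0.214	5.065
hsa-miR-145-5p	1.696	0.158	1.446	0.497	1.296	0.701	2.191	0.098	5.175
hsa-let-7e-3p	2.092	0.054	1.159	0.875	1.460	0.502	1.491	0.449	4.322
hsa-miR-24-1-5p	1.443	0.348	2.057	0.123	1.045	0.915	1.900	0.191	4.868
hsa-miR-30a-3p	1.364	0.466	1.258	0.720	1.815	0.256	1.902	0.180	4.717
hsa-miR-362-5p	1.584	0.222	2.059	0.117	1.646	0.333	1.316	0.657	5.277
hsa-miR-339-5p	1.333	0.509	1.303	0.653	1.716	0.285	1.089	0.985	3.010
hsa-miR-361-3p	1.992	0.071	1.485	0.445	1.381	0.584	0.933	0.967	3.723
hsa-miR-30e-3p	1.518	0.280	1.748	0.253	1.327	0.656	1.076	0.977	3.504
hsa-miR-145-3p	1.684	0.164	1.435	0.506	1.264	0.743	1.760	0.257	4.473
hsa-miR-29a-3p	1.526	0.271	1.718	0.261	1.401	0.561	1.080	0.980	3.651
hsa-miR-34a-5p	1.653	0.178	1.830	0.197	1.603	0.360	1.403	0.539	5.216
hsa-miR-193b-5p	1.373	0.454	1.034	0.900	1.785	0.242	1.022	0.876	2.742
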