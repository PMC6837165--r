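mirna	subtype	hr	p	psi
hsa-miR-30b-3p	LA	1.461	0.354	1.107
hsa-miR-1247-5p	LA	1.458	0.352	1.105
hsa-miR-221-3p	LA	1.373	0.437	0.936
hsa-miR-222-3p	LA	1.363	0.478	0.885
hsa-miR-1180-3p	LA	1.362	0.477	0.885
hsa-miR-186-5p	LA	1.332	0.505	0.827
hsa-miR-107	LA	1.331	0.509	0.823
hsa-miR-505-3p	LA	1.317	0.530	0.787
hsa-miR-455-5p	LA	1.308	0.534	0.774
hsa-miR-532-5p	LA	1.221	0.689	0.532
hsa-miR-502-3p	LA	1.217	0.689	0.528
hsa-miR-24-3p	LA	1.208	0.689	0.519
hsa-miR-485-3p	LB	2.073	0.116	1.956
hsa-miR-582-3p	LB	1.892	0.179	1.713
hsa-miR-491-5p	LB	1.603	0.348	1.255
hsa-miR-22-5p	LB	1.588	0.352	1.236
hsa-miR-1249-3p	LB	1.531	0.401	1.131
hsa-miR-146b-3p	LB	1.288	0.681	0.608
hsa-miR-374b-5p	LB	1.260	0.713	0.546
hsa-miR-151a-3p	LB	1.209	0.795	0.414
hsa-miR-152-3p	LB	1.004	0.844	0.159
hsa-miR-27b-5p	LB	1.020	0.877	0.143
hsa-miR-181a-3p	LB	1.019	0.876	0.143
hsa-miR-185-5p	LB	1.027	0.889	0.138
hsa-miR-1307-3p	LB	1.054	0.940	0.114
hsa-miR-425-3p	LB	0.939	0.957	-0.019
hsa-miR-30c-5p	HER2E	1.746	0.295	1.451
hsa-miR-26b-3p	HER2E	1.175	0.867	0.308
hsa-miR-29c-5p	HER2E	1.163	0.883	0.281
hsa-miR-19b-3p	HER2E	1.128	0.941	0.187
hsa-miR-20b-5p	HER2E	1.019	0.871	0.148
hsa-miR-874-3p	HER2E	1.038	0.900	0.138
hsa-miR-3127-5p	HER2E	1.038	0.901	0.136
hsa-miR-299-5p	HER2E	1.059	0.941	0.118
hsa-miR-20a-3p	HER2E	1.068	0.956	0.111
hsa-miR-199b-5p	BL	1.508	0.447	1.061
hsa-miR-889-3p	BL	1.240	0.753	0.486
hsa-miR-26b-5p	BL	1.230	0.769	0.461
hsa-miR-214-3p	BL	1.145	0.907	0.238
hsa-miR-136-3p	BL	0.999	0.836	0.163
hsa-miR-134-5p	BL	1.011	0.856	0.156
hsa-miR-101-5p	BL	1.022	0.873	0.148
hsa-miR-30b-5p	BL	0.992	0.844	0.148
hsa-miR-542-3p	BL	1.028	0.888	0.140
hsa-miR-154-5p	BL	1.060	0.947	0.114
hsa-miR-375	BL	1.066	0.958	0.108
hsa-miR-409-5p	BL	0.971	0.893	0.078
hsa-miR-409-3p	BL	0.929	0.972	-0.043
hsa-miR-539-5p	BL	0.925	0.984	-0.059
hsa-let-7f-5p	BL	0.920	0.993	-0.073
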