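gene	star_allele	variant_id	required_allele	score	priority
CYP1A2	*1A	.	.	1	99
CYP1A2	*1F	rs762551	A	2	2
CYP1A2	*1C	rs2069514	A	0	2
CYP1A2	*1L	rs2069514	A	1	1
CYP1A2	*1L	rs762551	A	1	1
CYP2B6	*1	.	.	1	99
CYP2B6	*9	rs3745274	T	1	2
CYP2B6	*4	rs2279343	G	2	2
CYP2B6	*6	rs3745274	T	0	1
CYP2B6	*6	rs2279343	G	0	1
CYP2B6	*5	rs3211371	T	0	2
CYP2B6	*22	rs34223104	C	2	2
CYP2C19	*1	.	.	1	99
CYP2C19	*2	rs4244285	A	0	1
CYP2C19	*3	rs4986893	A	0	1
CYP2C19	*17	rs12248560	T	2	1
CYP2C9	*1	.	.	0	99
CYP2C9	*2	rs1799853	T	1	1
CYP2C9	*3	rs1057910	C	1	1
CYP2D6	*1	.	.	1	99
CYP2D6	*2	rs16947	A	1	3
CYP2D6	*3	rs35742686	-	0	1
CYP2D6	*4	rs3892097	A	0	1
CYP2D6	*4	rs1065852	T	0	1
CYP2D6	*6	rs5030655	-	0	1
CYP2D6	*9	rs5030656	-	0.5	2
CYP2D6	*10	rs1065852	T	0.5	2
CYP2D6	*17	rs28371706	T	0.5	2
CYP2D6	*41	rs28371725	A	0.5	2
CYP3A4	*1	.	.	1	99
CYP3A4	*22	rs35599367	T	0	1
CYP3A5	*1	.	.	1	99
CYP3A5	*3	rs776746	G	0	1
CYP3A7	*1	.	.	1	99
CYP3A7	*1C	rs45446698	G	0	1
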