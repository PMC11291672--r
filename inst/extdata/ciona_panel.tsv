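marker_id	chromosome	position_bp	allele_robusta	allele_intestinalis	region	robusta_channel
SNP11	chr5	700100	A	G	left_shoulder	1
SNP12	chr5	760000	T	C	left_shoulder	1
SNP13	chr5	795000	G	A	left_shoulder	1
SNP14	chr5	855000	C	T	left_shoulder	1
SNP15	chr5	877281	A	C	core	1
SNP16	chr5	899300	G	T	right_shoulder	1
SNP18	chr5	1010000	T	A	right_shoulder	1
SNP19	chr5	1110000	C	G	right_shoulder	1
SNP20	chr5	1276000	A	T	right_shoulder	1
SNP21	chr5	1350000	G	C	right_shoulder	1
SB	chr5	2200000	T	G	background	1
MITO1	mtDNA	4520	C	A	mitochondrial	1
M01	chr1	1843000	A	C	multiplex_member	1
M02	chr2	2210500	G	A	multiplex_member	1
M03	chr3	905400	T	G	multiplex_member	1
M04	chr4	3120000	C	T	multiplex_member	1
M05	chr6	1507200	A	G	multiplex_member	1
M06	chr7	2650900	T	C	multiplex_member	1
M07	chr9	780300	G	T	multiplex_member	1
M08	chr11	1934800	C	A	multiplex_member	1
M09	chr12	644100	A	T	multiplex_member	1
M10	chr13	2286400	G	C	multiplex_member	1
M11	chr14	1102600	T	A	multiplex_member	1
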