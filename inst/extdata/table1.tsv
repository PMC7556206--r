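patient_id	hemisphere	hippocampal_lesion	neocortical_lesion	surgery	outcome_12m_engel	group
1	L	HS	FCD	/	/	1
2	R	HS	FCD	ATL	IIB	1
3	R	HS	Gliotic area/gray-white blurring	ATL	IA	2
4	R	HS	FCD	ATL	IA	1
5	L	Hc malformation	FCD	/	/	2
6	L	HS	FCD	EL + Hc resection	IB	2
7	R	HS	FCD	ATL	IIIA	2
8	R	HS	FCD	ATL	IIA	1
9	R	HS	FCD	ATL	IA	3
10	R	HS	Gliotic area/gray-white blurring	ATL	IVB	2
11	L	Hc malformation	Meningoencephalocele	Temporal pole resection	IA	3
12	L	HS	Mild MCD	ATL	IA	1
13	R	Hc gliosis	FCD	ATL	IA	3
14	R	Hc gliosis	Meningoencephalocele	Temporal pole resection + AH	IA	3
15	R	HS	Mild MCD	ATL	IA	2
16	R	Hc gliosis	Mild MCD	ATL	IA	2
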