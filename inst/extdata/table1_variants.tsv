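pos	ref	alt	id	closest	location	ac_1000G	an_1000G	ac_UK10K	an_UK10K	ac_GoNL	an_GoNL	ac_ExAC	an_ExAC	ac_UCL	an_UCL
18057973	A	ACCGGTTCCGGCGGCCGGGGCTG	NA	OVOL2	promoter	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18112700	T	A	rs556855465	PET117	intergenic	2	5008	4	7562	NA	NA	NA	NA	NA	NA
18114422	A	G	rs560139714	PET117	intergenic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18119439	A	G	rs563340932	PET117	intergenic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18124502	TAGA	T	NA	PET117	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18189275	CT	C	NA	CSRP2BP	intergenic	NA	NA	1	7562	NA	NA	NA	NA	NA	NA
18189278	C	T	rs772649261	CSRP2BP	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18240797	G	A	rs552441504	CSRP2BP	intergenic	5	5008	NA	NA	7	998	NA	NA	NA	NA
18273229	G	A	rs184537558	ZNF133	intergenic	5	5008	NA	NA	NA	NA	NA	NA	NA	NA
18292765	C	T	rs542530373	ZNF133	deep_intronic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18319195	A	G	rs530751423	ZNF133	intergenic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18379703	G	A	rs558852368	LINC00851	deep_intronic	2	5008	NA	NA	NA	NA	NA	NA	NA	NA
18396543	T	G	rs560809093	DZANK1	missense	NA	NA	NA	NA	1	998	5	120650	NA	NA
18476283	G	A	rs537806334	POLR3F	deep_intronic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18646498	G	A	rs532426738	DTD1	deep_intronic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18784373	C	A	rs570664591	DTD1	intergenic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18810051	G	A	rs543631581	C20orf78	non_coding_transcript	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18818189	T	C	rs566681725	C20orf78	deep_intronic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
18851016	C	T	rs550023958	C20orf78	intergenic	NA	NA	NA	NA	1	998	NA	NA	NA	NA
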