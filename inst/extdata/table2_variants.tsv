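pos	ref	alt	id	closest	location	ac_1000G	an_1000G	ac_UK10K	an_UK10K	ac_GoNL	an_GoNL	ac_ExAC	an_ExAC	ac_UCL	an_UCL
17779178	T	C	NA	BANF2	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
17962621	T	TTCGGGGGAGGGGGG	NA	SNX5	deep_intronic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18010425	T	C	rs62206463	OVOL2	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18058004	A	G	NA	OVOL2	promoter	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18373822	G	A	NA	LINC00851	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18504053	T	G	NA	SEC23B	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18800653	T	C	NA	NR_026885	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18831605	T	C	NA	C20orf78	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18836917	A	G	NA	C20orf78	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18863686	G	C	rs148906570	C20orf78	intergenic	10	5008	NA	NA	NA	NA	NA	NA	NA	NA
18870484	C	G	rs150426313	C20orf78	intergenic	10	5008	60	7562	9	998	NA	NA	NA	NA
18937206	C	G	NA	C20orf78	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
18950428	C	T	NA	C20orf78	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
19140530	G	A	NA	SLC24A3	intergenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
19325002	A	G	NA	SLC24A3	deep_intronic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
19331987	C	T	rs537549121	SLC24A3	deep_intronic	9	5008	2	7562	NA	NA	NA	NA	NA	NA
19601355	C	A	NA	SLC24A3	deep_intronic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
19637683	A	G	NA	SLC24A3	deep_intronic	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
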