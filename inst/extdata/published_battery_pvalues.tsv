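effect	measure	p	published_fdr
time	cpss	0.0025	TRUE
time	phqa	0.00001	TRUE
time	hads	0.019	TRUE
time	crafft	0.014	TRUE
time	rosenberg	0.00011	TRUE
time	kidscreen	0.0028	TRUE
time	cyrm	0.32	FALSE
time	probable_ptsd	0.00070	TRUE
time	probable_depression	0.00033	TRUE
time	probable_msd	0.0011	TRUE
time	suicidal_thinking	0.018	TRUE
time	probable_anxiety	0.00020	TRUE
time	probable_sud	0.012	TRUE
time	tobacco_use	0.71	FALSE
time	any_of_4	0.00004	TRUE
age	cpss	0.00001	TRUE
age	phqa	0.00001	TRUE
age	hads	0.00001	TRUE
age	crafft	0.00001	TRUE
age	rosenberg	0.00001	TRUE
age	kidscreen	0.00001	TRUE
age	cyrm	0.00002	TRUE
age	probable_ptsd	0.00001	TRUE
age	probable_depression	0.00001	TRUE
age	probable_msd	0.00001	TRUE
age	suicidal_thinking	0.0088	TRUE
age	probable_anxiety	0.00001	TRUE
age	probable_sud	0.00001	TRUE
age	tobacco_use	0.00001	TRUE
age	any_of_4	0.00001	TRUE
female_vs_male	cpss	0.00001	TRUE
female_vs_male	phqa	0.00001	TRUE
female_vs_male	hads	0.00001	TRUE
female_vs_male	crafft	0.00002	TRUE
female_vs_male	rosenberg	0.00001	TRUE
female_vs_male	kidscreen	0.00001	TRUE
female_vs_male	cyrm	0.0014	TRUE
female_vs_male	probable_ptsd	0.00001	TRUE
female_vs_male	probable_depression	0.00001	TRUE
female_vs_male	probable_msd	0.00001	TRUE
female_vs_male	suicidal_thinking	0.00001	TRUE
female_vs_male	probable_anxiety	0.00001	TRUE
female_vs_male	probable_sud	0.00001	TRUE
female_vs_male	tobacco_use	0.0040	TRUE
female_vs_male	any_of_4	0.00001	TRUE
other_vs_fm	cpss	0.00001	TRUE
other_vs_fm	phqa	0.00001	TRUE
other_vs_fm	hads	0.00001	TRUE
other_vs_fm	crafft	0.00001	TRUE
other_vs_fm	rosenberg	0.00001	TRUE
other_vs_fm	kidscreen	0.00001	TRUE
other_vs_fm	cyrm	0.00001	TRUE
other_vs_fm	probable_ptsd	0.00003	TRUE
other_vs_fm	probable_depression	0.00001	TRUE
other_vs_fm	probable_msd	0.00001	TRUE
other_vs_fm	suicidal_thinking	0.00001	TRUE
other_vs_fm	probable_anxiety	0.00006	TRUE
other_vs_fm	probable_sud	0.00024	TRUE
other_vs_fm	tobacco_use	0.00027	TRUE
other_vs_fm	any_of_4	0.00002	TRUE
pnts_vs_fm	cpss	0.00001	TRUE
pnts_vs_fm	phqa	0.00001	TRUE
pnts_vs_fm	hads	0.00004	TRUE
pnts_vs_fm	crafft	0.00001	TRUE
pnts_vs_fm	rosenberg	0.00001	TRUE
pnts_vs_fm	kidscreen	0.00001	TRUE
pnts_vs_fm	cyrm	0.00001	TRUE
pnts_vs_fm	probable_ptsd	0.00022	TRUE
pnts_vs_fm	probable_depression	0.00024	TRUE
pnts_vs_fm	probable_msd	0.00003	TRUE
pnts_vs_fm	suicidal_thinking	0.00018	TRUE
pnts_vs_fm	probable_anxiety	0.00001	TRUE
pnts_vs_fm	probable_sud	0.00006	TRUE
pnts_vs_fm	tobacco_use	0.0012	TRUE
pnts_vs_fm	any_of_4	0.00003	TRUE
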