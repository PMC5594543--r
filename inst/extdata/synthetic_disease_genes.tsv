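disease	gene	curated
Myocardial Ischemia	GENE149	TRUE
Myocardial Ischemia	GENE017	TRUE
Myocardial Ischemia	GENE041	TRUE
Myocardial Ischemia	GENE103	TRUE
Myocardial Ischemia	GENE388	TRUE
Myocardial Ischemia	GENE167	TRUE
Myocardial Ischemia	GENE376	TRUE
Myocardial Ischemia	GENE248	TRUE
Myocardial Ischemia	GENE304	TRUE
Myocardial Ischemia	GENE245	TRUE
Myocardial Ischemia	GENE061	TRUE
Myocardial Ischemia	GENE359	TRUE
Myocardial Ischemia	GENE286	TRUE
Myocardial Ischemia	GENE090	TRUE
Myocardial Ischemia	GENE083	TRUE
Myocardial Ischemia	GENE101	TRUE
Myocardial Ischemia	GENE280	TRUE
Myocardial Ischemia	GENE106	TRUE
Myocardial Ischemia	GENE191	TRUE
Myocardial Ischemia	GENE198	TRUE
Myocardial Ischemia	GENE023	TRUE
Myocardial Ischemia	GENE058	TRUE
Myocardial Ischemia	GENE256	TRUE
Myocardial Ischemia	GENE340	TRUE
Myocardial Ischemia	GENE082	TRUE
Myocardial Ischemia	GENE259	TRUE
Myocardial Ischemia	GENE372	TRUE
Myocardial Ischemia	GENE140	TRUE
Myocardial Ischemia	GENE143	TRUE
Hypertensive Diseases	GENE062	TRUE
Hypertensive Diseases	GENE075	TRUE
Hypertensive Diseases	GENE222	TRUE
Hypertensive Diseases	GENE051	TRUE
Hypertensive Diseases	GENE110	TRUE
Hypertensive Diseases	GENE189	TRUE
Hypertensive Diseases	GENE190	TRUE
Hypertensive Diseases	GENE304	TRUE
Hypertensive Diseases	GENE038	TRUE
Hypertensive Diseases	GENE162	TRUE
Hypertensive Diseases	GENE241	TRUE
Hypertensive Diseases	GENE115	TRUE
Hypertensive Diseases	GENE199	TRUE
Hypertensive Diseases	GENE223	TRUE
Hypertensive Diseases	GENE328	TRUE
Hypertensive Diseases	GENE342	TRUE
Hypertensive Diseases	GENE346	TRUE
Hypertensive Diseases	GENE031	TRUE
Hypertensive Diseases	GENE082	TRUE
Hypertensive Diseases	GENE156	TRUE
Hypertensive Diseases	GENE042	TRUE
Hypertensive Diseases	GENE088	TRUE
Hypertensive Diseases	GENE058	TRUE
Hypertensive Diseases	GENE313	TRUE
Hypertensive Diseases	GENE054	TRUE
Hypertensive Diseases	GENE274	TRUE
Hypertensive Diseases	GENE167	TRUE
Hypertensive Diseases	GENE344	TRUE
Hypertensive Diseases	GENE306	TRUE
Hypertensive Diseases	GENE093	TRUE
Hypertensive Diseases	GENE369	TRUE
Inflammation	GENE040	TRUE
Inflammation	GENE349	TRUE
Inflammation	GENE190	TRUE
Inflammation	GENE128	TRUE
Inflammation	GENE162	TRUE
Inflammation	GENE034	TRUE
Inflammation	GENE074	TRUE
Inflammation	GENE310	TRUE
Inflammation	GENE021	TRUE
Inflammation	GENE203	TRUE
Inflammation	GENE378	TRUE
Inflammation	GENE232	TRUE
Inflammation	GENE324	TRUE
Inflammation	GENE382	TRUE
Inflammation	GENE001	TRUE
Inflammation	GENE118	TRUE
Inflammation	GENE090	TRUE
Inflammation	GENE053	TRUE
Inflammation	GENE191	TRUE
Inflammation	GENE367	TRUE
Inflammation	GENE342	TRUE
Inflammation	GENE076	TRUE
Inflammation	GENE331	TRUE
Inflammation	GENE069	TRUE
Inflammation	GENE238	TRUE
Inflammation	GENE358	TRUE
Inflammation	GENE271	TRUE
Inflammation	GENE303	TRUE
Inflammation	GENE291	TRUE
Inflammation	GENE250	TRUE
Inflammation	GENE046	TRUE
Inflammation	GENE082	TRUE
Heart Failure	GENE049	TRUE
Heart Failure	GENE086	TRUE
Heart Failure	GENE225	TRUE
Heart Failure	GENE047	TRUE
Heart Failure	GENE228	TRUE
Heart Failure	GENE226	TRUE
Heart Failure	GENE399	TRUE
Heart Failure	GENE151	TRUE
Heart Failure	GENE340	TRUE
Heart Failure	GENE309	TRUE
Heart Failure	GENE315	TRUE
Heart Failure	GENE318	TRUE
Heart Failure	GENE342	TRUE
Heart Failure	GENE014	TRUE
Heart Failure	GENE373	TRUE
Heart Failure	GENE179	TRUE
Heart Failure	GENE262	TRUE
Heart Failure	GENE320	TRUE
Heart Failure	GENE337	TRUE
Heart Failure	GENE135	TRUE
Heart Failure	GENE138	TRUE
Heart Failure	GENE220	TRUE
Heart Failure	GENE203	TRUE
Heart Failure	GENE377	TRUE
Heart Failure	GENE355	TRUE
Heart Failure	GENE119	TRUE
Heart Failure	GENE036	TRUE
Heart Failure	GENE294	TRUE
Heart Failure	GENE387	TRUE
Heart Failure	GENE163	TRUE
Thrombosis	GENE301	TRUE
Thrombosis	GENE196	TRUE
Thrombosis	GENE375	TRUE
Thrombosis	GENE329	TRUE
Thrombosis	GENE088	TRUE
Thrombosis	GENE051	TRUE
Thrombosis	GENE365	TRUE
Thrombosis	GENE325	TRUE
Thrombosis	GENE102	TRUE
Thrombosis	GENE281	TRUE
Thrombosis	GENE323	TRUE
Thrombosis	GENE039	TRUE
Thrombosis	GENE331	TRUE
Thrombosis	GENE103	TRUE
Thrombosis	GENE307	TRUE
Thrombosis	GENE119	TRUE
Thrombosis	GENE138	TRUE
Thrombosis	GENE023	TRUE
Thrombosis	GENE360	TRUE
Thrombosis	GENE171	TRUE
Thrombosis	GENE387	TRUE
Thrombosis	GENE106	TRUE
Thrombosis	GENE343	TRUE
Thrombosis	GENE141	TRUE
Thrombosis	GENE021	TRUE
Thrombosis	GENE202	TRUE
Thrombosis	GENE308	TRUE
Thrombosis	GENE200	TRUE
Thrombosis	GENE398	TRUE
Thrombosis	GENE321	TRUE
Atrial Fibrillation	GENE051	TRUE
Atrial Fibrillation	GENE294	TRUE
Atrial Fibrillation	GENE133	TRUE
Atrial Fibrillation	GENE340	TRUE
Atrial Fibrillation	GENE337	TRUE
Atrial Fibrillation	GENE243	TRUE
Atrial Fibrillation	GENE114	TRUE
Atrial Fibrillation	GENE333	TRUE
Atrial Fibrillation	GENE298	TRUE
Atrial Fibrillation	GENE221	TRUE
Atrial Fibrillation	GENE143	TRUE
Atrial Fibrillation	GENE313	TRUE
Atrial Fibrillation	GENE141	TRUE
Atrial Fibrillation	GENE181	TRUE
Atrial Fibrillation	GENE356	TRUE
Atrial Fibrillation	GENE287	TRUE
Atrial Fibrillation	GENE152	TRUE
Atrial Fibrillation	GENE154	TRUE
Atrial Fibrillation	GENE328	TRUE
Atrial Fibrillation	GENE076	TRUE
Atrial Fibrillation	GENE119	TRUE
Atrial Fibrillation	GENE139	TRUE
Atrial Fibrillation	GENE334	TRUE
Atrial Fibrillation	GENE325	TRUE
Atrial Fibrillation	GENE153	TRUE
Atrial Fibrillation	GENE231	TRUE
Atrial Fibrillation	GENE351	TRUE
Atrial Fibrillation	GENE070	TRUE
Atrial Fibrillation	GENE229	TRUE
Atrial Fibrillation	GENE211	TRUE
Myocardial Ischemia	GENE001	TRUE
Hypertensive Diseases	GENE001	TRUE
Heart Failure	GENE001	TRUE
Thrombosis	GENE001	TRUE
Myocardial Ischemia	GENE057	FALSE
Myocardial Ischemia	GENE191	FALSE
Myocardial Ischemia	GENE320	FALSE
Myocardial Ischemia	GENE308	FALSE
Myocardial Ischemia	GENE282	FALSE
Myocardial Ischemia	GENE204	FALSE
Myocardial Ischemia	GENE065	FALSE
Myocardial Ischemia	GENE027	FALSE
Myocardial Ischemia	GENE132	FALSE
Myocardial Ischemia	GENE377	FALSE
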