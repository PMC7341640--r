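# synthetic stand-in for the published 253-gene EMT perturbation signature
gene_id	direction
CDH1	down
CDH2	up
VIM	down
JUP	up
FN1	down
SNAI1	down
SNAI2	down
ZEB1	up
ZEB2	up
TWIST1	down
TWIST2	up
CRB3	down
DSP	up
OCLN	down
CLDN3	up
CLDN4	down
CLDN7	down
KRT8	up
KRT18	down
KRT19	up
MMP2	down
MMP9	down
ITGB1	up
ITGA5	up
SPARC	up
COL1A1	down
COL1A2	up
COL3A1	up
TGFB1	up
TGFBR2	down
WNT5A	up
FOXC2	up
GSC	down
EPCAM	up
MUC1	down
ESRP1	down
ESRP2	down
GRHL2	down
OVOL2	up
ELMO3	up
RPS6KA1	down
TJP1	up
CDH11	down
POSTN	up
THBS1	down
SERPINE1	up
TNC	up
LOXL2	down
EMTSYN001	up
EMTSYN002	down
EMTSYN003	up
EMTSYN004	up
EMTSYN005	up
EMTSYN006	up
EMTSYN007	up
EMTSYN008	down
EMTSYN009	up
EMTSYN010	up
EMTSYN011	down
EMTSYN012	up
EMTSYN013	up
EMTSYN014	down
EMTSYN015	up
EMTSYN016	down
EMTSYN017	up
EMTSYN018	up
EMTSYN019	up
EMTSYN020	up
EMTSYN021	up
EMTSYN022	up
EMTSYN023	up
EMTSYN024	down
EMTSYN025	down
EMTSYN026	down
EMTSYN027	up
EMTSYN028	up
EMTSYN029	down
EMTSYN030	down
EMTSYN031	up
EMTSYN032	down
EMTSYN033	down
EMTSYN034	up
EMTSYN035	down
EMTSYN036	up
EMTSYN037	down
EMTSYN038	up
EMTSYN039	down
EMTSYN040	up
EMTSYN041	down
EMTSYN042	down
EMTSYN043	down
EMTSYN044	up
EMTSYN045	up
EMTSYN046	down
EMTSYN047	up
EMTSYN048	down
EMTSYN049	up
EMTSYN050	up
EMTSYN051	up
EMTSYN052	down
EMTSYN053	up
EMTSYN054	up
EMTSYN055	down
EMTSYN056	down
EMTSYN057	down
EMTSYN058	up
EMTSYN059	up
EMTSYN060	down
EMTSYN061	up
EMTSYN062	down
EMTSYN063	down
EMTSYN064	down
EMTSYN065	up
EMTSYN066	down
EMTSYN067	down
EMTSYN068	up
EMTSYN069	down
EMTSYN070	down
EMTSYN071	up
EMTSYN072	up
EMTSYN073	up
EMTSYN074	down
EMTSYN075	down
EMTSYN076	up
EMTSYN077	up
EMTSYN078	down
EMTSYN079	up
EMTSYN080	up
EMTSYN081	up
EMTSYN082	up
EMTSYN083	down
EMTSYN084	down
EMTSYN085	up
EMTSYN086	up
EMTSYN087	up
EMTSYN088	up
EMTSYN089	down
EMTSYN090	up
EMTSYN091	up
EMTSYN092	up
EMTSYN093	up
EMTSYN094	down
EMTSYN095	down
EMTSYN096	up
EMTSYN097	up
EMTSYN098	down
EMTSYN099	up
EMTSYN100	up
EMTSYN101	up
EMTSYN102	down
EMTSYN103	down
EMTSYN104	down
EMTSYN105	down
EMTSYN106	up
EMTSYN107	up
EMTSYN108	up
EMTSYN109	up
EMTSYN110	down
EMTSYN111	down
EMTSYN112	up
EMTSYN113	up
EMTSYN114	up
EMTSYN115	down
EMTSYN116	down
EMTSYN117	down
EMTSYN118	down
EMTSYN119	up
EMTSYN120	down
EMTSYN121	down
EMTSYN122	down
EMTSYN123	up
EMTSYN124	down
EMTSYN125	down
EMTSYN126	up
EMTSYN127	down
EMTSYN128	down
EMTSYN129	up
EMTSYN130	down
EMTSYN131	up
EMTSYN132	down
EMTSYN133	up
EMTSYN134	up
EMTSYN135	up
EMTSYN136	up
EMTSYN137	up
EMTSYN138	down
EMTSYN139	down
EMTSYN140	down
EMTSYN141	up
EMTSYN142	up
EMTSYN143	up
EMTSYN144	down
EMTSYN145	up
EMTSYN146	up
EMTSYN147	down
EMTSYN148	down
EMTSYN149	up
EMTSYN150	down
EMTSYN151	down
EMTSYN152	down
EMTSYN153	up
EMTSYN154	down
EMTSYN155	up
EMTSYN156	up
EMTSYN157	up
EMTSYN158	down
EMTSYN159	up
EMTSYN160	up
EMTSYN161	up
EMTSYN162	up
EMTSYN163	down
EMTSYN164	down
EMTSYN165	up
EMTSYN166	down
EMTSYN167	down
EMTSYN168	down
EMTSYN169	up
EMTSYN170	down
EMTSYN171	down
EMTSYN172	up
EMTSYN173	up
EMTSYN174	down
EMTSYN175	up
EMTSYN176	up
EMTSYN177	up
EMTSYN178	down
EMTSYN179	up
EMTSYN180	up
EMTSYN181	down
EMTSYN182	up
EMTSYN183	up
EMTSYN184	down
EMTSYN185	down
EMTSYN186	down
EMTSYN187	down
EMTSYN188	up
EMTSYN189	up
EMTSYN190	up
EMTSYN191	down
EMTSYN192	down
EMTSYN193	down
EMTSYN194	up
EMTSYN195	down
EMTSYN196	down
EMTSYN197	up
EMTSYN198	down
EMTSYN199	down
EMTSYN200	down
EMTSYN201	down
EMTSYN202	up
EMTSYN203	down
EMTSYN204	up
EMTSYN205	up
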