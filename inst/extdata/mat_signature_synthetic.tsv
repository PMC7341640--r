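# synthetic stand-in for the 138-gene MAT perturbation signature
gene_id	direction
VIM	down
SNAI2	down
SPARC	up
RHOA	up
RHOB	up
RHOC	down
ROCK1	up
ROCK2	up
ARHGDIB	up
ARHGAP5	down
MYL9	up
MYLK	up
PAK1	up
PAK2	down
RAC1	down
RAC2	down
CDC42	down
LIMK1	up
LIMK2	up
PFN1	up
CFL1	up
EZR	down
RDX	down
MSN	up
MYH9	up
MYH10	down
ARPC2	up
ARPC3	down
WASF2	down
CTTN	down
S100A4	down
ANXA1	up
CAPN2	down
MATSYN001	down
MATSYN002	down
MATSYN003	down
MATSYN004	up
MATSYN005	up
MATSYN006	up
MATSYN007	down
MATSYN008	down
MATSYN009	down
MATSYN010	up
MATSYN011	up
MATSYN012	up
MATSYN013	down
MATSYN014	down
MATSYN015	up
MATSYN016	down
MATSYN017	up
MATSYN018	down
MATSYN019	down
MATSYN020	down
MATSYN021	down
MATSYN022	down
MATSYN023	down
MATSYN024	up
MATSYN025	up
MATSYN026	up
MATSYN027	down
MATSYN028	down
MATSYN029	up
MATSYN030	up
MATSYN031	up
MATSYN032	down
MATSYN033	down
MATSYN034	up
MATSYN035	up
MATSYN036	up
MATSYN037	up
MATSYN038	up
MATSYN039	down
MATSYN040	up
MATSYN041	down
MATSYN042	down
MATSYN043	down
MATSYN044	down
MATSYN045	down
MATSYN046	down
MATSYN047	up
MATSYN048	down
MATSYN049	up
MATSYN050	down
MATSYN051	up
MATSYN052	down
MATSYN053	up
MATSYN054	down
MATSYN055	down
MATSYN056	down
MATSYN057	up
MATSYN058	down
MATSYN059	up
MATSYN060	down
MATSYN061	down
MATSYN062	up
MATSYN063	down
MATSYN064	down
MATSYN065	up
MATSYN066	up
MATSYN067	up
MATSYN068	down
MATSYN069	down
MATSYN070	down
MATSYN071	down
MATSYN072	down
MATSYN073	up
MATSYN074	down
MATSYN075	down
MATSYN076	up
MATSYN077	up
MATSYN078	up
MATSYN079	up
MATSYN080	down
MATSYN081	up
MATSYN082	up
MATSYN083	down
MATSYN084	down
MATSYN085	up
MATSYN086	up
MATSYN087	up
MATSYN088	down
MATSYN089	up
MATSYN090	up
MATSYN091	up
MATSYN092	down
MATSYN093	down
MATSYN094	up
MATSYN095	down
MATSYN096	down
MATSYN097	up
MATSYN098	up
MATSYN099	down
MATSYN100	up
MATSYN101	up
MATSYN102	down
MATSYN103	up
MATSYN104	down
MATSYN105	down
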