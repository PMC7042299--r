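family_id	individual_id	diagnosis	age_at_onset	index_case	sampled
FML001	II.1	MDS	23	TRUE	TRUE
FML002	II.1	MDS	23	TRUE	TRUE
FML003	II.1	MDS	23	TRUE	TRUE
FML004	II.1	MDS	23	TRUE	TRUE
FML005	II.1	MDS	23	TRUE	TRUE
FML006	II.1	MDS	23	TRUE	TRUE
FML007	II.1	MDS	23	TRUE	TRUE
FML008	II.1	MDS	23	TRUE	TRUE
FML009	II.1	MDS	23	TRUE	TRUE
FML010	II.1	MDS	23	TRUE	TRUE
FML011	II.1	MDS	23	TRUE	TRUE
FML012	II.1	MDS	23	TRUE	TRUE
FML013	II.1	AML	23	TRUE	TRUE
FML014	II.1	AML	23	TRUE	TRUE
FML015	II.1	AML	23	TRUE	TRUE
FML016	II.1	AML	23	TRUE	TRUE
FML017	II.1	AML	23	TRUE	TRUE
FML018	II.1	AML	23	TRUE	TRUE
FML019	II.1	AML	23	TRUE	TRUE
FML020	II.1	AML	23	TRUE	TRUE
FML021	II.1	AML	23	TRUE	TRUE
FML022	II.1	AML	23	TRUE	TRUE
FML023	II.1	AML	23	TRUE	TRUE
FML024	II.1	AML	23	TRUE	TRUE
FML025	II.1	AML	23	TRUE	TRUE
FML026	II.1	AML	23	TRUE	TRUE
FML027	II.1	AML	23	TRUE	TRUE
FML028	II.1	AML	23	TRUE	TRUE
FML029	II.1	AML	23	TRUE	TRUE
FML030	II.1	MDS	23	TRUE	TRUE
FML030	II.2	AML	26	FALSE	TRUE
FML030	II.3	none		FALSE	TRUE
FML031	II.1	MDS	23	TRUE	TRUE
FML031	II.2	AML	26	FALSE	TRUE
FML031	II.3	none		FALSE	TRUE
FML032	II.1	MDS	23	TRUE	TRUE
FML032	II.2	AML	26	FALSE	TRUE
FML032	II.3	none		FALSE	TRUE
FML033	II.1	MDS	23	TRUE	TRUE
FML033	II.2	AML	26	FALSE	TRUE
FML033	II.3	none		FALSE	TRUE
FML034	II.1	MDS	23	TRUE	TRUE
FML034	II.2	AML	26	FALSE	TRUE
FML034	II.3	none		FALSE	TRUE
FML035	II.1	MDS	23	TRUE	TRUE
FML035	II.2	AML	26	FALSE	TRUE
FML035	II.3	none		FALSE	TRUE
FML036	II.1	MDS	23	TRUE	TRUE
FML036	II.2	AML	26	FALSE	TRUE
FML036	II.3	none		FALSE	TRUE
FML037	II.1	MDS	23	TRUE	TRUE
FML037	II.2	AML	26	FALSE	TRUE
FML037	II.3	none		FALSE	TRUE
FML038	II.1	MDS	23	TRUE	TRUE
FML038	II.2	AML	26	FALSE	TRUE
FML038	II.3	none		FALSE	TRUE
FML039	II.1	MDS	23	TRUE	TRUE
FML039	II.2	AML	26	FALSE	TRUE
FML039	II.3	none		FALSE	TRUE
FML040	II.1	MDS	23	TRUE	TRUE
FML040	II.2	AML	26	FALSE	TRUE
FML040	II.3	none		FALSE	TRUE
FML041	II.1	MDS	23	TRUE	TRUE
FML041	II.2	AML	26	FALSE	TRUE
FML041	II.3	none		FALSE	TRUE
FML042	II.1	MDS	23	TRUE	TRUE
FML042	II.2	AML	26	FALSE	TRUE
FML042	II.3	none		FALSE	TRUE
FML043	II.1	MDS	23	TRUE	TRUE
FML043	II.2	AML	26	FALSE	TRUE
FML043	II.3	none		FALSE	TRUE
FML044	II.1	MDS	23	TRUE	TRUE
FML044	II.2	AML	26	FALSE	TRUE
FML044	II.3	none		FALSE	TRUE
FML045	II.1	MDS	23	TRUE	TRUE
FML045	II.2	AML	26	FALSE	TRUE
FML045	II.3	none		FALSE	TRUE
FML046	II.1	MDS	23	TRUE	TRUE
FML046	II.2	AML	26	FALSE	TRUE
FML046	II.3	none		FALSE	TRUE
FML047	II.1	MDS	23	TRUE	TRUE
FML047	II.2	AML	26	FALSE	TRUE
FML047	II.3	none		FALSE	TRUE
FML048	II.1	MDS	23	TRUE	TRUE
FML048	II.2	TCP	26	FALSE	TRUE
FML048	II.3	MDS	29	FALSE	TRUE
FML048	II.4	none		FALSE	TRUE
FML049	II.1	AML	23	TRUE	TRUE
FML049	II.2	TCP	26	FALSE	TRUE
FML049	II.3	none		FALSE	TRUE
FML050	II.1	AML	23	TRUE	TRUE
FML050	II.2	TCP	26	FALSE	TRUE
FML050	II.3	none		FALSE	TRUE
FML051	II.1	AML	23	TRUE	TRUE
FML051	II.2	TCP	26	FALSE	TRUE
FML051	II.3	none		FALSE	TRUE
FML052	II.1	AML	23	TRUE	TRUE
FML052	II.2	TCP	26	FALSE	TRUE
FML052	II.3	none		FALSE	TRUE
FML053	II.1	AML	23	TRUE	TRUE
FML053	II.2	TCP	26	FALSE	TRUE
FML053	II.3	none		FALSE	TRUE
FML054	II.1	AML	23	TRUE	TRUE
FML054	II.2	TCP	26	FALSE	TRUE
FML054	II.3	none		FALSE	TRUE
FML055	II.1	AML	23	TRUE	TRUE
FML055	II.2	TCP	26	FALSE	TRUE
FML055	II.3	none		FALSE	TRUE
FML056	II.1	AML	23	TRUE	TRUE
FML056	II.2	TCP	26	FALSE	TRUE
FML056	II.3	none		FALSE	TRUE
FML057	II.1	AML	23	TRUE	TRUE
FML057	II.2	TCP	26	FALSE	TRUE
FML057	II.3	none		FALSE	TRUE
FML058	II.1	AML	23	TRUE	TRUE
FML058	II.2	TCP	26	FALSE	TRUE
FML058	II.3	none		FALSE	TRUE
FML059	II.1	AML	23	TRUE	TRUE
FML059	II.2	TCP	26	FALSE	TRUE
FML059	II.3	none		FALSE	TRUE
FML060	II.1	AML	23	TRUE	TRUE
FML060	II.2	TCP	26	FALSE	TRUE
FML060	II.3	none		FALSE	TRUE
FML061	II.1	AML	23	TRUE	TRUE
FML061	II.2	TCP	26	FALSE	TRUE
FML061	II.3	none		FALSE	TRUE
FML062	II.1	AML	23	TRUE	TRUE
FML062	II.2	TCP	26	FALSE	TRUE
FML062	II.3	none		FALSE	TRUE
FML063	II.1	AML	23	TRUE	TRUE
FML063	II.2	BMF	26	FALSE	TRUE
FML063	II.3	MDS	29	FALSE	TRUE
FML063	II.4	none		FALSE	TRUE
FML064	II.1	AML	23	TRUE	TRUE
FML064	II.2	BMF	26	FALSE	TRUE
FML064	II.3	MDS	29	FALSE	TRUE
FML064	II.4	none		FALSE	TRUE
FML065	II.1	AML	23	TRUE	TRUE
FML065	II.2	BMF	26	FALSE	TRUE
FML065	II.3	MDS	29	FALSE	TRUE
FML065	II.4	none		FALSE	TRUE
FML066	II.1	AML	23	TRUE	TRUE
FML066	II.2	BMF	26	FALSE	TRUE
FML066	II.3	MDS	29	FALSE	TRUE
FML066	II.4	none		FALSE	TRUE
FML067	II.1	AML	23	TRUE	TRUE
FML067	II.2	BMF	26	FALSE	TRUE
FML067	II.3	MDS	29	FALSE	TRUE
FML067	II.4	none		FALSE	TRUE
FML068	II.1	AML	23	TRUE	TRUE
FML068	II.2	BMF	26	FALSE	TRUE
FML068	II.3	MDS	29	FALSE	TRUE
FML068	II.4	none		FALSE	TRUE
FML069	II.1	AML	23	TRUE	TRUE
FML069	II.2	BMF	26	FALSE	TRUE
FML069	II.3	MDS	29	FALSE	TRUE
FML069	II.4	none		FALSE	TRUE
FML070	II.1	AML	23	TRUE	TRUE
FML070	II.2	BMF	26	FALSE	TRUE
FML070	II.3	MDS	29	FALSE	TRUE
FML070	II.4	none		FALSE	TRUE
FML071	II.1	AML	23	TRUE	TRUE
FML071	II.2	BMF	26	FALSE	TRUE
FML071	II.3	MDS	29	FALSE	TRUE
FML071	II.4	none		FALSE	TRUE
FML072	II.1	AML	23	TRUE	TRUE
FML072	II.2	BMF	26	FALSE	TRUE
FML072	II.3	MDS	29	FALSE	TRUE
FML072	II.4	none		FALSE	TRUE
FML073	II.1	AML	23	TRUE	TRUE
FML073	II.2	BMF	26	FALSE	TRUE
FML073	II.3	MDS	29	FALSE	TRUE
FML073	II.4	none		FALSE	TRUE
FML074	II.1	AML	23	TRUE	TRUE
FML074	II.2	BMF	26	FALSE	TRUE
FML074	II.3	MDS	29	FALSE	TRUE
FML074	II.4	none		FALSE	TRUE
FML075	II.1	AML	23	TRUE	TRUE
FML075	II.2	BMF	26	FALSE	TRUE
FML075	II.3	MDS	29	FALSE	TRUE
FML075	II.4	none		FALSE	TRUE
FML076	II.1	AML	23	TRUE	TRUE
FML076	II.2	BMF	26	FALSE	TRUE
FML076	II.3	MDS	29	FALSE	TRUE
FML076	II.4	none		FALSE	TRUE
FML077	II.1	AML	23	TRUE	TRUE
FML077	II.2	BMF	26	FALSE	TRUE
FML077	II.3	MDS	29	FALSE	TRUE
FML077	II.4	none		FALSE	TRUE
FML078	II.1	AML	23	TRUE	TRUE
FML078	II.2	BMF	26	FALSE	TRUE
FML078	II.3	MDS	29	FALSE	TRUE
FML078	II.4	none		FALSE	TRUE
FML079	II.1	AML	23	TRUE	TRUE
FML079	II.2	BMF	26	FALSE	TRUE
FML079	II.3	MDS	29	FALSE	TRUE
FML079	II.4	none		FALSE	TRUE
FML080	II.1	AML	23	TRUE	TRUE
FML080	II.2	BMF	26	FALSE	TRUE
FML080	II.3	MDS	29	FALSE	TRUE
FML080	II.4	none		FALSE	TRUE
FML081	II.1	AML	23	TRUE	TRUE
FML081	II.2	BMF	26	FALSE	TRUE
FML081	II.3	MDS	29	FALSE	TRUE
FML081	II.4	none		FALSE	TRUE
FML082	II.1	AML	23	TRUE	TRUE
FML082	II.2	BMF	26	FALSE	TRUE
FML082	II.3	MDS	29	FALSE	TRUE
FML082	II.4	none		FALSE	TRUE
FML083	II.1	MDS	23	TRUE	TRUE
FML083	II.2	BMF	26	FALSE	TRUE
FML083	II.3	AML	29	FALSE	TRUE
FML084	II.1	MDS	23	TRUE	TRUE
FML084	II.2	BMF	26	FALSE	TRUE
FML084	II.3	AML	29	FALSE	TRUE
FML085	II.1	MDS	23	TRUE	TRUE
FML085	II.2	BMF	26	FALSE	TRUE
FML085	II.3	AML	29	FALSE	TRUE
FML086	II.1	MDS	23	TRUE	TRUE
FML086	II.2	BMF	26	FALSE	TRUE
FML086	II.3	AML	29	FALSE	TRUE
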