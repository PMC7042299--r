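family_id	gene	tier	category
FML001	RUNX1	high	pathogenic
FML002	RUNX1	high	likely_pathogenic
FML003	RUNX1	high	pathogenic
FML004	RUNX1	high	likely_pathogenic
FML005	RUNX1	high	pathogenic
FML006	RUNX1	high	likely_pathogenic
FML007	RUNX1	high	pathogenic
FML008	RUNX1	high	likely_pathogenic
FML009	GATA2	high	pathogenic
FML010	GATA2	high	likely_pathogenic
FML011	GATA2	high	pathogenic
FML012	GATA2	high	likely_pathogenic
FML013	GATA2	high	pathogenic
FML014	GATA2	high	likely_pathogenic
FML015	GATA2	high	pathogenic
FML016	CEBPA	high	likely_pathogenic
FML017	CEBPA	high	pathogenic
FML018	CEBPA	high	likely_pathogenic
FML019	CEBPA	high	pathogenic
FML020	CEBPA	high	likely_pathogenic
FML021	CEBPA	high	pathogenic
FML022	DDX41	high	likely_pathogenic
FML023	DDX41	high	pathogenic
FML024	DDX41	high	likely_pathogenic
FML025	DDX41	high	pathogenic
FML026	DDX41	high	likely_pathogenic
FML027	TERT	high	pathogenic
FML028	TERT	high	likely_pathogenic
FML029	TERT	high	pathogenic
FML030	TERT	high	likely_pathogenic
FML031	TERT	high	pathogenic
FML032	TERC	high	likely_pathogenic
FML033	TERC	high	pathogenic
FML034	TERC	high	likely_pathogenic
FML035	ETV6	high	pathogenic
FML036	ETV6	high	likely_pathogenic
FML037	ANKRD26	high	pathogenic
FML038	ANKRD26	high	likely_pathogenic
FML039	TP53	high	pathogenic
FML040	SAMD9L	moderate	likely_pathogenic
FML041	SRP72	moderate	pathogenic
FML042	ACD	moderate	likely_pathogenic
FML043	CHEK2	moderate	pathogenic
FML044	ATG2B/GSKIP	emerging	likely_pathogenic
FML045	ERCC6L2	emerging	pathogenic
FML046	FANCA	emerging	likely_pathogenic
FML047	MECOM	emerging	pathogenic
FML048	SBDS	emerging	likely_pathogenic
FML049	WAS	emerging	pathogenic
FML050			none
FML051			none
FML052			none
FML053			none
FML054			none
FML055			none
FML056			none
FML057			none
FML058			none
FML059			none
FML060			none
FML061			none
FML062			none
FML063			none
FML064			none
FML065			none
FML066			none
FML067			none
FML068			none
FML069			none
FML070			none
FML071			none
FML072			none
FML073			none
FML074			none
FML075			none
FML076			none
FML077			none
FML078			none
FML079			none
FML080			none
FML081			none
FML082			none
FML083			none
FML084			none
FML085			none
FML086			none
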