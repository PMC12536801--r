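gene_symbol	ko_ids	aliases	stage
pth	K90001		sporulation onset and checkpoints
yaaT	K90002		Spo0A regulon
spoIIAB	K90003		engulfment
spoIIIAE	K90004		SigF regulon
spoIIIAD	K90005		SigE regulon
ctpB	K90006		SigG regulon
ftsW	K90007		SigK regulon
spoVD	K90008		spore cortex
lgt	K90009		spore coat
lytH	K90010		germination
cotP	K90011		sporulation onset and checkpoints
spoIIIAG	K90012		Spo0A regulon
spoIIR	K90013		engulfment
spoVAD	K90014		SigF regulon
gerC	K90015		SigE regulon
yabP	K90016		SigG regulon
yqfD	K90017		SigK regulon
gerD	K90018		spore cortex
spoVAA	K90019		spore coat
gpr	K90020		germination
ytaF	K90021		sporulation onset and checkpoints
gdh	K90022		Spo0A regulon
ypeB	K90023		engulfment
spoVID	K90024		SigF regulon
ymfJ	K90025		SigE regulon
sporgene_026	K90026		SigG regulon
sporgene_027	K90027		SigK regulon
sporgene_028	K90028		spore cortex
sporgene_029	K90029		spore coat
sporgene_030	K90030		germination
sporgene_031	K90031		sporulation onset and checkpoints
sporgene_032	K90032		Spo0A regulon
sporgene_033	K90033		engulfment
sporgene_034	K90034		SigF regulon
sporgene_035	K90035		SigE regulon
sporgene_036	K90036		SigG regulon
sporgene_037	K90037		SigK regulon
sporgene_038	K90038		spore cortex
sporgene_039	K90039		spore coat
sporgene_040	K90040		germination
sporgene_041	K90041		sporulation onset and checkpoints
sporgene_042	K90042		Spo0A regulon
sporgene_043	K90043		engulfment
sporgene_044	K90044		SigF regulon
sporgene_045	K90045		SigE regulon
sporgene_046	K90046		SigG regulon
sporgene_047	K90047		SigK regulon
sporgene_048	K90048		spore cortex
sporgene_049	K90049		spore coat
sporgene_050	K90050		germination
sporgene_051	K90051		sporulation onset and checkpoints
sporgene_052	K90052		Spo0A regulon
sporgene_053	K90053		engulfment
sporgene_054	K90054		SigF regulon
sporgene_055	K90055		SigE regulon
sporgene_056	K90056		SigG regulon
sporgene_057	K90057		SigK regulon
sporgene_058	K90058		spore cortex
sporgene_059	K90059		spore coat
sporgene_060	K90060		germination
sporgene_061	K90061		sporulation onset and checkpoints
sporgene_062	K90062		Spo0A regulon
sporgene_063	K90063		engulfment
sporgene_064	K90064		SigF regulon
sporgene_065	K90065		SigE regulon
sporgene_066	K90066		SigG regulon
sporgene_067	K90067		SigK regulon
sporgene_068	K90068		spore cortex
sporgene_069	K90069		spore coat
sporgene_070	K90070		germination
sporgene_071	K90071		sporulation onset and checkpoints
sporgene_072	K90072		Spo0A regulon
sporgene_073	K90073		engulfment
sporgene_074	K90074		SigF regulon
sporgene_075	K90075		SigE regulon
sporgene_076	K90076		SigG regulon
sporgene_077	K90077		SigK regulon
sporgene_078	K90078		spore cortex
sporgene_079	K90079		spore coat
sporgene_080	K90080		germination
sporgene_081	K90081		sporulation onset and checkpoints
sporgene_082	K90082		Spo0A regulon
sporgene_083	K90083		engulfment
sporgene_084	K90084		SigF regulon
sporgene_085	K90085		SigE regulon
sporgene_086	K90086		SigG regulon
sporgene_087	K90087		SigK regulon
sporgene_088	K90088		spore cortex
sporgene_089	K90089		spore coat
sporgene_090	K90090		germination
sporgene_091	K90091		sporulation onset and checkpoints
sporgene_092	K90092		Spo0A regulon
sporgene_093	K90093		engulfment
sporgene_094	K90094		SigF regulon
sporgene_095	K90095		SigE regulon
sporgene_096	K90096		SigG regulon
sporgene_097	K90097		SigK regulon
sporgene_098	K90098		spore cortex
sporgene_099	K90099		spore coat
sporgene_100	K90100		germination
sporgene_101	K90101		sporulation onset and checkpoints
sporgene_102	K90102		Spo0A regulon
sporgene_103	K90103		engulfment
sporgene_104	K90104		SigF regulon
sporgene_105	K90105		SigE regulon
sporgene_106	K90106		SigG regulon
sporgene_107	K90107		SigK regulon
sporgene_108	K90108		spore cortex
sporgene_109	K90109		spore coat
sporgene_110	K90110		germination
sporgene_111	K90111		sporulation onset and checkpoints
sporgene_112	K90112		Spo0A regulon
sporgene_113	K90113		engulfment
sporgene_114	K90114		SigF regulon
sporgene_115	K90115		SigE regulon
sporgene_116	K90116		SigG regulon
sporgene_117	K90117		SigK regulon
sporgene_118	K90118		spore cortex
sporgene_119	K90119		spore coat
sporgene_120	K90120		germination
sporgene_121	K90121		sporulation onset and checkpoints
sporgene_122	K90122		Spo0A regulon
sporgene_123	K90123		engulfment
sporgene_124	K90124		SigF regulon
sporgene_125	K90125		SigE regulon
sporgene_126	K90126		SigG regulon
sporgene_127	K90127		SigK regulon
sporgene_128	K90128		spore cortex
sporgene_129	K90129		spore coat
sporgene_130	K90130		germination
sporgene_131	K90131		sporulation onset and checkpoints
sporgene_132	K90132		Spo0A regulon
sporgene_133	K90133		engulfment
sporgene_134	K90134		SigF regulon
sporgene_135	K90135		SigE regulon
sporgene_136	K90136		SigG regulon
sporgene_137	K90137		SigK regulon
sporgene_138	K90138		spore cortex
sporgene_139	K90139		spore coat
sporgene_140	K90140		germination
sporgene_141	K90141		sporulation onset and checkpoints
sporgene_142	K90142		Spo0A regulon
sporgene_143	K90143		engulfment
sporgene_144	K90144		SigF regulon
sporgene_145	K90145		SigE regulon
sporgene_146	K90146		SigG regulon
sporgene_147	K90147		SigK regulon
sporgene_148	K90148		spore cortex
sporgene_149	K90149		spore coat
sporgene_150	K90150		germination
sporgene_151	K90151		sporulation onset and checkpoints
sporgene_152	K90152		Spo0A regulon
sporgene_153	K90153		engulfment
sporgene_154	K90154		SigF regulon
sporgene_155	K90155		SigE regulon
sporgene_156	K90156		SigG regulon
sporgene_157	K90157		SigK regulon
sporgene_158	K90158		spore cortex
sporgene_159	K90159		spore coat
sporgene_160	K90160		germination
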