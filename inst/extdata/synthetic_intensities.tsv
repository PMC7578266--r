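spot_id	Maq_rep1	Maq_rep2	Maq_rep3	DAA_rep1	DAA_rep2	DAA_rep3	nanoHA_rep1	nanoHA_rep2	nanoHA_rep3
ART_003_EAI(pY)AAPFAKKKXC	431.472513312283	440.199904566882	425.288467065832	472.778052445428	375.827822970336	413.680332284664	433.766350292634	392.483296200472	448.87268011817
SYN001_733_745	209.749893620095	240.348933179104	209.767081826329	66.6012332657737	120.324894160992	72.0079737971516	95.4169407776482	125.746229531762	97.4436899572622
SYN002_402_414	703.653326713044	648.614535821529	732.886674826238	338.198213862766	327.615127719051	356.06029667572	422.442120771511	503.185639324815	435.173090785833
SYN003_221_233	755.654926406796	740.853898485129	787.137586184141	342.861325744229	422.18444400802	351.875469458146	447.937597958112	422.268332964058	439.601064282549
SYN004_648_660	60.5732187069157	65.9593468703947	66.4425994993995	36.7782369124993	26.1740563614702	33.6009247452257	67.719168384257	67.8663324255618	64.6502017540721
SYN005_870_882	102.122180933474	95.4686329234458	127.216515456676	113.222783168079	112.963561149041	119.527128076663	123.46676342386	103.968687738093	113.966241515566
SYN006_420_432	14.6591258294926	24.6538727083275	14.8563874504883	33.6505090781575	24.885913192406	28.7041951342786	9.12440626380245	22.2917536213993	20.765407708447
SYN007_708_720	3164.88053489932	3066.31286643468	3128.07765295454	3228.21162849256	3571.80607860534	2975.0734358352	3380.28634625882	2916.34409997599	3384.67474856625
SYN008_234_246	271.982716167042	254.31734881241	233.693277499203	234.541037458355	282.222719960594	274.009779237283	291.774833286589	255.640904567184	242.082145837107
SYN009_662_674	281.920940987212	252.398437757116	277.806806430443	255.215223834817	299.89176538022	280.695908079942	243.929258042128	-7.45867593725197	237.172610593193
SYN010_420_432	167.519644035045	152.253456784186	-7.28633633455175	145.023587227718	149.895426667912	146.18255758104	160.150792437617	169.55907276827	155.62894752038
SYN011_574_586	172.218572298743	-13.0457891270959	145.244129471621	161.209653503391	149.467074859581	152.135877683168	148.141493921473	163.398666487778	145.262703495368
SYN012_200_212	99.9156002492593	100.992406484898	113.177552997776	123.108127782147	105.682381240941	92.4548638296842	99.6393857922232	107.945448429011	102.611570539262
SYN013_769_781	454.194256634351	865.696075751781	633.09937666577	410.987633635991	428.77652815983	483.349639146275	595.985952596203	380.909894322728	586.098886649903
SYN014_574_586	1067.91680620648	1191.09396849941	1055.40522229664	1090.96975293466	1243.76714039103	1127.282897312	1154.85111723647	1117.6006728622	1124.39803968007
SYN015_469_481	279.622852215972	251.576720148867	233.49155003806	270.994720118082	246.402809935743	254.786035564882	310.656043969504	263.741319117287	232.297577973121
SYN016_673_685	292.038693084979	327.059974999637	340.559703960193	303.091898248049	322.553744936016	289.974333033978	305.959061379533	335.209522891309	297.240418585498
SYN017_9_21	418.301816355166	198.629438447538	583.547963181911	385.514658983022	740.379127102774	593.972710223997	326.714671327264	496.283132057276	435.827523352689
SYN018_122_134	1116.77221542264	1142.38693861784	1039.96119193875	1042.55586970817	967.942228695757	933.50462596501	965.292166963009	1005.22456513145	897.914339889249
SYN019_823_835	260.610600658056	207.300631073505	208.111893175788	233.149147824718	232.660682270661	193.201828440759	215.30700818054	222.269062393941	231.661169093987
SYN020_109_121	723.076389446037	639.291093983722	743.570217215709	841.26728525405	670.483967388847	696.59932083615	672.180177556909	638.757529048451	687.522061203426
SYN021_691_703	532.646705091414	543.187950403036	517.500724948141	573.547570219006	517.146596277817	602.688414470489	581.409700179806	493.839476869629	555.628079791988
SYN022_695_707	880.990561434117	820.036313589214	897.953418566034	843.926332078826	833.948940518288	743.301355175111	801.982940966002	876.691476234402	888.579912534722
SYN023_660_672	688.134514183095	624.126705213014	483.980273899314	665.808595977665	925.34727663402	1152.13344250655	773.381960759643	490.935517865467	936.48974051516
SYN024_364_376	329.520859379949	353.915554586217	317.675898565174	283.01501265913	313.051452549344	317.102360231799	310.488935432055	326.11897112177	287.046875713725
SYN025_476_488	65.3949584048885	67.0185248283245	73.4060551978234	67.2943368776759	79.9530444831183	-6.68872637288556	65.8931315057443	65.2302296725031	86.9787951095734
SYN026_146_158	202.978043176577	187.414354453714	210.794085033487	237.446491900297	232.928042221055	200.359903378478	202.607744952509	192.111906156429	193.027440608222
SYN027_571_583	1468.60319517367	1566.51526438946	1620.75208656438	1410.77339431886	1229.12641257118	1318.36502870027	1415.69554227674	1495.96359199591	1499.48752820375
SYN028_569_581	132.90734498137	155.091389634585	122.115608649177	137.147130431588	129.984057924532	133.033859067243	131.144185527614	119.615690188779	136.843916528928
SYN029_883_895	249.216952878741	249.541864913469	279.454501739747	282.547444488928	285.1962930493	279.352567959249	321.798643777465	278.897291915763	272.02691700925
SYN030_78_90	139.325365339617	146.201538870413	152.002300625887	136.303547182594	135.830802000777	121.640414438441	141.802142230376	145.519986474509	156.288085110982
SYN031_50_62	540.177892152027	662.930504862746	512.033116035594	529.209261606844	623.683072397153	607.433959442882	534.06032063183	614.778115893137	527.04901769199
SYN032_205_217	283.563651087366	272.546991847932	277.39628133787	317.226462837257	317.076262293021	302.24416072581	252.615022477837	269.430655277132	279.355519287326
SYN033_120_132	404.908267727574	415.56331756814	397.469383821817	389.161553239355	359.674932037767	396.713729411499	402.652636391968	410.016723523422	479.667979620587
SYN034_285_297	3058.95387857182	3323.52385257246	3680.42760849619	3593.03052424008	3321.93109981936	4052.68765782302	3312.0082544805	3554.23586030022	3371.81247974318
SYN035_279_291	376.766320904458	406.192675992729	356.377035306122	413.571954706183	458.200297859375	350.969108049412	431.432262752293	461.948408102945	397.178626111277
SYN036_364_376	304.518952373591	262.051497318025	271.344632959397	258.652155987348	308.82183660511	242.198565886716	241.696839400037	325.26100393491	238.080215510454
SYN037_296_308	62.2331131629634	59.8075544618492	56.5487267520656	61.6069080305228	63.3847206265804	60.8996899411239	58.2215267642685	66.883058474818	62.9732584810757
SYN038_56_68	103.979919467697	109.348164168769	108.83446673677	115.776254987047	115.268786226984	111.620001771812	103.547307157657	120.143027840529	108.163942022355
SYN039_540_552	326.385976670159	340.791470216771	375.204614135419	331.445454393633	371.656524767494	355.388317045818	357.017838758454	345.304130393115	314.688265655441
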