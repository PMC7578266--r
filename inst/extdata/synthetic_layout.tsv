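spot_id	protein_name	symbol	phospho_positions	uniprot_accession	sequence
ART_003_EAI(pY)AAPFAKKKXC	internal control peptide	ART3	[]	SYN00000	EAIYAAPFAKKKX
SYN001_733_745	synthetic protein 001	SYN001	[733]	SYN00001	YGPRNESFNCWRQ
SYN002_402_414	synthetic protein 002	SYN002	[403]	SYN00002	CYNFSDNDDLEIV
SYN003_221_233	synthetic protein 003	SYN003	[221]	SYN00003	KNFKPVKSHVFFY
SYN004_648_660	synthetic protein 004	SYN004	[651, 660]	SYN00004	KDRYKGERANGPY
SYN005_870_882	synthetic protein 005	SYN005	[870]	SYN00005	YGTWATYGFTDYR
SYN006_420_432	synthetic protein 006	SYN006	[432]	SYN00006	PANDWPAGVYVAY
SYN007_708_720	synthetic protein 007	SYN007	[708]	SYN00007	YRATKPNWVNKDC
SYN008_234_246	synthetic protein 008	SYN008	[244]	SYN00008	PLQGWNNCECGRY
SYN009_662_674	synthetic protein 009	SYN009	[664]	SYN00009	SGGAEYPDFGWRL
SYN010_420_432	synthetic protein 010	SYN010	[421]	SYN00010	VYVEWGNAFGEQP
SYN011_574_586	synthetic protein 011	SYN011	[583]	SYN00011	QVRITMLSHYPIN
SYN012_200_212	synthetic protein 012	SYN012	[204, 212]	SYN00012	LISAYFLMAVDDY
SYN013_769_781	synthetic protein 013	SYN013	[775]	SYN00013	QEDSHFKGVMWEY
SYN014_574_586	synthetic protein 014	SYN014	[585]	SYN00014	ICCNFDYNYWNYL
SYN015_469_481	synthetic protein 015	SYN015	[470]	SYN00015	SGRKKKDVMTDYC
SYN016_673_685	synthetic protein 016	SYN016	[681, 683]	SYN00016	MGGKADHIYHYNL
SYN017_9_21	synthetic protein 017	SYN017	[9]	SYN00017	YVIECVRIAPSYH
SYN018_122_134	synthetic protein 018	SYN018	[130]	SYN00018	PALHQVERFYLPN
SYN019_823_835	synthetic protein 019	SYN019	[828, 829]	SYN00019	TQVMCYYCLWTKM
SYN020_109_121	synthetic protein 020	SYN020	[109, 116, 120]	SYN00020	YNSMRIRYGLIYN
SYN021_691_703	synthetic protein 021	SYN021	[695, 701]	SYN00021	IVPHYFVEGKYAP
SYN022_695_707	synthetic protein 022	SYN022	[699]	SYN00022	IVCIYVETHDGQP
SYN023_660_672	synthetic protein 023	SYN023	[660]	SYN00023	KYLLDPVAKKTFS
SYN024_364_376	synthetic protein 024	SYN024	[367]	SYN00024	HVCGSSVVYSKCN
SYN025_476_488	synthetic protein 025	SYN025	[478]	SYN00025	QTMYKACEWWILR
SYN026_146_158	synthetic protein 026	SYN026	[149]	SYN00026	HTVTPAPLYCIPR
SYN027_571_583	synthetic protein 027	SYN027	[571, 580]	SYN00027	YHFFIGELSYRQE
SYN028_569_581	synthetic protein 028	SYN028	[579]	SYN00028	LTEAFVYGMLYNT
SYN029_883_895	synthetic protein 029	SYN029	[889]	SYN00029	IACNGPYKVFTPV
SYN030_78_90	synthetic protein 030	SYN030	[83]	SYN00030	WMENLYYERNTES
SYN031_50_62	synthetic protein 031	SYN031	[58]	SYN00031	CRWQSRWYYSNFK
SYN032_205_217	synthetic protein 032	SYN032	[206, 217]	SYN00032	DYLVVKSLPSVIY
SYN033_120_132	synthetic protein 033	SYN033	[127]	SYN00033	GDQFKMQYEVATC
SYN034_285_297	synthetic protein 034	SYN034	[290]	SYN00034	DWYPTYSVLGWQY
SYN035_279_291	synthetic protein 035	SYN035	[284]	SYN00035	RRFYLYMEVTEIW
SYN036_364_376	synthetic protein 036	SYN036	[366]	SYN00036	PNFRNGYTGMFLT
SYN037_296_308	synthetic protein 037	SYN037	[298]	SYN00037	HSRFERIQCIKIY
SYN038_56_68	synthetic protein 038	SYN038	[62]	SYN00038	QDDSHMYYMAVIS
SYN039_540_552	synthetic protein 039	SYN039	[544, 550]	SYN00039	SPTKYKGCQEYRD
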