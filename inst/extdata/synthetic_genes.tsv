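gene_id	chrom	start	end	strand	developmental	complex_member	ohnologue	omim_disease	ancestral	dosage_sensitive	hi_score	max_expression
G00001	1	168882	204283	+	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	0.19006535943441	10.0381829388355
G00002	1	405683	454909	+	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	0.010323901402969	8.50495674131544
G00003	1	477067	516245	+	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	0.109471327100271	7.99768991228595
G00004	1	543290	573781	+	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE	0.52347725647943	175.386256992032
G00005	1	640023	683258	-	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	2.68217849484055e-05	2.97144389065601
G00006	1	875211	888736	+	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	0.322958200628082	31.6268386457403
G00007	1	913144	930351	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0148508880997314	8.30891775843089
G00008	1	998053	1040319	-	TRUE	FALSE	TRUE	FALSE	TRUE	FALSE	0.274840547793815	2.93643005143958
G00009	1	1103391	1139584	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.00925512675516102	7.36637084940552
G00010	1	1200185	1216009	-	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	0.532429539546935	49.0018620284361
G00011	1	1312934	1319867	-	TRUE	FALSE	TRUE	TRUE	TRUE	TRUE	0.995886824155004	12.0024379575276
G00012	1	1698588	1709909	+	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.000787840185605541	3.16750071659796
G00013	1	1947222	1961958	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.647206688713006	9.60956032175941
G00014	1	2318360	2344932	-	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	0.50619290625217	65.4998916059307
G00015	1	2526111	2539993	+	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	0.144794481748579	7.3249881713805
G00016	1	2635660	2673030	-	FALSE	TRUE	FALSE	FALSE	TRUE	TRUE	0.636680072256172	3.78596348986675
G00017	1	2936538	2941892	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.000122204515821134	1.66767502601928
G00018	1	2957473	2979369	-	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	0.000520514844988629	3.18154571178824
G00019	1	3045527	3073674	+	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE	0.762172899148321	10.6249235884002
G00020	1	3222873	3227943	+	FALSE	TRUE	FALSE	TRUE	FALSE	FALSE	0.00325572507571592	7.79692218088934
G00021	1	3312023	3343194	-	TRUE	FALSE	TRUE	FALSE	TRUE	FALSE	0.103580522674117	17.886374589551
G00022	1	3534826	3546931	-	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	0.0516841337255599	4.74884340822926
G00023	1	3600790	3621945	-	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	0.187751158667214	5.25445628933652
G00024	1	3705125	3739177	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.104815446957	16.5762133254913
G00025	1	4024043	4063954	-	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	0.0491513454466018	27.8346218475605
G00026	1	4600712	4631075	-	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE	0.0188430890622351	32.080809772913
G00027	1	4688610	4704126	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.166607936296629	1.06232989513832
G00028	2	9061	18109	-	FALSE	TRUE	TRUE	FALSE	TRUE	FALSE	0.000388637465730107	8.88375606933314
G00029	2	252459	261311	-	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE	0.00227403174418866	101.470340736244
G00030	2	360782	379516	-	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE	0.618150526152811	47.6909109861283
G00031	2	620599	655632	+	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE	0.105195654947884	2.94579329445209
G00032	2	714706	719716	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0609177555852809	19.2685787622624
G00033	2	892081	906466	+	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	0.0145977619604987	2.80984493256724
G00034	2	1079952	1126938	-	TRUE	FALSE	TRUE	FALSE	TRUE	TRUE	0.381335814876749	11.6075443310575
G00035	2	1228220	1274873	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	8.21641358162815e-05	33.2642310165902
G00036	2	1358361	1396394	+	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0118388822703872	5.64780609246954
G00037	2	1420130	1440117	-	TRUE	TRUE	FALSE	FALSE	TRUE	TRUE	0.709803926042595	54.0542216551061
G00038	2	1515819	1543996	-	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE	0.00163260930119766	5.64047505258617
G00039	2	1613176	1651654	-	FALSE	FALSE	TRUE	FALSE	TRUE	TRUE	0.0922524498656005	3.01650050966132
G00040	2	1679903	1712764	-	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	0.106242745720674	2.88886215135179
G00041	2	1806645	1839825	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0227876308478388	2.16672694221679
G00042	2	1902122	1916893	+	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	9.85809075682443e-09	4.47404471011915
G00043	2	1980500	1995245	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0336363070975547	5.34343172058159
G00044	2	2007128	2029630	-	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	0.960426502457995	16.6382257608619
G00045	2	2138162	2185572	+	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	0.224672666189548	5.97476560279315
G00046	2	2435474	2483790	-	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	0.00130464922099443	77.4849707386222
G00047	2	2556846	2595138	-	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	0.0820269693271504	1.51625508802985
G00048	2	2777357	2815352	-	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE	0.398564671184393	12.1574616967484
G00049	2	2997794	3026902	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.0023585442366187	12.1622802000201
G00050	2	3314318	3319419	+	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	0.108656729350464	56.4622492888532
G00051	2	3685899	3718300	+	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	0.00272309731928155	8.89658785845497
G00052	2	3780834	3823489	-	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	0.246524123987199	35.3897557179402
G00053	2	3882970	3921788	+	TRUE	FALSE	TRUE	FALSE	TRUE	TRUE	0.991600901159699	2.77948492191535
G00054	2	3967872	3993244	-	FALSE	TRUE	TRUE	FALSE	TRUE	FALSE	0.0110946675672275	45.3799043745622
G00055	2	4096433	4125543	-	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	0.152002194226123	3.49302923603258
G00056	2	4148042	4177223	-	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	0.971634145280352	14.3538036673521
G00057	2	4188028	4193089	+	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE	0.00625930349485052	2.11306400620441
G00058	2	4231629	4252633	-	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	0.582944301994272	9.3941271372871
G00059	2	4386195	4418740	-	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE	0.0591099988475405	68.1593539305512
G00060	2	4815430	4857731	+	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	0.669983901703929	146.355349899179
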