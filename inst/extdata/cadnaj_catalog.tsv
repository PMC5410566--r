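# Published catalog of the 76 pepper CaDnaJ family members (Table 1 shape).
# Columns: gene_name locus start end chromosome group size_aa mw_da pi introns
# Unplaced scaffold genes carry chromosome "00" and empty coordinates.
# The table is preserved verbatim, including its known internal
# inconsistencies (e.g. CaDnaJ02/CaDnaJ03 sharing MW/pI); it is data, not
# corrected.
gene_name	locus	start	end	chromosome	group	size_aa	mw_da	pi	introns
CaDnaJ01	CA01g16030	97618202	97621808	1	C	574	64187.51	8.54	5
CaDnaJ02	CA01g17770	143624907	143627243	1	C	778	32485.78	6.35	0
CaDnaJ03	CA01g18690	156550800	156555986	1	A	300	32485.78	6.35	11
CaDnaJ04	CA01g22020	169879103	169880683	1	C	526	58220.93	8.34	0
CaDnaJ05	CA01g25030	203653187	203656231	1	C	1014	113869.47	5.73	0
CaDnaJ06	CA01g27370	222188570	222189529	1	C	288	32533.02	8.65	1
CaDnaJ07	CA01g30060	252896608	252899637	1	C	968	110547.4	8.45	2
CaDnaJ08	CA02g03340	46401318	46404099	2	C	469	51784.11	7.97	3
CaDnaJ09	CA02g06030	81542166	81542741	2	C	184	20655.63	8.95	1
CaDnaJ10	CA02g07560	109106142	109111419	2	C	505	57920.91	8.19	4
CaDnaJ11	CA02g15460	144816870	144819496	2	B	352	38501.82	9.17	2
CaDnaJ12	CA03g00750	1443148	1444782	3	C	180	21530.33	9.49	1
CaDnaJ13	CA03g08730	28341344	28342355	3	C	249	28757.26	5.52	1
CaDnaJ14	CA03g19380	212945408	212947600	3	C	730	81652.23	9.02	0
CaDnaJ15	CA03g24080	228862136	228863317	3	C	393	43430.55	9.85	0
CaDnaJ16	CA03g25800	235233410	235241868	3	C	785	59082.25	7.21	9
CaDnaJ17	CA03g31950	249441998	249454817	3	A	421	45593.07	9.23	7
CaDnaJ18	CA03g37040	257676539	257678405	3	C	215	23745.93	5.02	5
CaDnaJ19	CA04g03850	11909825	11910715	4	A	286	31473.8	8.86	1
CaDnaJ20	CA04g12150	170393420	170395215	4	C	209	23712.34	5.97	2
CaDnaJ21	CA04g16150	205132799	205133939	4	C	347	37710.14	8.68	2
CaDnaJ22	CA04g16480	205935059	205935586	4	C	175	20694.67	9.97	0
CaDnaJ23	CA04g19270	214481447	214481839	4	E	130	15006.93	9.52	0
CaDnaJ24	CA04g21880	219689981	219690469	4	C	162	17672.7	9.87	0
CaDnaJ25	CA05g00380	478405	487668	5	C	1432	157852.71	8.6	10
CaDnaJ26	CA05g03820	10149653	10153690	5	A	417	46743.88	6.12	5
CaDnaJ27	CA05g09770	104367131	104370250	5	C	212	23288.3	5.32	5
CaDnaJ28	CA05g10040	111541112	111547755	5	E	258	28711.63	8.68	1
CaDnaJ29	CA05g11830	157117370	157119724	5	C	784	88043.88	7.08	0
CaDnaJ30	CA05g12050	165924883	165925699	5	C	183	20601.3	9.21	2
CaDnaJ31	CA05g17350	225414158	225414685	5	C	175	20366.33	9.6	0
CaDnaJ32	CA05g18040	227747673	227748459	5	C	233	27032.68	6.54	1
CaDnaJ33	CA05g19550	231614733	231618044	5	A	419	46582.74	6.01	4
CaDnaJ34	CA06g00330	381222	387261	6	B	345	39132.52	6.35	9
CaDnaJ35	CA06g19300	218954099	218961832	6	B	345	38203.22	9.11	1
CaDnaJ36	CA06g27020	234692516	234693273	6	D	216	24361.61	9.77	1
CaDnaJ37	CA07g03000	13658626	13660185	7	E	519	57652.71	5.32	0
CaDnaJ38	CA07g04780	39783049	39785325	7	C	758	84482.15	8.38	0
CaDnaJ39	CA07g14410	212076067	212082495	7	B	345	37215.12	9.17	2
CaDnaJ40	CA07g14580	212629401	212635278	7	C	295	33432.67	5.6	8
CaDnaJ41	CA07g20780	230038893	230039930	7	C	138	15577.42	9.69	1
CaDnaJ42	CA07g20790	230043861	230044460	7	C	199	16176.37	8.87	0
CaDnaJ43	CA07g21520	231469760	231475634	7	C	562	64225.13	8.53	8
CaDnaJ44	CA08g04550	83124279	83126597	8	C	772	86114.31	8.13	0
CaDnaJ45	CA08g04600	84686555	84694315	8	C	1272	140416.01	6.06	7
CaDnaJ46	CA08g06460	119037486	119039876	8	B	323	35771.63	8.74	2
CaDnaJ47	CA08g09710	127054669	127056621	8	C	650	74087.37	8.35	0
CaDnaJ48	CA08g11000	129804829	129805596	8	C	255	28904.03	9.37	0
CaDnaJ49	CA08g11250	130268529	130271774	8	C	1081	120431.12	8.59	0
CaDnaJ50	CA08g12000	131886063	131888726	8	C	268	29611.44	6.97	6
CaDnaJ51	CA08g12400	132522159	132523390	8	C	169	19029.27	5.96	4
CaDnaJ52	CA08g15850	138087951	138093573	8	A	447	48202.89	9.29	6
CaDnaJ53	CA08g16300	138809830	138812058	8	E	742	81179.23	8.8	0
CaDnaJ54	CA08g16570	139457347	139458186	8	C	279	31836.41	7.73	0
CaDnaJ55	CA09g01340	2706279	2712890	9	C	666	74144.61	5.07	10
CaDnaJ56	CA09g02890	7558262	7563055	9	C	437	48590.89	6.07	7
CaDnaJ57	CA09g10060	137889893	137892146	9	C	524	57233.33	9.24	4
CaDnaJ58	CA09g11550	183732592	183739583	9	B	344	37544.53	9.23	2
CaDnaJ59	CA10g18490	226999515	226999919	10	C	134	15596.59	9.45	0
CaDnaJ60	CA10g20680	230815988	230820272	10	C	285	32803.76	5.92	7
CaDnaJ61	CA10g21560	232003695	232006477	10	C	303	34356.11	7.71	2
CaDnaJ62	CA11g00780	1313193	1320773	11	C	414	45782.29	5.93	10
CaDnaJ63	CA11g05830	31452436	31455481	11	B	309	34460.23	9.18	1
CaDnaJ64	CA11g10010	113882240	113883699	11	B	355	39775.51	7.59	2
CaDnaJ65	CA11g15800	246441094	246443635	11	A	420	46685.7	5.96	5
CaDnaJ66	CA11g15990	246907971	246916099	11	C	249	29550.83	9.42	8
CaDnaJ67	CA12g07660	35330989	35333794	12	A	420	46676.65	6.17	5
CaDnaJ68	CA12g15900	210077200	210078225	12	C	341	38582.29	8.38	0
CaDnaJ69	CA12g16980	217402887	217403441	12	C	184	20599.06	4.81	0
CaDnaJ70	CA12g18310	225521850	225529944	12	C	366	41110.67	5.41	8
CaDnaJ71	CA12g21480	233476472	233477521	12	C	349	40840.83	7.63	0
CaDnaJ72	CA00g32600			00	A	421	47162.33	7	6
CaDnaJ73	CA00g54170			00	E	711	77402.78	5.83	0
CaDnaJ74	CA00g57050			00	C	193	22938.37	4.56	4
CaDnaJ75	CA00g75210			00	C	771	86305.23	9.37	0
CaDnaJ76	CA00g93240			00	C	570	62812.03	4.95	7
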